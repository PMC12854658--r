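# Combine two detectors' per-stay calls (union / intersection) and
# summarize which detector contributed each positive.

#' Combine two sets of per-stay bleeding calls
#'
#' `union`: a stay is positive when either detector is positive; severity is
#' the maximum of the two (MB > CRNMB). `intersection`: positive only when
#' both are; severity again the maximum. A `history` label from the text
#' detector counts as negative for active-bleeding combination but is kept in
#' the component columns. With `nlp_overrides = TRUE`, detector B's severity
#' replaces A's whenever both are positive and disagree (the "reclassified by
#' NLP" reading).
#'
#' @param calls_a,calls_b tibbles with columns stay_id, label; must cover
#'   identical stay_id sets
#' @param mode `"union"` or `"intersection"`
#' @param nlp_overrides let detector B's severity win on disagreement
#' @return tibble: stay_id, label, mode, label_a, label_b, provenance
#' @export
combine_calls <- function(calls_a, calls_b, mode = c("union", "intersection"),
                          nlp_overrides = FALSE) {
  mode <- match.arg(mode)
  a <- tibble(stay_id = as.character(calls_a$stay_id), label_a = as.character(calls_a$label))
  b <- tibble(stay_id = as.character(calls_b$stay_id), label_b = as.character(calls_b$label))
  only_a <- setdiff(a$stay_id, b$stay_id)
  only_b <- setdiff(b$stay_id, a$stay_id)
  if (length(only_a) > 0 || length(only_b) > 0) {
    abort(paste0(
      "call sets cover different stays; only in A: {",
      paste(head(only_a, 5), collapse = ", "), "}; only in B: {",
      paste(head(only_b, 5), collapse = ", "), "}"
    ))
  }
  m <- inner_join(a, b, by = "stay_id")
  ra <- severity_rank(m$label_a)
  rb <- severity_rank(m$label_b)
  pos_a <- ra > 0
  pos_b <- rb > 0
  sev <- if (nlp_overrides) ifelse(pos_a & pos_b, rb, pmax(ra, rb)) else pmax(ra, rb)
  positive <- if (mode == "union") pos_a | pos_b else pos_a & pos_b
  m$label <- ifelse(positive, c("none", "CRNMB", "MB")[sev + 1], "none")
  m$provenance <- dplyr::case_when(
    pos_a & pos_b ~ "both",
    pos_a ~ "a_only",
    pos_b ~ "b_only",
    TRUE ~ "neither"
  )
  m$mode <- mode
  m[, c("stay_id", "label", "mode", "label_a", "label_b", "provenance")]
}

#' Attribution of combined positives to their source detectors
#'
#' Among union-combined stays whose combined label equals `severity`, counts
#' how many were called at that severity by detector A alone, B alone, or
#' both, with shares of the positive total (1-decimal rounding, exact values
#' retained).
#'
#' @param combined output of [combine_calls()] in union mode
#' @param severity `"MB"` or `"CRNMB"`
#' @return tibble: source, n, pct (exact), pct_rounded; zero rows when no
#'   stay carries the severity
#' @export
attribution_summary <- function(combined, severity = c("MB", "CRNMB")) {
  severity <- match.arg(severity)
  pos <- combined[combined$label == severity, , drop = FALSE]
  if (nrow(pos) == 0) {
    return(tibble(source = character(), n = integer(), pct = numeric(),
                  pct_rounded = numeric()))
  }
  at_a <- pos$label_a == severity
  at_b <- pos$label_b == severity
  n <- c(a_only = sum(at_a & !at_b), b_only = sum(!at_a & at_b), both = sum(at_a & at_b))
  pct <- n / nrow(pos) * 100
  tibble(source = names(n), n = as.integer(n), pct = as.numeric(pct),
         pct_rounded = round_half_away(as.numeric(pct), 1))
}
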