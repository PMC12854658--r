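# Structured-data rule engine.
#
# A stay is labelled MB when any of the following holds:
#   - hemoglobin drop >= 4 g/dL within 48 h
#   - drop in [2, 4) g/dL within 48 h followed by death within 24 h of the
#     drop's later measurement
#   - hemoglobin nadir < 7 g/dL
#   - nadir in [7, 9] g/dL followed by death within 24 h of the nadir
#   - more than 5 units of whole blood or red blood cells transfused
#   - prescription of an antihemorrhagic (reversal) agent
#   - an MB ICD-10-GM diagnosis code
# Else CRNMB when the drop or nadir band occurs without the linked death, or
# a CRNMB code is present. Else no bleeding. MB takes precedence over CRNMB.

MB_CRITERIA <- c("HB_DROP_GE4", "HB_DROP_2TO4_DEATH24", "HB_MIN_LT7",
                 "HB_MIN_7TO9_DEATH24", "TRANSFUSION_GT5",
                 "ANTIHEMORRHAGIC_RX", "ICD_MB")
CRNMB_CRITERIA <- c("HB_DROP_2TO4_NO_DEATH", "HB_MIN_7TO9_NO_DEATH", "ICD_CRNMB")

#' Default antihemorrhagic agent list
#'
#' Reversal agents whose prescription is taken as indicative of major
#' bleeding: idarucizumab, andexanet alfa, and the prothrombin complex
#' concentrates prothromplex, octaplex, and beriplex.
#'
#' @return lowercase character vector of agent names
#' @export
antihemorrhagic_agents <- function() {
  c("idarucizumab", "andexanet alfa", "prothromplex", "octaplex", "beriplex")
}

#' Largest hemoglobin drop within a time window
#'
#' Scans all ordered measurement pairs no more than `window_hours` apart and
#' returns the pair maximizing the decline (earlier value minus later value)
#' when that maximum is positive. Ties are broken by earliest end timestamp,
#' then earliest start timestamp.
#'
#' @param labs tibble with columns `ts` (POSIXct or numeric hours) and
#'   `value` (g/dL), sorted ascending by `ts`
#' @param window_hours window width in hours
#' @return `NULL`, or a list with start_ts, end_ts, start_value, end_value,
#'   drop, window_hours
#' @export
max_hb_drop <- function(labs, window_hours = 48) {
  n <- nrow(labs)
  if (n < 2) {
    return(NULL)
  }
  ts <- labs$ts
  if (is.unsorted(as.numeric(ts))) abort("labs must be sorted ascending by ts")
  val <- labs$value
  best <- NULL
  lo <- 1L
  for (j in 2:n) {
    gap <- if (inherits(ts, "POSIXct")) hours_between(ts[j], ts) else ts[j] - ts
    cand <- which(gap <= window_hours & gap > 0)
    cand <- cand[cand < j]
    if (length(cand) == 0) next
    drops <- val[cand] - val[j]
    dmax <- max(drops)
    if (dmax <= 0) next
    i <- cand[drops == dmax][1] # earliest start on ties
    if (is.null(best) || dmax > best$drop) {
      best <- list(start_ts = ts[i], end_ts = ts[j],
                   start_value = val[i], end_value = val[j],
                   drop = dmax, window_hours = window_hours)
    }
    # ties across j resolve to the earliest end_ts: strict > above keeps
    # the first (earliest-j) maximum
  }
  best
}

#' Minimum hemoglobin value of a stay
#'
#' @param labs tibble with columns `ts`, `value`
#' @return `NULL` for an empty series, else list(value, ts); earliest
#'   timestamp on ties
#' @export
min_hb <- function(labs) {
  if (nrow(labs) == 0) {
    return(NULL)
  }
  i <- which(labs$value == min(labs$value))[1]
  list(value = labs$value[i], ts = labs$ts[i])
}

#' Did death occur within a horizon after an anchor event?
#'
#' @param anchor_ts anchor timestamp (drop end or nadir)
#' @param death_ts death timestamp, possibly `NA`
#' @param horizon_hours horizon in hours; the bound is inclusive
#' @return logical
#' @export
death_within <- function(anchor_ts, death_ts, horizon_hours = 24) {
  if (is.null(death_ts) || length(death_ts) == 0 || is.na(death_ts)) {
    return(FALSE)
  }
  gap <- if (inherits(anchor_ts, "POSIXct")) hours_between(death_ts, anchor_ts) else death_ts - anchor_ts
  gap >= 0 && gap <= horizon_hours
}

#' Countable transfusion units of a stay
#'
#' Sums units over whole blood and red blood cell events; plasma is excluded
#' from the major-bleeding transfusion rule.
#'
#' @param transfusions tibble with columns `product`, `units`
#' @return integer total
#' @export
transfusion_total <- function(transfusions) {
  if (nrow(transfusions) == 0) {
    return(0L)
  }
  keep <- transfusions$product %in% c("whole_blood", "red_blood_cells")
  sum(as.integer(transfusions$units[keep]))
}

#' Was an antihemorrhagic agent prescribed?
#'
#' Matching is word-boundary tolerant on the normalized lowercase agent name,
#' so trade-name suffixes ("Beriplex P/N 500") still hit.
#'
#' @param prescriptions tibble with column `agent_name` (lowercase)
#' @param agents agent list, see [antihemorrhagic_agents()]
#' @return logical
#' @export
antihemorrhagic_hit <- function(prescriptions, agents = antihemorrhagic_agents()) {
  if (nrow(prescriptions) == 0) {
    return(FALSE)
  }
  names_lc <- tolower(prescriptions$agent_name)
  any(vapply(agents, function(a) {
    any(grepl(paste0("\\b", a, "\\b"), names_lc, perl = TRUE))
  }, logical(1)))
}

#' Classify one stay from structured data
#'
#' @param bundle stay bundle from [stay_bundle()]
#' @param window_hours hemoglobin-drop window (default 48 h)
#' @param death_horizon_hours death-linkage horizon (default 24 h)
#' @param patterns ICD pattern table, see [icd_patterns()]
#' @param agents antihemorrhagic agent list
#' @return one-row tibble: stay_id, label, criteria_fired (list),
#'   sources_fired (list), mb_mortality, evidence (list)
#' @export
classify_stay <- function(bundle, window_hours = 48, death_horizon_hours = 24,
                          patterns = icd_patterns(),
                          agents = antihemorrhagic_agents()) {
  stay <- bundle$stay
  death_ts <- stay$death_ts[[1]]
  criteria <- character()
  evidence <- character()

  drop <- max_hb_drop(bundle$labs, window_hours)
  if (!is.null(drop)) {
    if (drop$drop >= 4) {
      criteria <- c(criteria, "HB_DROP_GE4")
      evidence <- c(evidence, sprintf("Hb drop %.2f g/dL within %g h", drop$drop, window_hours))
    } else if (drop$drop >= 2) {
      if (death_within(drop$end_ts, death_ts, death_horizon_hours)) {
        criteria <- c(criteria, "HB_DROP_2TO4_DEATH24")
        evidence <- c(evidence, sprintf("Hb drop %.2f g/dL with death within %g h", drop$drop, death_horizon_hours))
      } else {
        criteria <- c(criteria, "HB_DROP_2TO4_NO_DEATH")
        evidence <- c(evidence, sprintf("Hb drop %.2f g/dL, no linked death", drop$drop))
      }
    }
  }

  nadir <- min_hb(bundle$labs)
  if (!is.null(nadir)) {
    if (nadir$value < 7) {
      criteria <- c(criteria, "HB_MIN_LT7")
      evidence <- c(evidence, sprintf("Hb nadir %.2f g/dL", nadir$value))
    } else if (nadir$value <= 9) {
      if (death_within(nadir$ts, death_ts, death_horizon_hours)) {
        criteria <- c(criteria, "HB_MIN_7TO9_DEATH24")
        evidence <- c(evidence, sprintf("Hb nadir %.2f g/dL with death within %g h", nadir$value, death_horizon_hours))
      } else {
        criteria <- c(criteria, "HB_MIN_7TO9_NO_DEATH")
        evidence <- c(evidence, sprintf("Hb nadir %.2f g/dL, no linked death", nadir$value))
      }
    }
  }

  units <- transfusion_total(bundle$transfusions)
  if (units > 5) {
    criteria <- c(criteria, "TRANSFUSION_GT5")
    evidence <- c(evidence, sprintf("%d units of blood / red blood cells transfused", units))
  }

  if (antihemorrhagic_hit(bundle$prescriptions, agents)) {
    criteria <- c(criteria, "ANTIHEMORRHAGIC_RX")
    evidence <- c(evidence, "antihemorrhagic agent prescribed")
  }

  codes <- classify_codes(bundle$diagnoses, patterns)
  if (codes$mb_hit) {
    criteria <- c(criteria, "ICD_MB")
    hits <- codes$matched[codes$matched$severity == "MB", ]
    evidence <- c(evidence, paste0("MB code ", hits$code, " (", hits$pattern, ")"))
  }
  if (codes$crnmb_hit) {
    criteria <- c(criteria, "ICD_CRNMB")
    hits <- codes$matched[codes$matched$severity == "CRNMB", ]
    evidence <- c(evidence, paste0("CRNMB code ", hits$code, " (", hits$pattern, ")"))
  }

  label <- if (any(criteria %in% MB_CRITERIA)) "MB" else if (any(criteria %in% CRNMB_CRITERIA)) "CRNMB" else "none"

  # source attribution is restricted to the tier that fixed the label
  # (Figs-style contribution analysis counts within MB and CRNMB separately)
  lab_crit <- if (label == "MB") {
    c("HB_DROP_GE4", "HB_DROP_2TO4_DEATH24", "HB_MIN_LT7", "HB_MIN_7TO9_DEATH24")
  } else {
    c("HB_DROP_2TO4_NO_DEATH", "HB_MIN_7TO9_NO_DEATH")
  }
  icd_crit <- if (label == "MB") "ICD_MB" else "ICD_CRNMB"
  sources <- character()
  if (label != "none") {
    if (any(criteria %in% lab_crit)) sources <- c(sources, "laboratory")
    if (any(criteria %in% icd_crit)) sources <- c(sources, "icd")
    if (label == "MB" && "TRANSFUSION_GT5" %in% criteria) sources <- c(sources, "transfusion")
    if (label == "MB" && "ANTIHEMORRHAGIC_RX" %in% criteria) sources <- c(sources, "medication")
  }

  tibble(
    stay_id = stay$stay_id[[1]],
    label = label,
    criteria_fired = list(criteria),
    sources_fired = list(sources),
    mb_mortality = label == "MB" && !is.na(death_ts),
    evidence = list(evidence)
  )
}

#' Run the structured-data rule engine over a cohort
#'
#' @param x a `bleed_cohort` (typically after [filter_eligible()])
#' @inheritParams classify_stay
#' @return tibble of per-stay calls, one row per stay, in cohort order
#' @export
detect_sda <- function(x, window_hours = 48, death_horizon_hours = 24,
                       patterns = icd_patterns(),
                       agents = antihemorrhagic_agents()) {
  stopifnot(inherits(x, "bleed_cohort"))
  split_tab <- function(tab) split(tab, factor(tab$stay_id, levels = x$stays$stay_id))
  labs <- split_tab(x$labs)
  tfs <- split_tab(x$transfusions)
  rxs <- split_tab(x$prescriptions)
  dxs <- split_tab(x$diagnoses)
  calls <- lapply(seq_len(nrow(x$stays)), function(i) {
    id <- x$stays$stay_id[i]
    bundle <- list(stay = x$stays[i, , drop = FALSE],
                   labs = labs[[id]], transfusions = tfs[[id]],
                   prescriptions = rxs[[id]], diagnoses = dxs[[id]])
    classify_stay(bundle, window_hours, death_horizon_hours, patterns, agents)
  })
  bind_rows(calls)
}

#' Prevalence summary of bleeding calls
#'
#' Counts and percentages for the no-bleeding / CRNMB / MB partition plus
#' MB in-hospital mortality. Percentages are reported both exact and rounded
#' half away from zero to two decimals.
#'
#' @param calls call tibble from [detect_sda()]; alternatively pass `counts`
#' @param denominator total number of stays
#' @param counts optional named vector `c(none=, CRNMB=, MB=, mb_mortality=)`
#'   to summarize published counts directly
#' @return tibble with columns category, n, pct (exact), pct_rounded
#' @export
cohort_prevalence <- function(calls = NULL, denominator = NULL, counts = NULL) {
  if (is.null(counts)) {
    stopifnot(!is.null(calls))
    if (is.null(denominator)) denominator <- nrow(calls)
    counts <- c(
      none = sum(calls$label == "none"),
      CRNMB = sum(calls$label == "CRNMB"),
      MB = sum(calls$label == "MB"),
      mb_mortality = sum(calls$mb_mortality)
    )
  }
  need <- c("none", "CRNMB", "MB", "mb_mortality")
  if (!all(need %in% names(counts))) abort("counts must name none, CRNMB, MB, mb_mortality")
  if (is.null(denominator)) abort("denominator required with explicit counts")
  if (counts[["none"]] + counts[["CRNMB"]] + counts[["MB"]] != denominator) {
    abort("none + CRNMB + MB counts must sum to the denominator")
  }
  n <- as.integer(counts[need])
  pct <- n / denominator * 100
  tibble(
    category = c("none", "CRNMB", "MB", "MB in-hospital mortality"),
    n = n,
    pct = pct,
    pct_rounded = round_half_away(pct, 2)
  )
}
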