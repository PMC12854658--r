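# Validation against gold-standard labels: binarization scenarios, accuracy
# metrics with Wilson 95% CIs, Fleiss kappa, and the source-contribution /
# overlap analysis.

#' Binarize calls against gold labels under a validation scenario
#'
#' Scenarios: `all_bleeding` — positive is MB or CRNMB; `mb_vs_rest` —
#' positive is MB, everything else negative; `crnmb_vs_none` — stays with
#' gold MB are excluded from the denominator, then positive is CRNMB. A
#' `history` call counts as negative in every scenario (the scenarios
#' concern active bleeding during the stay).
#'
#' @param calls tibble with stay_id, label
#' @param gold tibble with stay_id, label (gold standard)
#' @param scenario one of `"all_bleeding"`, `"mb_vs_rest"`, `"crnmb_vs_none"`
#' @return list: tp, fp, tn, fn, n_evaluated, n_excluded
#' @export
binarize_calls <- function(calls, gold,
                           scenario = c("all_bleeding", "mb_vs_rest", "crnmb_vs_none")) {
  scenario <- match.arg(scenario)
  c2 <- tibble(stay_id = as.character(calls$stay_id), call = as.character(calls$label))
  g2 <- tibble(stay_id = as.character(gold$stay_id), gold = as.character(gold$label))
  if (!setequal(c2$stay_id, g2$stay_id)) abort("calls and gold must cover the same stays")
  m <- inner_join(c2, g2, by = "stay_id")
  m$call[m$call == "history"] <- "none"
  total <- nrow(m)
  if (scenario == "crnmb_vs_none") m <- m[m$gold != "MB", , drop = FALSE]
  pos <- switch(scenario,
    all_bleeding = c("MB", "CRNMB"),
    mb_vs_rest = "MB",
    crnmb_vs_none = "CRNMB"
  )
  gp <- m$gold %in% pos
  cp <- m$call %in% pos
  list(
    tp = sum(gp & cp), fp = sum(!gp & cp), tn = sum(!gp & !cp), fn = sum(gp & !cp),
    n_evaluated = nrow(m), n_excluded = total - nrow(m), scenario = scenario
  )
}

#' Wilson score confidence interval for a binomial proportion
#'
#' @param successes number of successes
#' @param trials number of trials (must be >= 1)
#' @param level confidence level
#' @return named numeric vector `c(low, high)`, clipped to `[0, 1]`
#' @export
wilson_ci <- function(successes, trials, level = 0.95) {
  if (trials < 1) abort("wilson_ci: trials must be >= 1")
  if (successes < 0 || successes > trials) abort("wilson_ci: successes outside [0, trials]")
  z <- qnorm(1 - (1 - level) / 2)
  p <- successes / trials
  denom <- 1 + z^2 / trials
  center <- (p + z^2 / (2 * trials)) / denom
  half <- z / denom * sqrt(p * (1 - p) / trials + z^2 / (4 * trials^2))
  # the bounds are exactly 0 / 1 at the degenerate corners; avoid float fuzz
  low <- if (successes == 0) 0 else max(0, center - half)
  high <- if (successes == trials) 1 else min(1, center + half)
  c(low = low, high = high)
}

#' Diagnostic accuracy metrics with Wilson 95% CIs
#'
#' Sensitivity, specificity, positive and negative predictive value, and
#' accuracy, each with a Wilson interval; F1 is reported as a point estimate
#' only. A metric with a zero denominator is reported as `NA` with the
#' reason, never silently as zero.
#'
#' @param counts confusion counts from [binarize_calls()] (or any list with
#'   tp, fp, tn, fn)
#' @param level confidence level for the Wilson intervals
#' @return tibble: metric, estimate, ci_low, ci_high, numerator, denominator,
#'   note
#' @export
detection_metrics <- function(counts, level = 0.95) {
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  n <- tp + fp + tn + fn
  prop_row <- function(name, num, den, why) {
    if (den == 0) {
      return(tibble(metric = name, estimate = NA_real_, ci_low = NA_real_,
                    ci_high = NA_real_, numerator = num, denominator = den,
                    note = why))
    }
    ci <- wilson_ci(num, den, level)
    tibble(metric = name, estimate = num / den, ci_low = ci[["low"]],
           ci_high = ci[["high"]], numerator = num, denominator = den,
           note = NA_character_)
  }
  out <- bind_rows(
    prop_row("sensitivity", tp, tp + fn, "no gold positives"),
    prop_row("specificity", tn, tn + fp, "no gold negatives"),
    prop_row("ppv", tp, tp + fp, "no positive calls"),
    prop_row("npv", tn, tn + fn, "no negative calls"),
    prop_row("accuracy", tp + tn, n, "no evaluated stays")
  )
  sens <- out$estimate[out$metric == "sensitivity"]
  ppv <- out$estimate[out$metric == "ppv"]
  f1 <- if (is.na(sens) || is.na(ppv) || (sens + ppv) == 0) NA_real_ else 2 * ppv * sens / (ppv + sens)
  bind_rows(out, tibble(metric = "f1", estimate = f1, ci_low = NA_real_,
                        ci_high = NA_real_, numerator = NA_integer_,
                        denominator = NA_integer_,
                        note = if (is.na(f1)) "undefined precision or recall" else NA_character_))
}

#' Fleiss kappa for a fixed number of raters
#'
#' Chance-corrected agreement over categorical ratings. `ratings` is an
#' items-by-raters matrix (or data frame) of category labels; every item must
#' be rated by the same number of raters. The agreement band follows the
#' Landis–Koch scale (>0.80 almost perfect, 0.61–0.80 substantial, 0.41–0.60
#' moderate, 0.21–0.40 fair, 0.00–0.20 slight, <0 poor). A large-sample z
#' test of kappa = 0 is included.
#'
#' @param ratings items x raters matrix/data frame of categorical ratings
#' @return list: kappa, band, p_observed, p_expected, z, p_value, n_items,
#'   n_raters, categories
#' @export
fleiss_kappa <- function(ratings) {
  ratings <- as.matrix(ratings)
  if (nrow(ratings) < 2 || ncol(ratings) < 2) {
    abort("fleiss_kappa needs at least 2 items and 2 raters")
  }
  if (anyNA(ratings)) abort("every item must be rated by every rater (no missing cells)")
  cats <- sort(unique(as.character(ratings)))
  n_items <- nrow(ratings)
  n_raters <- ncol(ratings)
  # items x categories count table
  counts <- vapply(cats, function(cl) rowSums(ratings == cl), numeric(n_items))
  counts <- matrix(counts, nrow = n_items)
  p_j <- colSums(counts) / (n_items * n_raters)
  p_i <- (rowSums(counts^2) - n_raters) / (n_raters * (n_raters - 1))
  p_bar <- mean(p_i)
  pe_bar <- sum(p_j^2)
  kappa <- if (pe_bar == 1) 1 else (p_bar - pe_bar) / (1 - pe_bar)
  band <- if (kappa > 0.80) "almost perfect" else if (kappa > 0.60) "substantial" else
    if (kappa > 0.40) "moderate" else if (kappa > 0.20) "fair" else
      if (kappa >= 0) "slight" else "poor"
  # Fleiss (1971) large-sample variance under H0: kappa = 0
  se0 <- sqrt(2 / (n_items * n_raters * (n_raters - 1))) *
    sqrt(pe_bar - (2 * n_raters - 3) * pe_bar^2 + 2 * (n_raters - 2) * sum(p_j^3)) /
    (1 - pe_bar)
  z <- if (se0 > 0) kappa / se0 else NA_real_
  p_value <- if (is.na(z)) NA_real_ else 2 * stats::pnorm(-abs(z))
  list(kappa = kappa, band = band, p_observed = p_bar, p_expected = pe_bar,
       z = z, p_value = p_value, n_items = n_items, n_raters = n_raters,
       categories = cats)
}

#' Landis–Koch interpretation band for an agreement coefficient
#'
#' @param kappa agreement coefficient
#' @return band label
#' @export
kappa_band <- function(kappa) {
  if (kappa > 0.80) "almost perfect" else if (kappa > 0.60) "substantial" else
    if (kappa > 0.40) "moderate" else if (kappa > 0.20) "fair" else
      if (kappa >= 0) "slight" else "poor"
}

#' Contribution of structured data sources to detected bleeding
#'
#' For stays called at the given severity: per-source counts (a stay can be
#' counted by several sources, so shares may sum past 100%) and the overlap
#' histogram of stays detected by exactly m sources.
#'
#' @param calls call tibble with `label` and list-column `sources_fired`
#' @param severity `"MB"` or `"CRNMB"`
#' @return list: `per_source` tibble (source, n, pct of positives) and
#'   `overlap` tibble (n_sources 1..4, n)
#' @export
source_contribution <- function(calls, severity = c("MB", "CRNMB")) {
  severity <- match.arg(severity)
  pos <- calls[calls$label == severity, , drop = FALSE]
  sources <- c("laboratory", "icd", "transfusion", "medication")
  if (nrow(pos) == 0) {
    return(list(
      per_source = tibble(source = character(), n = integer(), pct = numeric()),
      overlap = tibble(n_sources = integer(), n = integer()),
      n_positive = 0L
    ))
  }
  fired <- pos$sources_fired
  per_source <- tibble(
    source = sources,
    n = unname(vapply(sources, function(s) sum(map_lgl(fired, ~ s %in% .x)), integer(1)))
  )
  per_source$pct <- per_source$n / nrow(pos) * 100
  m <- map_int(fired, length)
  overlap <- tibble(n_sources = 1:4,
                    n = vapply(1:4, function(k) sum(m == k), integer(1)))
  list(per_source = per_source, overlap = overlap, n_positive = nrow(pos))
}
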