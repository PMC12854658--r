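# ICD-10-GM bleeding code lists and wildcard-aware matching.
#
# The packaged list carries 12 major-bleeding (MB) and 41 clinically relevant
# nonmajor bleeding (CRNMB) patterns. A trailing "_" marks a code family
# (German-modification convention): "I61_" covers "I61" and every "I61.x"
# subdivision; "M25.0_" covers "M25.0" and "M25.0x".

#' Normalize a raw ICD-10 code
#'
#' Uppercases, trims whitespace, and inserts the dot after the third
#' character when a 4+ character code is written without one ("I610" becomes
#' "I61.0"). The result is validated against ICD-10 syntax (letter, two
#' digits, optional dotted subdivision).
#'
#' @param raw a single code string
#' @return normalized code string
#' @export
icd_normalize <- function(raw) {
  if (is.na(raw) || !nzchar(trimws(raw))) abort("empty ICD code")
  code <- toupper(trimws(raw))
  if (!grepl(".", code, fixed = TRUE) && nchar(code) >= 4) {
    code <- paste0(substr(code, 1, 3), ".", substr(code, 4, nchar(code)))
  }
  if (!grepl("^[A-Z][0-9]{2}(\\.[0-9A-Z]+)?$", code)) {
    abort(paste0("not a valid ICD-10 code: '", raw, "'"))
  }
  code
}

#' Load the bleeding ICD-10-GM pattern list
#'
#' Returns the packaged MB/CRNMB code lists, or a user-supplied override in
#' the same CSV format (columns pattern, severity, label). Patterns ending in
#' "_" are prefix wildcards; all others match exactly after normalization.
#'
#' @param path optional path to an override CSV
#' @return tibble with columns pattern, severity, label, stem, wildcard
#' @export
icd_patterns <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "icd_bleeding_codes.csv", package = "bleedr")
  }
  pat <- readr::read_csv(path, col_types = "ccc", progress = FALSE)
  if (!all(c("pattern", "severity", "label") %in% names(pat))) {
    abort("ICD list must have columns pattern, severity, label")
  }
  if (!all(pat$severity %in% c("MB", "CRNMB"))) abort("severity must be MB or CRNMB")
  pat$wildcard <- endsWith(pat$pattern, "_")
  stem_raw <- ifelse(pat$wildcard, substr(pat$pattern, 1, nchar(pat$pattern) - 1), pat$pattern)
  pat$stem <- vapply(stem_raw, icd_normalize, character(1))
  if (anyDuplicated(pat[, c("stem", "severity")])) abort("duplicate pattern within a severity list")
  as_tibble(pat)
}

match_one <- function(code, stems, wildcard) {
  exact <- code == stems
  sub <- wildcard & startsWith(
    code,
    ifelse(grepl("\\.", stems), stems, paste0(stems, "."))
  )
  exact | sub
}

#' Match a normalized code against one severity list
#'
#' @param code a normalized ICD-10 code (see [icd_normalize()])
#' @param severity `"MB"` or `"CRNMB"`
#' @param patterns pattern table from [icd_patterns()]
#' @return logical: does the code hit the list?
#' @export
icd_match <- function(code, severity, patterns = icd_patterns()) {
  if (!severity %in% c("MB", "CRNMB")) abort("severity must be 'MB' or 'CRNMB'")
  p <- patterns[patterns$severity == severity, , drop = FALSE]
  any(match_one(code, p$stem, p$wildcard))
}

#' Classify a set of diagnosis codes against both bleeding lists
#'
#' @param diagnoses tibble with column `icd10gm_code` (normalized), or a
#'   character vector of codes
#' @param patterns pattern table from [icd_patterns()]
#' @return list with `mb_hit`, `crnmb_hit`, and `matched` (tibble of
#'   code/pattern/severity pairs, for evidence reporting)
#' @export
classify_codes <- function(diagnoses, patterns = icd_patterns()) {
  codes <- if (is.data.frame(diagnoses)) diagnoses$icd10gm_code else diagnoses
  codes <- unique(as.character(codes))
  matched <- tibble(code = character(), pattern = character(), severity = character())
  for (code in codes) {
    hit <- match_one(code, patterns$stem, patterns$wildcard)
    if (any(hit)) {
      matched <- bind_rows(matched, tibble(
        code = code,
        pattern = patterns$pattern[hit],
        severity = patterns$severity[hit]
      ))
    }
  }
  list(
    mb_hit = any(matched$severity == "MB"),
    crnmb_hit = any(matched$severity == "CRNMB"),
    matched = matched
  )
}
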