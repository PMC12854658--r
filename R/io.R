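# JSONL helpers shared by the calls/corpus readers and the CLI.

#' Read a JSON-lines file into a list of records
#'
#' @param path file path
#' @return list with one element per non-empty line
#' @export
read_jsonl <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, jsonlite::fromJSON, simplifyVector = TRUE)
}

#' Write a list of records as JSON lines
#'
#' @param records list of named lists (one per line)
#' @param path output path
#' @return `path`, invisibly
#' @export
write_jsonl <- function(records, path) {
  lines <- vapply(
    records,
    function(r) jsonlite::toJSON(r, auto_unbox = TRUE, null = "null", digits = NA),
    character(1)
  )
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Write per-stay bleeding calls as JSON lines
#'
#' @param calls tibble as returned by [detect_sda()] or [nlp_calls()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_calls <- function(calls, path) {
  recs <- lapply(seq_len(nrow(calls)), function(i) {
    r <- as.list(calls[i, , drop = FALSE])
    r <- lapply(r, function(col) if (is.list(col)) col[[1]] else col)
    r
  })
  write_jsonl(recs, path)
}

#' Read per-stay bleeding calls from JSON lines
#'
#' @param path file path
#' @return tibble with one row per stay; list-columns for set-valued fields
#' @export
read_calls <- function(path) {
  recs <- read_jsonl(path)
  tibble(
    stay_id = map_chr(recs, ~ as.character(.x$stay_id %||% .x$doc_id)),
    label = map_chr(recs, ~ as.character(.x$label)),
    criteria_fired = map(recs, ~ as.character(.x$criteria_fired %||% character())),
    sources_fired = map(recs, ~ as.character(.x$sources_fired %||% character())),
    mb_mortality = map_lgl(recs, ~ isTRUE(.x$mb_mortality)),
    evidence = map(recs, ~ as.character(.x$evidence %||% character()))
  )
}
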