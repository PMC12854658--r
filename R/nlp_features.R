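# Text preprocessing for the discharge-summary classifier: deterministic
# sentence segmentation, tokenization with a pluggable lemmatizer, and an
# n-gram TF-IDF vectorizer. Everything is language-agnostic; the default
# abbreviation list covers common French clinical shorthand.

#' Default abbreviation list for sentence segmentation
#'
#' Tokens (lowercase, with trailing period) after which a period does not end
#' a sentence.
#'
#' @return character vector
#' @export
nlp_abbreviations <- function() {
  c("p.", "ex.", "dr.", "prof.", "mme.", "m.", "mr.", "etc.", "env.",
    "cf.", "resp.", "no.", "tel.")
}

#' Segment text into sentences
#'
#' Splits on sentence-final punctuation (`.`, `!`, `?`) followed by
#' whitespace or end of text, unless the preceding word is a known
#' abbreviation. Returns character-offset spans into the original text
#' (1-based, inclusive), non-overlapping and ordered.
#'
#' @param text a single string
#' @param abbreviations abbreviation list, see [nlp_abbreviations()]
#' @return tibble with columns start, end, text; zero rows for empty input
#' @export
segment_sentences <- function(text, abbreviations = nlp_abbreviations()) {
  empty <- tibble(start = integer(), end = integer(), text = character())
  if (is.na(text) || !nzchar(trimws(text))) {
    return(empty)
  }
  chars <- strsplit(text, "")[[1]]
  n <- length(chars)
  m <- gregexpr("[.!?]+(?=\\s|$)", text, perl = TRUE)[[1]]
  ends <- integer()
  if (m[1] != -1) {
    for (k in seq_along(m)) {
      pos <- m[k] + attr(m, "match.length")[k] - 1L # last punctuation char
      # word ending at pos, incl. the punctuation
      ws <- gregexpr("\\S+$", substr(text, 1, pos), perl = TRUE)[[1]]
      word <- tolower(substr(text, ws[1], pos))
      if (!word %in% abbreviations) ends <- c(ends, pos)
    }
  }
  if (length(ends) == 0 || max(ends) < n) ends <- c(ends, n)
  starts <- c(1L, head(ends, -1) + 1L)
  out <- tibble(start = starts, end = ends)
  # trim surrounding whitespace from each span
  out$text <- substr(rep(text, nrow(out)), out$start, out$end)
  keep <- nzchar(trimws(out$text))
  out <- out[keep, , drop = FALSE]
  for (i in seq_len(nrow(out))) {
    s <- out$text[i]
    lead <- nchar(s) - nchar(sub("^\\s+", "", s))
    trail <- nchar(s) - nchar(sub("\\s+$", "", s))
    out$start[i] <- out$start[i] + lead
    out$end[i] <- out$end[i] - trail
    out$text[i] <- substr(text, out$start[i], out$end[i])
  }
  out
}

#' Tokenize sentences into normalized token streams
#'
#' Lowercases and extracts unicode word tokens, then applies the configured
#' lemmatizer (a function mapping a token vector to a token vector; `NULL`
#' means the identity, which is a valid configuration).
#'
#' @param texts character vector of sentences
#' @param lemmatizer optional function(character) -> character
#' @return list of character vectors
#' @export
tokenize_sentences <- function(texts, lemmatizer = NULL) {
  toks <- stringr::str_extract_all(stringr::str_to_lower(texts), "[\\p{L}\\p{N}]+")
  if (!is.null(lemmatizer)) toks <- lapply(toks, lemmatizer)
  toks
}

ngramize <- function(tokens, ngram_max = 2) {
  out <- tokens
  if (ngram_max >= 2 && length(tokens) >= 2) {
    for (k in 2:ngram_max) {
      if (length(tokens) < k) break
      idx <- seq_len(length(tokens) - k + 1)
      grams <- tokens[idx]
      for (j in 2:k) grams <- paste(grams, tokens[idx + j - 1], sep = "_")
      out <- c(out, grams)
    }
  }
  out
}

#' Build an n-gram TF-IDF vectorizer from tokenized sentences
#'
#' Vocabulary is restricted to n-grams appearing in at least `min_df`
#' sentences; rows of the transformed matrix are L2-normalized. The smoothed
#' idf is `log((1 + n) / (1 + df)) + 1`.
#'
#' @param token_lists list of token vectors (one per sentence)
#' @param ngram_max maximum n-gram length
#' @param min_df document-frequency floor
#' @return a `bleedr_vectorizer` (vocabulary + idf + settings)
#' @export
build_vectorizer <- function(token_lists, ngram_max = 2, min_df = 2) {
  grams <- lapply(token_lists, ngramize, ngram_max = ngram_max)
  df <- table(unlist(lapply(grams, unique)))
  vocab <- sort(names(df)[df >= min_df])
  if (length(vocab) == 0) abort("empty vocabulary; lower min_df or provide more text")
  nd <- length(token_lists)
  dfv <- as.numeric(df[vocab])
  idf <- log((1 + nd) / (1 + dfv)) + 1
  structure(
    list(vocab = setNames(seq_along(vocab), vocab), idf = idf,
         ngram_max = ngram_max, min_df = min_df, n_train = nd),
    class = "bleedr_vectorizer"
  )
}

#' Transform tokenized sentences into a sparse TF-IDF matrix
#'
#' @param vec a `bleedr_vectorizer`
#' @param token_lists list of token vectors
#' @return sparse `dgCMatrix`, sentences in rows
#' @export
vectorize <- function(vec, token_lists) {
  stopifnot(inherits(vec, "bleedr_vectorizer"))
  ii <- integer(); jj <- integer(); xx <- numeric()
  for (s in seq_along(token_lists)) {
    grams <- ngramize(token_lists[[s]], vec$ngram_max)
    idx <- vec$vocab[grams]
    idx <- idx[!is.na(idx)]
    if (length(idx) == 0) next
    tf <- table(idx)
    j <- as.integer(names(tf))
    w <- as.numeric(tf) * vec$idf[j]
    nrm <- sqrt(sum(w^2))
    if (nrm > 0) w <- w / nrm
    ii <- c(ii, rep.int(s, length(j)))
    jj <- c(jj, j)
    xx <- c(xx, w)
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                       dims = c(length(token_lists), length(vec$vocab)),
                       dimnames = list(NULL, names(vec$vocab)))
}
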