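# Three-stage sentence classifier over discharge summaries, with
# priority-based document aggregation:
#   stage 1: bleeding-relevant vs irrelevant sentences
#   stage 2: irrelevant / antecedent (history) / active bleeding
#   stage 3: MB vs CRNMB within active sentences
# Document label = highest-priority sentence label, MB > CRNMB > history >
# no bleeding. Both a regularized logistic model (glmnet) and a linear SVM
# (e1071) are trained per stage; the winner is chosen by 5-fold
# cross-validated macro-F1, ties going to the simpler logistic model.

SENTENCE_LABELS <- c("irrelevant", "antecedent", "active_mb", "active_crnmb")
DOC_LABELS <- c("A_crnmb", "B_mb", "C_history", "D_none")

#' Macro-averaged F1 score
#'
#' Unweighted mean of per-class F1 over the classes present in `truth`.
#' A class never predicted scores 0.
#'
#' @param truth character/factor vector of gold labels
#' @param pred character/factor vector of predictions
#' @return macro-F1 in `[0, 1]`
#' @export
macro_f1 <- function(truth, pred) {
  truth <- as.character(truth)
  pred <- as.character(pred)
  classes <- sort(unique(truth))
  f1 <- vapply(classes, function(cl) {
    tp <- sum(truth == cl & pred == cl)
    fp <- sum(truth != cl & pred == cl)
    fn <- sum(truth == cl & pred != cl)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  mean(f1)
}

class_weights <- function(y) {
  tab <- table(y)
  w <- length(y) / (length(tab) * tab)
  setNames(as.numeric(w), names(tab))
}

fit_logistic <- function(x, y, lambda_grid) {
  fam <- if (nlevels(y) == 2) "binomial" else "multinomial"
  w <- class_weights(y)[as.character(y)]
  glmnet::glmnet(x, y, family = fam, alpha = 0,
                 lambda = sort(lambda_grid, decreasing = TRUE), weights = w,
                 standardize = FALSE)
}

predict_logistic <- function(fit, x, lambda) {
  as.character(predict(fit, newx = x, s = lambda, type = "class"))
}

fit_svm <- function(x, y, cost) {
  e1071::svm(x, y, kernel = "linear", cost = cost,
             class.weights = class_weights(y), scale = FALSE)
}

predict_svm <- function(fit, x) {
  as.character(predict(fit, x))
}

stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# CV model selection for one stage; returns the refit winner plus the grid.
fit_stage <- function(x, y, stage_name, folds = 5,
                      lambda_grid = c(0.1, 0.01, 0.001),
                      cost_grid = c(0.1, 1, 10)) {
  y <- factor(as.character(y))
  if (nlevels(y) < 2) {
    abort(paste0("stage '", stage_name, "' needs at least 2 classes in the training corpus"))
  }
  fold <- stratified_folds(as.character(y), folds)
  grid <- bind_rows(
    tibble(family = "logistic", param = lambda_grid),
    tibble(family = "svm", param = cost_grid)
  )
  pooled <- lapply(seq_len(nrow(grid)), function(g) character(length(y)))
  for (f in seq_len(folds)) {
    tr <- fold != f
    te <- fold == f
    if (!any(te) || length(unique(y[tr])) < 2) next
    ytr <- droplevels(y[tr])
    logit <- fit_logistic(x[tr, , drop = FALSE], ytr, lambda_grid)
    for (g in seq_len(nrow(grid))) {
      pred <- if (grid$family[g] == "logistic") {
        predict_logistic(logit, x[te, , drop = FALSE], grid$param[g])
      } else {
        predict_svm(fit_svm(x[tr, , drop = FALSE], ytr, grid$param[g]),
                    x[te, , drop = FALSE])
      }
      pooled[[g]][te] <- pred
    }
  }
  grid$macro_f1 <- vapply(seq_len(nrow(grid)), function(g) {
    scored <- nzchar(pooled[[g]])
    macro_f1(as.character(y)[scored], pooled[[g]][scored])
  }, numeric(1))
  # preference order for ties: logistic before svm; larger lambda / smaller
  # cost first (the simpler model wins)
  pref <- order(grid$family != "logistic",
                ifelse(grid$family == "logistic", -grid$param, grid$param))
  best <- pref[which.max(grid$macro_f1[pref])]
  family <- grid$family[best]
  param <- grid$param[best]
  model <- if (family == "logistic") fit_logistic(x, y, lambda_grid) else fit_svm(x, y, param)
  list(stage = stage_name, family = family, param = param, model = model,
       levels = levels(y), grid = grid)
}

predict_stage <- function(stage, x) {
  if (stage$family == "logistic") {
    predict_logistic(stage$model, x, stage$param)
  } else {
    predict_svm(stage$model, x)
  }
}

corpus_sentence_table <- function(corpus, lemmatizer, abbreviations) {
  rows <- lapply(seq_len(nrow(corpus)), function(i) {
    sents <- if ("sentences" %in% names(corpus) && !is.null(corpus$sentences[[i]])) {
      corpus$sentences[[i]]
    } else {
      segment_sentences(corpus$text[[i]], abbreviations)
    }
    labels <- if ("sentence_labels" %in% names(corpus)) corpus$sentence_labels[[i]] else NULL
    if (!is.null(labels) && length(labels) != nrow(sents)) {
      abort(paste0("document ", corpus$doc_id[[i]], ": ", length(labels),
                   " sentence labels for ", nrow(sents), " sentences"))
    }
    tibble(doc_id = corpus$doc_id[[i]], text = sents$text,
           label = if (is.null(labels)) NA_character_ else as.character(labels))
  })
  bind_rows(rows)
}

#' Train the three-stage discharge-summary classifier
#'
#' @param corpus tibble with columns doc_id, text, and per-document
#'   `sentence_labels` (list column of labels among irrelevant, antecedent,
#'   active_mb, active_crnmb); an optional `sentences` list column (tibbles
#'   from [segment_sentences()]) overrides re-segmentation
#' @param seed integer seed controlling fold assignment
#' @param folds number of cross-validation folds
#' @param ngram_max,min_df vectorizer settings, see [build_vectorizer()]
#' @param lemmatizer optional token lemmatizer (`NULL` = identity)
#' @param lambda_grid ridge penalties tried for the logistic candidate
#' @param cost_grid costs tried for the linear SVM candidate
#' @param abbreviations segmentation abbreviation list
#' @return an `nlp_bundle`: vectorizer, three stage models, tuning record,
#'   seed and settings
#' @export
nlp_train <- function(corpus, seed = 1, folds = 5, ngram_max = 2, min_df = 2,
                      lemmatizer = NULL,
                      lambda_grid = c(0.1, 0.01, 0.001),
                      cost_grid = c(0.1, 1, 10),
                      abbreviations = nlp_abbreviations()) {
  sents <- corpus_sentence_table(corpus, lemmatizer, abbreviations)
  if (anyNA(sents$label)) abort("every training document needs sentence_labels")
  bad <- setdiff(unique(sents$label), SENTENCE_LABELS)
  if (length(bad) > 0) abort(paste0("unknown sentence label: ", bad[1]))

  toks <- tokenize_sentences(sents$text, lemmatizer)
  vec <- build_vectorizer(toks, ngram_max = ngram_max, min_df = min_df)
  x <- vectorize(vec, toks)

  y1 <- ifelse(sents$label == "irrelevant", "irrelevant", "relevant")
  y2 <- ifelse(sents$label %in% c("active_mb", "active_crnmb"), "active", sents$label)
  active <- sents$label %in% c("active_mb", "active_crnmb")

  withr::with_seed(seed, {
    s1 <- fit_stage(x, y1, "stage1 (relevant vs irrelevant)", folds, lambda_grid, cost_grid)
    s2 <- fit_stage(x, y2, "stage2 (irrelevant/antecedent/active)", folds, lambda_grid, cost_grid)
    s3 <- fit_stage(x[active, , drop = FALSE], sents$label[active],
                    "stage3 (MB vs CRNMB)", folds, lambda_grid, cost_grid)
  })

  tuning <- bind_rows(
    mutate(s1$grid, stage = "stage1"),
    mutate(s2$grid, stage = "stage2"),
    mutate(s3$grid, stage = "stage3")
  )
  structure(
    list(vectorizer = vec, lemmatizer = lemmatizer,
         stages = list(stage1 = s1, stage2 = s2, stage3 = s3),
         tuning_record = tuning, seed = seed,
         settings = list(folds = folds, ngram_max = ngram_max, min_df = min_df,
                         lambda_grid = lambda_grid, cost_grid = cost_grid,
                         abbreviations = abbreviations)),
    class = "nlp_bundle"
  )
}

#' @export
print.nlp_bundle <- function(x, ...) {
  cat("<nlp_bundle> vocab:", length(x$vectorizer$vocab), "n-grams; stages:\n")
  for (s in x$stages) {
    cat("  ", s$stage, "->", s$family, "(param", s$param, ")\n")
  }
  invisible(x)
}

#' Aggregate sentence labels into a document label
#'
#' Pure function of the multiset of sentence labels; priority
#' MB > CRNMB > history of bleeding > no bleeding.
#'
#' @param labels character vector of sentence labels
#' @return one of `"B_mb"`, `"A_crnmb"`, `"C_history"`, `"D_none"`
#' @export
aggregate_sentence_labels <- function(labels) {
  if (any(labels == "active_mb")) {
    "B_mb"
  } else if (any(labels == "active_crnmb")) {
    "A_crnmb"
  } else if (any(labels == "antecedent")) {
    "C_history"
  } else {
    "D_none"
  }
}

#' Classify one discharge summary
#'
#' Each sentence is routed stage1 -> stage2 -> stage3; a sentence judged
#' irrelevant at stage 1 or stage 2 stays irrelevant (stage 2 can veto
#' stage 1). Active sentences get an MB/CRNMB decision at stage 3.
#'
#' @param bundle trained `nlp_bundle`
#' @param text document text (ignored when `sentences` given)
#' @param sentences optional pre-segmented sentence tibble
#' @return list with `sentence_labels` and `doc_label`
#' @export
nlp_predict <- function(bundle, text = NULL, sentences = NULL) {
  stopifnot(inherits(bundle, "nlp_bundle"))
  if (is.null(sentences)) {
    sentences <- segment_sentences(text %||% "", bundle$settings$abbreviations)
  }
  if (nrow(sentences) == 0) {
    return(list(sentence_labels = character(), doc_label = "D_none"))
  }
  toks <- tokenize_sentences(sentences$text, bundle$lemmatizer)
  x <- vectorize(bundle$vectorizer, toks)
  out <- rep("irrelevant", nrow(sentences))
  rel <- predict_stage(bundle$stages$stage1, x) == "relevant"
  if (any(rel)) {
    s2 <- predict_stage(bundle$stages$stage2, x[rel, , drop = FALSE])
    out[rel][s2 == "antecedent"] <- "antecedent"
    act <- which(rel)[s2 == "active"]
    if (length(act) > 0) {
      s3 <- predict_stage(bundle$stages$stage3, x[act, , drop = FALSE])
      out[act] <- s3
    }
  }
  list(sentence_labels = out, doc_label = aggregate_sentence_labels(out))
}

#' Classify a corpus and emit per-document bleeding calls
#'
#' Document labels are mapped to detector labels: B_mb -> MB, A_crnmb ->
#' CRNMB, C_history -> history, D_none -> none.
#'
#' @param bundle trained `nlp_bundle`
#' @param corpus tibble with doc_id, text (and optional stay_id, sentences)
#' @return tibble: doc_id, stay_id, doc_label, label
#' @export
nlp_calls <- function(bundle, corpus) {
  map_label <- c(B_mb = "MB", A_crnmb = "CRNMB", C_history = "history", D_none = "none")
  preds <- lapply(seq_len(nrow(corpus)), function(i) {
    sents <- if ("sentences" %in% names(corpus)) corpus$sentences[[i]] else NULL
    nlp_predict(bundle, text = corpus$text[[i]], sentences = sents)
  })
  tibble(
    doc_id = as.character(corpus$doc_id),
    stay_id = if ("stay_id" %in% names(corpus)) as.character(corpus$stay_id) else as.character(corpus$doc_id),
    doc_label = map_chr(preds, "doc_label"),
    label = unname(map_label[map_chr(preds, "doc_label")])
  )
}

#' Stratified train/test split of an annotated corpus
#'
#' Deterministic under `seed`; the training set has `round(n * train_fraction)`
#' documents, allocated across document-label strata by largest remainder so
#' class proportions are preserved within one document.
#'
#' @param corpus corpus tibble (column `doc_label` used for stratification
#'   when present)
#' @param train_fraction fraction of documents assigned to training
#' @param seed integer seed
#' @return list with elements `train` and `test`
#' @export
split_corpus <- function(corpus, train_fraction = 0.7, seed = 1) {
  if (train_fraction <= 0 || train_fraction >= 1) abort("train_fraction must be in (0, 1)")
  n <- nrow(corpus)
  target <- round(n * train_fraction)
  strata <- if ("doc_label" %in% names(corpus) && !anyNA(corpus$doc_label)) {
    as.character(corpus$doc_label)
  } else {
    rep("all", n)
  }
  levels <- sort(unique(strata))
  quota <- vapply(levels, function(s) sum(strata == s) * train_fraction, numeric(1))
  take <- floor(quota)
  rem <- target - sum(take)
  if (rem > 0) {
    frac <- quota - take
    bump <- order(-frac, levels)[seq_len(rem)]
    take[bump] <- take[bump] + 1
  } else if (rem < 0) {
    frac <- quota - take
    cut <- order(frac, levels)[seq_len(-rem)]
    take[cut] <- take[cut] - 1
  }
  train_idx <- integer()
  withr::with_seed(seed, {
    for (k in seq_along(levels)) {
      idx <- which(strata == levels[k])
      train_idx <- c(train_idx, sample(idx, take[k]))
    }
  })
  train_idx <- sort(train_idx)
  list(train = corpus[train_idx, , drop = FALSE],
       test = corpus[setdiff(seq_len(n), train_idx), , drop = FALSE])
}

#' Save / load a trained classifier bundle
#'
#' @param bundle an `nlp_bundle`
#' @param path file path
#' @return `path` (save) or the restored bundle (load)
#' @export
nlp_save <- function(bundle, path) {
  stopifnot(inherits(bundle, "nlp_bundle"))
  saveRDS(bundle, path, version = 3)
  invisible(path)
}

#' @rdname nlp_save
#' @export
nlp_load <- function(path) {
  bundle <- readRDS(path)
  stopifnot(inherits(bundle, "nlp_bundle"))
  bundle
}

#' Read / write an annotated corpus as JSON lines
#'
#' One object per document: doc_id, stay_id, text, optional sentence_labels
#' and doc_label, optional sentences (start/end/text records).
#'
#' @param path file path
#' @return corpus tibble
#' @export
read_corpus <- function(path) {
  recs <- read_jsonl(path)
  tibble(
    doc_id = map_chr(recs, ~ as.character(.x$doc_id)),
    stay_id = map_chr(recs, ~ as.character(.x$stay_id %||% .x$doc_id)),
    text = map_chr(recs, ~ as.character(.x$text)),
    sentences = map(recs, function(r) {
      if (is.null(r$sentences)) NULL else as_tibble(r$sentences)
    }),
    sentence_labels = map(recs, ~ if (is.null(.x$sentence_labels)) NULL else as.character(.x$sentence_labels)),
    doc_label = map_chr(recs, ~ as.character(.x$doc_label %||% NA_character_))
  )
}

#' @rdname read_corpus
#' @param corpus corpus tibble
#' @export
write_corpus <- function(corpus, path) {
  recs <- lapply(seq_len(nrow(corpus)), function(i) {
    r <- list(doc_id = corpus$doc_id[[i]],
              stay_id = if ("stay_id" %in% names(corpus)) corpus$stay_id[[i]] else corpus$doc_id[[i]],
              text = corpus$text[[i]])
    if ("sentences" %in% names(corpus) && !is.null(corpus$sentences[[i]])) {
      r$sentences <- corpus$sentences[[i]]
    }
    if ("sentence_labels" %in% names(corpus) && !is.null(corpus$sentence_labels[[i]])) {
      r$sentence_labels <- corpus$sentence_labels[[i]]
    }
    if ("doc_label" %in% names(corpus) && !is.na(corpus$doc_label[[i]])) {
      r$doc_label <- corpus$doc_label[[i]]
    }
    r
  })
  write_jsonl(recs, path)
}
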