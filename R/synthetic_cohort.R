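# Seeded generator of synthetic eligible cohorts: structured tables with
# injected rule-qualifying events plus template discharge summaries with
# gold sentence/document labels. Every emitted stay passes the eligibility
# filter; each positive stay carries one injected qualifying event drawn
# from the criterion mix, and a configurable fraction of negatives sit just
# outside the rule boundaries (1.9 g/dL drops, 9.1 g/dL nadirs, exactly 5
# transfused units, codes absent from the bleeding lists).

MB_MIX_DEFAULT <- c(HB_DROP_GE4 = 1, HB_DROP_2TO4_DEATH24 = 1, HB_MIN_LT7 = 1,
                    HB_MIN_7TO9_DEATH24 = 1, TRANSFUSION_GT5 = 1,
                    ANTIHEMORRHAGIC_RX = 1, ICD_MB = 1)
CRNMB_MIX_DEFAULT <- c(HB_DROP_2TO4_NO_DEATH = 1, HB_MIN_7TO9_NO_DEATH = 1,
                       ICD_CRNMB = 1)

#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate the study conditions: prevalence near the reported
#' magnitudes (MB 8%, CRNMB 15%), all bleeding criteria represented, and a
#' quarter of the negatives built as boundary near-misses. `death_at_bound_fraction`
#' places that fraction of injected deaths at exactly the 24-hour horizon to
#' pin the inclusive boundary.
#'
#' @param n_stays number of stays
#' @param prevalence named fractions `c(MB=, CRNMB=)`; must sum to at most 1
#' @param mb_mix,crnmb_mix unnormalized weights over injected criteria
#' @param near_miss_fraction fraction of negative stays built at rule
#'   boundaries
#' @param death_at_bound_fraction fraction of injected deaths at exactly the
#'   death horizon
#' @param seed integer seed
#' @param template_set `"neutral"` or `"fr"` sentence templates
#' @return config list of class `bleedr_config`
#' @export
cohort_config <- function(n_stays = 1000,
                          prevalence = c(MB = 0.08, CRNMB = 0.15),
                          mb_mix = MB_MIX_DEFAULT,
                          crnmb_mix = CRNMB_MIX_DEFAULT,
                          near_miss_fraction = 0.25,
                          death_at_bound_fraction = 0.2,
                          seed = 1,
                          template_set = "neutral") {
  if (any(prevalence < 0) || sum(prevalence) > 1) {
    abort("prevalences must be nonnegative and sum to at most 1")
  }
  if (!setequal(names(prevalence), c("MB", "CRNMB"))) abort("prevalence must name MB and CRNMB")
  if (!all(names(mb_mix) %in% MB_CRITERIA)) abort("unknown MB criterion in mb_mix")
  if (!all(names(crnmb_mix) %in% CRNMB_CRITERIA)) abort("unknown CRNMB criterion in crnmb_mix")
  structure(
    list(n_stays = n_stays, prevalence = prevalence,
         mb_mix = mb_mix / sum(mb_mix), crnmb_mix = crnmb_mix / sum(crnmb_mix),
         near_miss_fraction = near_miss_fraction,
         death_at_bound_fraction = death_at_bound_fraction,
         seed = seed, template_set = template_set),
    class = "bleedr_config"
  )
}

trunc_norm <- function(n, mean, sd, lo, hi) {
  pmin(pmax(rnorm(n, mean, sd), lo), hi)
}

benign_series <- function() {
  k <- sample(3:10, 1)
  offsets <- cumsum(c(runif(1, 1, 6), runif(k - 1, 4, 24)))
  base <- trunc_norm(1, 13, 1, 10, 17)
  list(offset = offsets, value = base + runif(k, -0.4, 0.4))
}

ladder_series <- function(nadir, steps = 4) {
  # slow monotone descent: 0.9 g/dL per 24 h, so no 48-h pair drops >= 2
  offsets <- 6 + 24 * (0:steps)
  values <- nadir + 0.9 * (steps:0)
  list(offset = offsets, value = values)
}

ANTITHROMBOTIC_RX <- data.frame(
  atc = c("B01AA04", "B01AB05", "B01AC06", "B01AE07", "B01AF01", "B01AX05"),
  agent = c("phenprocoumon", "enoxaparin", "acetylsalicylic acid",
            "dabigatran etexilate", "rivaroxaban", "fondaparinux")
)

ANTIHEMORRHAGIC_RX <- data.frame(
  atc = c("V03AB37", "V03AB38", "B02BD01", "B02BD01", "B02BD01"),
  agent = c("Idarucizumab", "Andexanet alfa", "Prothromplex Total NF",
            "Octaplex 500", "Beriplex P/N 500")
)

MB_CODE_POOL <- c("H21.0", "H31.3", "H35.6", "H43.1", "I60.1", "I31.2",
                  "I61.0", "I62.9", "K66.1", "M25.04", "R57.1", "T81.1")
CRNMB_CODE_POOL <- c("H11.3", "K25.0", "K26.4", "K29.0", "K62.5", "K92.0",
                     "K92.1", "K92.2", "R04.0", "R31", "R58", "T81.0")
MISS_CODE_POOL <- c("K25.4", "K25.5", "I10", "E11.9", "M25.1", "J18.9")

inject_event <- function(criterion, at_bound) {
  out <- list(labs = NULL, death_offset = NA_real_, transfusion_units = NA_integer_,
              transfusion_product = NA_character_, agent = NA_character_,
              agent_atc = NA_character_, code = NA_character_)
  death_gap <- function() if (at_bound) 24 else runif(1, 0, 23.5)
  if (criterion == "HB_DROP_GE4") {
    v0 <- runif(1, 13.5, 15.5)
    drop <- 4 + runif(1, 0, 3)
    out$labs <- list(offset = c(6, 14, 38), value = c(v0, v0 - 0.1, v0 - drop))
  } else if (criterion == "HB_DROP_2TO4_DEATH24") {
    v0 <- runif(1, 14, 15.5)
    drop <- runif(1, 2.05, 3.9)
    out$labs <- list(offset = c(6, 42), value = c(v0, v0 - drop))
    out$death_offset <- 42 + death_gap()
  } else if (criterion == "HB_MIN_LT7") {
    out$labs <- ladder_series(runif(1, 5.05, 6.9))
  } else if (criterion == "HB_MIN_7TO9_DEATH24") {
    out$labs <- ladder_series(runif(1, 7.05, 8.95))
    out$death_offset <- max(out$labs$offset) + death_gap()
  } else if (criterion == "TRANSFUSION_GT5") {
    out$labs <- benign_series()
    out$transfusion_units <- sample(6:8, 1)
    out$transfusion_product <- sample(c("red_blood_cells", "whole_blood"), 1)
  } else if (criterion == "ANTIHEMORRHAGIC_RX") {
    out$labs <- benign_series()
    i <- sample(nrow(ANTIHEMORRHAGIC_RX), 1)
    out$agent <- ANTIHEMORRHAGIC_RX$agent[i]
    out$agent_atc <- ANTIHEMORRHAGIC_RX$atc[i]
  } else if (criterion == "ICD_MB") {
    out$labs <- benign_series()
    out$code <- sample(MB_CODE_POOL, 1)
  } else if (criterion == "HB_DROP_2TO4_NO_DEATH") {
    v0 <- runif(1, 14, 15.5)
    drop <- runif(1, 2.05, 3.9)
    out$labs <- list(offset = c(6, 42), value = c(v0, v0 - drop))
  } else if (criterion == "HB_MIN_7TO9_NO_DEATH") {
    lad <- ladder_series(runif(1, 7.05, 8.95))
    out$labs <- list(offset = c(lad$offset, max(lad$offset) + 24),
                     value = c(lad$value, min(lad$value) + 0.9))
  } else if (criterion == "ICD_CRNMB") {
    out$labs <- benign_series()
    out$code <- sample(CRNMB_CODE_POOL, 1)
  } else if (criterion == "NM_DROP_1.9") {
    out$labs <- list(offset = c(6, 18, 30, 42),
                     value = c(12.5, 12.45, 10.6, 10.6 + runif(1, 0, 0.04)))
  } else if (criterion == "NM_NADIR_9.1") {
    out$labs <- list(offset = c(6, 30, 54, 78),
                     value = c(11.0, 10.0, 9.1 + runif(1, 0, 0.05), 9.8))
  } else if (criterion == "NM_TRANSFUSION_5") {
    out$labs <- benign_series()
    out$transfusion_units <- 5L
    out$transfusion_product <- "red_blood_cells"
  } else if (criterion == "NM_CODE") {
    out$labs <- benign_series()
    out$code <- sample(MISS_CODE_POOL, 1)
  } else if (criterion == "BENIGN") {
    out$labs <- benign_series()
  } else {
    abort(paste0("unknown injection criterion: ", criterion))
  }
  out
}

#' Generate a synthetic structured cohort with ground truth
#'
#' Every stay is eligible by construction (age 65+, one antithrombotic
#' prescription, stay of at least 24 hours). MB- and CRNMB-truth stays each
#' receive one injected qualifying event sampled from the configured
#' criterion mix; negatives get benign hemoglobin series, a configured
#' fraction of them built at the rule boundaries. Fully deterministic under
#' the config seed.
#'
#' @param config from [cohort_config()]
#' @return list: `cohort` (a `bleed_cohort`) and `truth` (tibble stay_id,
#'   label, injected_criterion)
#' @export
simulate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "bleedr_config"))
  n <- config$n_stays
  empty <- function() {
    tibble(stay_id = character(), label = character(), injected_criterion = character())
  }
  if (n == 0) {
    co <- cohort(tibble(stay_id = character(), patient_id = character(),
                        admission_ts = character(), discharge_ts = character(),
                        death_ts = character(), age_years = integer(),
                        sex = character(), hospital_id = character()))
    return(list(cohort = co, truth = empty()))
  }
  withr::with_seed(config$seed, {
    n_mb <- round(n * config$prevalence[["MB"]])
    n_crnmb <- round(n * config$prevalence[["CRNMB"]])
    n_neg <- n - n_mb - n_crnmb
    n_nm <- round(n_neg * config$near_miss_fraction)
    labels <- sample(c(rep("MB", n_mb), rep("CRNMB", n_crnmb), rep("none", n_neg)))
    criteria <- character(n)
    criteria[labels == "MB"] <- sample(names(config$mb_mix), n_mb, replace = TRUE,
                                       prob = config$mb_mix)
    criteria[labels == "CRNMB"] <- sample(names(config$crnmb_mix), n_crnmb,
                                          replace = TRUE, prob = config$crnmb_mix)
    neg_idx <- which(labels == "none")
    nm_idx <- if (n_nm > 0) sample(neg_idx, n_nm) else integer()
    criteria[neg_idx] <- "BENIGN"
    nm_pool <- c("NM_DROP_1.9", "NM_NADIR_9.1", "NM_TRANSFUSION_5", "NM_CODE")
    if (length(nm_idx) > 0) {
      criteria[nm_idx] <- sample(nm_pool, length(nm_idx), replace = TRUE)
    }

    t0 <- as.POSIXct("2015-01-01 00:00:00", tz = "UTC")
    ids <- sprintf("S%05d", seq_len(n))
    stays <- list(); labs <- list(); tfs <- list(); rxs <- list(); dxs <- list()
    for (i in seq_len(n)) {
      at_bound <- runif(1) < config$death_at_bound_fraction
      ev <- inject_event(criteria[i], at_bound)
      admission <- t0 + round(runif(1, 0, 700) * 86400)
      last_lab <- max(ev$labs$offset)
      if (!is.na(ev$death_offset)) {
        discharge_off <- ev$death_offset
      } else {
        discharge_off <- max(last_lab + runif(1, 12, 48), 24.5)
      }
      stays[[i]] <- tibble(
        stay_id = ids[i], patient_id = paste0("P", ids[i]),
        admission_ts = admission,
        discharge_ts = admission + discharge_off * 3600,
        death_ts = if (is.na(ev$death_offset)) as.POSIXct(NA) else admission + ev$death_offset * 3600,
        age_years = sample(65:95, 1),
        sex = sample(c("male", "female"), 1),
        hospital_id = "SYNTH1"
      )
      labs[[i]] <- tibble(stay_id = ids[i], analyte = "hemoglobin",
                          value = round(ev$labs$value, 2),
                          ts = admission + ev$labs$offset * 3600)
      j <- sample(nrow(ANTITHROMBOTIC_RX), 1)
      rx <- tibble(stay_id = ids[i], atc_code = ANTITHROMBOTIC_RX$atc[j],
                   agent_name = ANTITHROMBOTIC_RX$agent[j],
                   ts = admission + runif(1, 1, 12) * 3600)
      if (!is.na(ev$agent)) {
        rx <- bind_rows(rx, tibble(stay_id = ids[i], atc_code = ev$agent_atc,
                                   agent_name = ev$agent,
                                   ts = admission + runif(1, 6, 20) * 3600))
      }
      rxs[[i]] <- rx
      if (!is.na(ev$transfusion_units)) {
        tfs[[i]] <- tibble(stay_id = ids[i], product = ev$transfusion_product,
                           units = ev$transfusion_units,
                           ts = admission + runif(1, 6, 20) * 3600)
      }
      if (!is.na(ev$code)) {
        dxs[[i]] <- tibble(stay_id = ids[i], icd10gm_code = ev$code,
                           present_on_admission = runif(1) < 0.5)
      }
    }
    co <- cohort(bind_rows(stays), bind_rows(labs),
                 if (length(tfs) > 0) bind_rows(tfs) else NULL,
                 bind_rows(rxs),
                 if (length(dxs) > 0) bind_rows(dxs) else NULL)
    truth <- tibble(stay_id = ids, label = labels, injected_criterion = criteria)
  })
  list(cohort = co, truth = truth)
}

load_templates <- function(template_set = "neutral") {
  path <- system.file("extdata", "sentence_templates.csv", package = "bleedr")
  tpl <- readr::read_csv(path, col_types = "cccc", progress = FALSE)
  tpl <- tpl[tpl$set == template_set, , drop = FALSE]
  if (nrow(tpl) == 0) abort(paste0("unknown template set: ", template_set))
  need <- c("active_mb", "active_crnmb", "antecedent", "irrelevant")
  miss <- setdiff(need, unique(tpl$label))
  if (length(miss) > 0) {
    abort(paste0("template set '", template_set, "' lacks label(s): ",
                 paste(miss, collapse = ", ")))
  }
  tpl
}

pick_template <- function(tpl, label, n = 1) {
  pool <- tpl[tpl$label == label, , drop = FALSE]
  pool$text[sample.int(nrow(pool), n, replace = TRUE)]
}

build_document <- function(doc_label, tpl) {
  plain <- tpl[tpl$label == "irrelevant" & tpl$kind == "plain", , drop = FALSE]
  neg <- tpl[tpl$label == "irrelevant" & tpl$kind == "negation", , drop = FALSE]
  k <- sample(2:5, 1)
  sents <- plain$text[sample.int(nrow(plain), k, replace = TRUE)]
  labels <- rep("irrelevant", k)
  if (nrow(neg) > 0 && runif(1) < 0.3) {
    sents <- c(sents, neg$text[sample.int(nrow(neg), 1)])
    labels <- c(labels, "irrelevant")
  }
  add <- function(lab, n) {
    sents <<- c(sents, pick_template(tpl, lab, n))
    labels <<- c(labels, rep(lab, n))
  }
  if (doc_label == "B_mb") {
    add("active_mb", sample(1:2, 1))
    if (runif(1) < 0.3) add("active_crnmb", 1)
    if (runif(1) < 0.3) add("antecedent", 1)
  } else if (doc_label == "A_crnmb") {
    add("active_crnmb", sample(1:2, 1))
    if (runif(1) < 0.3) add("antecedent", 1)
  } else if (doc_label == "C_history") {
    add("antecedent", sample(1:2, 1))
  }
  ord <- sample(seq_along(sents))
  sents <- sents[ord]
  labels <- labels[ord]
  text <- paste(sents, collapse = " ")
  ends <- cumsum(nchar(sents) + 1) - 1
  starts <- ends - nchar(sents) + 1
  list(text = text,
       sentences = tibble(start = starts, end = ends, text = sents),
       sentence_labels = labels)
}

#' Generate a synthetic annotated discharge-summary corpus
#'
#' Documents are built from label-keyed sentence templates plus irrelevant
#' filler (including hard-negative negated bleeding mentions), so the
#' resulting corpus is separable by construction. The emitted document label
#' always equals the priority aggregation of the emitted sentence labels.
#'
#' @param n_docs number of documents (ignored when `doc_label_mix` holds
#'   counts)
#' @param doc_label_mix named counts or fractions over `A_crnmb`, `B_mb`,
#'   `C_history`, `D_none`; counts are used exactly
#' @param seed integer seed
#' @param template_set `"neutral"` or `"fr"`
#' @param stay_ids optional stay ids to attach (length = number of docs)
#' @return corpus tibble: doc_id, stay_id, text, sentences, sentence_labels,
#'   doc_label
#' @export
simulate_corpus <- function(n_docs = 400,
                            doc_label_mix = c(A_crnmb = 100, B_mb = 100,
                                              C_history = 0, D_none = 200),
                            seed = 1, template_set = "neutral",
                            stay_ids = NULL) {
  bad <- setdiff(names(doc_label_mix), DOC_LABELS)
  if (length(bad) > 0) abort(paste0("unknown doc label in mix: ", bad[1]))
  mix <- setNames(rep(0, length(DOC_LABELS)), DOC_LABELS)
  mix[names(doc_label_mix)] <- doc_label_mix
  counts <- if (sum(mix) > 1 + 1e-9 && all(abs(mix - round(mix)) < 1e-9)) {
    as.integer(round(mix))
  } else {
    if (abs(sum(mix) - 1) > 1e-9) abort("doc_label_mix fractions must sum to 1")
    cnt <- floor(mix * n_docs)
    left <- n_docs - sum(cnt)
    if (left > 0) {
      bump <- order(-(mix * n_docs - cnt))[seq_len(left)]
      cnt[bump] <- cnt[bump] + 1
    }
    as.integer(cnt)
  }
  n <- sum(counts)
  tpl <- load_templates(template_set)
  withr::with_seed(seed, {
    doc_labels <- sample(rep(DOC_LABELS, counts))
    docs <- lapply(doc_labels, build_document, tpl = tpl)
  })
  ids <- sprintf("D%05d", seq_len(n))
  tibble(
    doc_id = ids,
    stay_id = if (is.null(stay_ids)) ids else as.character(stay_ids),
    text = map_chr(docs, "text"),
    sentences = map(docs, "sentences"),
    sentence_labels = map(docs, "sentence_labels"),
    doc_label = doc_labels
  )
}

#' Generate discharge summaries aligned to a structured ground truth
#'
#' One document per stay: MB stays get `B_mb` documents, CRNMB stays
#' `A_crnmb`; a configurable fraction of non-bleeding stays get
#' history-of-bleeding documents (`C_history`), the rest `D_none`.
#'
#' @param truth truth tibble from [simulate_cohort()]
#' @param seed integer seed
#' @param template_set `"neutral"` or `"fr"`
#' @param history_fraction fraction of non-bleeding stays documented with a
#'   bleeding history
#' @return corpus tibble keyed by stay_id
#' @export
simulate_documents <- function(truth, seed = 1, template_set = "neutral",
                               history_fraction = 0.1) {
  tpl <- load_templates(template_set)
  n <- nrow(truth)
  withr::with_seed(seed, {
    doc_labels <- dplyr::case_when(
      truth$label == "MB" ~ "B_mb",
      truth$label == "CRNMB" ~ "A_crnmb",
      TRUE ~ "D_none"
    )
    none_idx <- which(doc_labels == "D_none")
    n_hist <- round(length(none_idx) * history_fraction)
    if (n_hist > 0) doc_labels[sample(none_idx, n_hist)] <- "C_history"
    docs <- lapply(doc_labels, build_document, tpl = tpl)
  })
  tibble(
    doc_id = paste0("DOC-", truth$stay_id),
    stay_id = truth$stay_id,
    text = map_chr(docs, "text"),
    sentences = map(docs, "sentences"),
    sentence_labels = map(docs, "sentence_labels"),
    doc_label = doc_labels
  )
}
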