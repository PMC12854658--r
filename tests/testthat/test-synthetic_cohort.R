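test_that("generation is deterministic and respects configured sizes", {
  cfg <- cohort_config(n_stays = 120, seed = 17)
  s1 <- simulate_cohort(cfg)
  s2 <- simulate_cohort(cfg)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$cohort$labs, s2$cohort$labs)
  expect_identical(s1$cohort$stays, s2$cohort$stays)
  expect_equal(nrow(s1$cohort$stays), 120)
  expect_equal(sum(s1$truth$label == "MB"), round(120 * 0.08))
  expect_equal(sum(s1$truth$label == "CRNMB"), round(120 * 0.15))
  s3 <- simulate_cohort(cohort_config(n_stays = 120, seed = 18))
  expect_false(identical(s1$cohort$labs, s3$cohort$labs))
  empty <- simulate_cohort(cohort_config(n_stays = 0, seed = 1))
  expect_equal(nrow(empty$cohort$stays), 0)
  expect_equal(nrow(empty$truth), 0)
  expect_error(cohort_config(prevalence = c(MB = 0.7, CRNMB = 0.5)), "sum")
})

test_that("every generated stay passes the eligibility filter", {
  sim <- simulate_cohort(cohort_config(n_stays = 200, seed = 23))
  eligible <- filter_eligible(sim$cohort)
  expect_equal(nrow(eligible$stays), 200)
})

test_that("rule engine recovers generator truth perfectly; near-misses never fire", {
  sim <- simulate_cohort(cohort_config(n_stays = 400, seed = 29))
  calls <- detect_sda(sim$cohort)
  merged <- dplyr::inner_join(calls, sim$truth, by = "stay_id",
                              suffix = c("_call", "_truth"))
  expect_equal(merged$label_call, merged$label_truth)
  near <- merged[startsWith(merged$injected_criterion, "NM_"), ]
  expect_gt(nrow(near), 0)
  expect_true(all(lengths(near$criteria_fired) == 0))
  # the intended criterion fires on every injected positive
  pos <- merged[merged$label_truth != "none", ]
  hit <- purrr::map2_lgl(pos$criteria_fired, pos$injected_criterion, ~ .y %in% .x)
  expect_true(all(hit))
})

test_that("death-linked injections respect the inclusive 24-hour boundary", {
  cfg <- cohort_config(n_stays = 300, seed = 31,
                       mb_mix = c(HB_DROP_2TO4_DEATH24 = 1, HB_MIN_7TO9_DEATH24 = 1),
                       death_at_bound_fraction = 1) # all deaths at exactly +24 h
  sim <- simulate_cohort(cfg)
  calls <- detect_sda(sim$cohort)
  merged <- dplyr::inner_join(calls, sim$truth, by = "stay_id",
                              suffix = c("_call", "_truth"))
  expect_equal(merged$label_call, merged$label_truth)
  expect_true(all(merged$mb_mortality[merged$label_truth == "MB"]))
})

test_that("emitted document labels equal priority aggregation of sentence labels", {
  corpus <- simulate_corpus(n_docs = 400, seed = 37,
                            doc_label_mix = c(A_crnmb = 100, B_mb = 100,
                                              C_history = 50, D_none = 150))
  expect_equal(as.vector(table(corpus$doc_label)[c("A_crnmb", "B_mb", "C_history", "D_none")]),
               c(100L, 100L, 50L, 150L))
  agg <- vapply(corpus$sentence_labels, aggregate_sentence_labels, character(1))
  expect_equal(agg, corpus$doc_label)
  # sentence spans tile the document text
  for (i in c(1, 57, 200)) {
    sp <- corpus$sentences[[i]]
    expect_equal(substr(corpus$text[[i]], sp$start[1], sp$end[1]), sp$text[1])
    expect_true(all(diff(sp$start) > 0))
  }
  c2 <- simulate_corpus(n_docs = 50, seed = 41)
  c3 <- simulate_corpus(n_docs = 50, seed = 41)
  expect_identical(c2, c3)
  expect_error(simulate_corpus(doc_label_mix = c(bogus = 1)), "unknown doc label")
})

test_that("truth-aligned documents track stay labels with optional history", {
  sim <- simulate_cohort(cohort_config(n_stays = 100, seed = 43))
  docs <- simulate_documents(sim$truth, seed = 44, history_fraction = 0.2)
  expect_equal(docs$stay_id, sim$truth$stay_id)
  expect_true(all(docs$doc_label[sim$truth$label == "MB"] == "B_mb"))
  expect_true(all(docs$doc_label[sim$truth$label == "CRNMB"] == "A_crnmb"))
  none <- docs$doc_label[sim$truth$label == "none"]
  expect_true(all(none %in% c("C_history", "D_none")))
  expect_equal(sum(none == "C_history"), round(sum(sim$truth$label == "none") * 0.2))
  # none-truth documents carry no active-bleeding sentences
  none_docs <- docs[sim$truth$label == "none", ]
  expect_false(any(unlist(none_docs$sentence_labels) %in% c("active_mb", "active_crnmb")))
})

test_that("the French-like template set works end to end", {
  corpus <- simulate_corpus(n_docs = 60, seed = 47, template_set = "fr",
                            doc_label_mix = c(A_crnmb = 15, B_mb = 15,
                                              C_history = 10, D_none = 20))
  agg <- vapply(corpus$sentence_labels, aggregate_sentence_labels, character(1))
  expect_equal(agg, corpus$doc_label)
  expect_error(bleedr:::load_templates("martian"), "unknown template set")
})
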