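test_that("binarization handles the three scenarios and conserves stays", {
  gold <- tibble::tibble(stay_id = c("a", "b", "c"), label = c("MB", "CRNMB", "none"))
  calls <- gold
  mb <- binarize_calls(calls, gold, "mb_vs_rest")
  expect_equal(unlist(mb[c("tp", "fp", "tn", "fn")]), c(tp = 1, fp = 0, tn = 2, fn = 0))
  cr <- binarize_calls(calls, gold, "crnmb_vs_none")
  expect_equal(cr$n_evaluated, 2) # gold MB stay excluded
  expect_equal(cr$n_excluded, 1)
  expect_equal(cr$n_evaluated + cr$n_excluded, nrow(gold))
  allb <- binarize_calls(calls, gold, "all_bleeding")
  expect_equal(allb$tp, 2)
  none <- tibble::tibble(stay_id = paste0("s", 1:5), label = "none")
  mb5 <- binarize_calls(none, tibble::tibble(stay_id = paste0("s", 1:5), label = "MB"),
                        "mb_vs_rest")
  expect_equal(mb5$fn, 5)
  hist <- tibble::tibble(stay_id = c("a", "b", "c"), label = c("history", "CRNMB", "none"))
  expect_equal(binarize_calls(hist, gold, "all_bleeding")$fn, 1) # history is negative
  expect_error(binarize_calls(calls[1:2, ], gold, "all_bleeding"), "same stays")
})

test_that("metrics match their defining formulas, with undefined cells as NA", {
  perfect <- detection_metrics(list(tp = 1, fp = 0, tn = 1, fn = 0))
  expect_equal(perfect$estimate[perfect$metric != "f1"], rep(1, 5))
  m <- detection_metrics(list(tp = 232, fp = 223, tn = 180, fn = 44))
  sens <- m$estimate[m$metric == "sensitivity"]
  ppv <- m$estimate[m$metric == "ppv"]
  expect_equal(m$estimate[m$metric == "f1"], 2 * ppv * sens / (ppv + sens))
  expect_equal(2 * 0.84 * 0.51 / (0.84 + 0.51), 0.635, tolerance = 1e-3) # harmonic mean
  acc <- m$estimate[m$metric == "accuracy"]
  n <- 232 + 223 + 180 + 44
  spec <- m$estimate[m$metric == "specificity"]
  expect_equal(acc, (sens * (232 + 44) + spec * (223 + 180)) / n)
  deg <- detection_metrics(list(tp = 0, fp = 0, tn = 10, fn = 5))
  expect_true(is.na(deg$estimate[deg$metric == "ppv"]))
  expect_equal(deg$note[deg$metric == "ppv"], "no positive calls")
  expect_equal(deg$estimate[deg$metric == "sensitivity"], 0)
})

test_that("wilson_ci matches the independent score-interval oracle", {
  expect_equal(wilson_ci(0, 10)[["low"]], 0)
  expect_equal(wilson_ci(10, 10)[["high"]], 1)
  got <- wilson_ci(232, 276)
  expect_equal(round(got[["low"]], 3), 0.793)
  expect_equal(round(got[["high"]], 3), 0.879)
  withr::with_seed(77, {
    for (rep in 1:50) {
      n <- sample(1:500, 1)
      x <- sample(0:n, 1)
      got <- wilson_ci(x, n)
      want <- stats::prop.test(x, n, correct = FALSE)$conf.int
      expect_equal(got[["low"]], want[1], tolerance = 1e-12)
      expect_equal(got[["high"]], want[2], tolerance = 1e-12)
      p <- x / n
      expect_true(got[["low"]] <= p + 1e-12 && p <= got[["high"]] + 1e-12)
    }
  })
  # width shrinks with trials at fixed proportion
  widths <- vapply(c(10, 40, 160, 640), function(n) {
    ci <- wilson_ci(round(0.3 * n), n)
    ci[["high"]] - ci[["low"]]
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
  expect_error(wilson_ci(5, 0), "trials")
})

test_that("fleiss_kappa matches hand computation and the agreement bands", {
  all_agree <- matrix(rep(c("yes", "no"), each = 3), nrow = 2, byrow = TRUE)
  fl <- fleiss_kappa(rbind(all_agree, all_agree))
  expect_equal(fl$kappa, 1)
  expect_equal(fl$band, "almost perfect")
  # 4 items x 3 raters, 2 categories; hand-computed: Pbar = 2/3, Pe = 1/2,
  # kappa = (2/3 - 1/2) / (1 - 1/2) = 1/3
  m <- rbind(c("A", "A", "A"),
             c("A", "A", "B"),
             c("B", "B", "B"),
             c("A", "B", "B"))
  fl <- fleiss_kappa(m)
  expect_equal(fl$kappa, 1 / 3, tolerance = 1e-12)
  expect_equal(fl$p_observed, 2 / 3, tolerance = 1e-12)
  expect_equal(fl$p_expected, 1 / 2, tolerance = 1e-12)
  expect_equal(kappa_band(0.65), "substantial")
  expect_equal(kappa_band(0.61), "substantial")
  expect_equal(kappa_band(0.15), "slight")
  expect_equal(kappa_band(-0.2), "poor")
  expect_error(fleiss_kappa(m[1, , drop = FALSE]), "at least 2")
  m_na <- m; m_na[2, 2] <- NA
  expect_error(fleiss_kappa(m_na), "missing")
})

test_that("fleiss_kappa is near zero under random label permutation", {
  withr::with_seed(101, {
    base <- matrix(sample(c("A", "B"), 1000 * 3, replace = TRUE), ncol = 3)
    kappas <- vapply(1:200, function(i) {
      fleiss_kappa(matrix(sample(base), ncol = 3))$kappa
    }, numeric(1))
    expect_lt(max(abs(kappas)), 0.1)
    expect_lt(abs(mean(kappas)), 0.01)
  })
})

test_that("source contribution counts overlap correctly", {
  calls <- tibble::tibble(
    stay_id = c("a", "b", "c", "d"),
    label = c("MB", "MB", "MB", "none"),
    sources_fired = list("laboratory", c("laboratory", "icd"), "icd", character())
  )
  sc <- source_contribution(calls, "MB")
  expect_equal(sc$per_source$n[sc$per_source$source == "laboratory"], 2L)
  expect_equal(sc$per_source$n[sc$per_source$source == "icd"], 2L)
  expect_equal(sc$overlap$n[sc$overlap$n_sources == 1], 2L)
  expect_equal(sc$overlap$n[sc$overlap$n_sources == 2], 1L)
  expect_equal(sum(sc$overlap$n), sc$n_positive)
  expect_equal(source_contribution(calls[4, ], "MB")$n_positive, 0L)
  withr::with_seed(8, {
    sim <- simulate_cohort(cohort_config(n_stays = 150, seed = 12))
    calls <- detect_sda(sim$cohort)
    for (sev in c("MB", "CRNMB")) {
      sc <- source_contribution(calls, sev)
      expect_equal(sum(sc$overlap$n), sc$n_positive) # conservation
    }
  })
})
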