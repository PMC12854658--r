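test_that("max_hb_drop handles the documented example series", {
  expect_equal(max_hb_drop(mk_labs(c(0, 24), c(14, 9.5)))$drop, 4.5)
  expect_null(max_hb_drop(mk_labs(c(0, 60), c(12, 7.5)))) # only pair spans 60 h
  got <- max_hb_drop(mk_labs(c(0, 24, 48), c(10, 12, 9)))
  expect_equal(got$drop, 3)
  expect_equal(got$start_value, 12)
  expect_null(max_hb_drop(mk_labs(0, 12)))   # a single value supports no drop
  expect_null(max_hb_drop(mk_labs(c(0, 10), c(9, 11)))) # rising series
  expect_error(max_hb_drop(tibble::tibble(ts = c(5, 1), value = c(10, 9))), "sorted")
})

test_that("max_hb_drop equals the all-pairs brute force on random series", {
  withr::with_seed(42, {
    for (rep in 1:300) {
      n <- sample(2:60, 1)
      hours <- sort(runif(n, 0, 200))
      values <- round(runif(n, 6, 16), 2)
      labs <- tibble::tibble(ts = hours, value = values)
      got <- max_hb_drop(labs)
      want <- brute_max_drop(hours, values)
      if (is.null(want)) {
        expect_null(got)
      } else {
        expect_equal(got$drop, want$drop)
        expect_equal(got$end_ts, want$end)
        expect_equal(got$start_ts, want$start)
      }
    }
  })
})

test_that("min_hb returns the earliest-timestamp nadir", {
  expect_equal(min_hb(mk_labs(c(0, 12), c(9.1, 6.8)))$value, 6.8)
  expect_null(min_hb(mk_labs(numeric(), numeric())))
  tie <- min_hb(mk_labs(c(0, 10), c(8, 8)))
  expect_equal(tie$ts, hrs(0))
})

test_that("death_within uses an inclusive 24-h bound", {
  expect_true(death_within(hrs(0), hrs(12)))
  expect_false(death_within(hrs(0), hrs(25)))
  expect_true(death_within(hrs(0), hrs(24)))   # exactly at the horizon
  expect_false(death_within(hrs(10), hrs(5)))  # death before the anchor
  expect_false(death_within(hrs(0), as.POSIXct(NA)))
})

test_that("transfusion totals count blood and red cells, not plasma", {
  tf <- function(product, units) tibble::tibble(product = product, units = units)
  expect_equal(transfusion_total(tf(c("red_blood_cells", "red_blood_cells"), c(3, 3))), 6L)
  expect_equal(transfusion_total(tf("plasma", 8)), 0L)
  expect_equal(transfusion_total(tf(c("whole_blood", "plasma"), c(4, 4))), 4L)
})

test_that("antihemorrhagic matching is word-boundary tolerant", {
  rx <- function(x) tibble::tibble(agent_name = tolower(x))
  expect_true(antihemorrhagic_hit(rx("Idarucizumab")))
  expect_true(antihemorrhagic_hit(rx("Beriplex P/N 500")))
  expect_true(antihemorrhagic_hit(rx("andexanet alfa 200 mg")))
  expect_false(antihemorrhagic_hit(rx("enoxaparin")))
  expect_false(antihemorrhagic_hit(rx("octaplexin"))) # no partial-word hit
})

test_that("classify_stay reproduces the documented rule outcomes", {
  lab <- function(...) classify_stay(mk_bundle(...))
  expect_equal(lab(labs_hours = 10, labs_values = 6.8)$label, "MB")
  expect_equal(lab(c(0, 36), c(13, 10))$label, "CRNMB")          # 3 g/dL drop, no death
  expect_equal(lab(c(0, 36), c(13, 10), death_hour = 48)$label, "MB") # death 12 h after drop end
  expect_equal(lab(codes = "K92.2")$label, "CRNMB")
  mb_prec <- lab(c(0, 36), c(13, 10.5), codes = "I61.0")
  expect_equal(mb_prec$label, "MB") # MB precedence over a CRNMB-band drop
  expect_equal(lab()$label, "none")
  expect_true("ICD_MB" %in% mb_prec$criteria_fired[[1]])
})

test_that("rule boundaries map deterministically to the documented labels", {
  drop_label <- function(drop, death = NA) {
    classify_stay(mk_bundle(c(0, 36), c(14, 14 - drop), death_hour = death))$label
  }
  expect_equal(drop_label(1.99), "none")
  expect_equal(drop_label(2.00), "CRNMB")
  expect_equal(drop_label(3.99), "CRNMB")
  expect_equal(drop_label(4.00), "MB")
  expect_equal(drop_label(2.00, death = 60), "MB")   # death exactly 24 h after end
  expect_equal(drop_label(2.00, death = 60.1), "CRNMB")
  expect_equal(drop_label(3.99, death = 50), "MB")

  nadir_label <- function(v, death = NA) {
    classify_stay(mk_bundle(10, v, death_hour = death))$label
  }
  expect_equal(nadir_label(6.99), "MB")
  expect_equal(nadir_label(7.00), "CRNMB")
  expect_equal(nadir_label(9.00), "CRNMB")
  expect_equal(nadir_label(9.01), "none")
  expect_equal(nadir_label(7.00, death = 34), "MB")  # death 24 h after nadir
  expect_equal(nadir_label(9.00, death = 34), "MB")
  expect_equal(nadir_label(9.00, death = 34.1), "CRNMB")

  tr_label <- function(u) {
    classify_stay(mk_bundle(transfusions = list(product = "red_blood_cells",
                                                units = u, hour = 12)))$label
  }
  expect_equal(tr_label(5L), "none") # strictly more than 5 units
  expect_equal(tr_label(6L), "MB")
})

test_that("labels partition stays and MB-qualifying events never lower severity", {
  base <- mk_bundle(c(0, 36), c(13, 10.5)) # CRNMB drop
  expect_equal(classify_stay(base)$label, "CRNMB")
  base$diagnoses <- tibble::tibble(stay_id = "S1", icd10gm_code = "I61.0",
                                   present_on_admission = NA)
  expect_equal(classify_stay(base)$label, "MB")
  withr::with_seed(9, {
    sim <- simulate_cohort(cohort_config(n_stays = 60, seed = 21))
    calls <- detect_sda(sim$cohort)
    expect_true(all(calls$label %in% c("MB", "CRNMB", "none")))
    # exactly one label per stay, by construction of the call tibble
    expect_equal(nrow(calls), dplyr::n_distinct(calls$stay_id))
    # adding an MB diagnosis makes every stay MB
    co2 <- sim$cohort
    co2$diagnoses <- dplyr::bind_rows(
      co2$diagnoses,
      tibble::tibble(stay_id = co2$stays$stay_id, icd10gm_code = "I61.0",
                     present_on_admission = NA)
    )
    calls2 <- detect_sda(co2)
    expect_true(all(calls2$label == "MB"))
  })
})

test_that("source attribution follows the label's severity tier", {
  # ICD CRNMB hit inside an MB-labelled stay stays out of sources_fired
  b <- mk_bundle(labs_hours = 10, labs_values = 6.5, codes = "K92.1")
  call <- classify_stay(b)
  expect_equal(call$label, "MB")
  expect_setequal(call$sources_fired[[1]], "laboratory")
  expect_true("ICD_CRNMB" %in% call$criteria_fired[[1]])
  # medication + transfusion attribution
  b2 <- mk_bundle(agents = "idarucizumab",
                  transfusions = list(product = "whole_blood", units = 7L, hour = 5))
  call2 <- classify_stay(b2)
  expect_setequal(call2$sources_fired[[1]], c("transfusion", "medication"))
})

test_that("mb_mortality marks MB stays with in-hospital death", {
  expect_true(classify_stay(mk_bundle(10, 6.5, death_hour = 200,
                                      discharge_hour = 200))$mb_mortality)
  expect_false(classify_stay(mk_bundle(10, 6.5))$mb_mortality)
  expect_false(classify_stay(mk_bundle(10, 12, death_hour = 30,
                                       discharge_hour = 30))$mb_mortality)
})

test_that("cohort_prevalence reproduces count-to-percentage arithmetic", {
  tab <- cohort_prevalence(
    counts = c(none = 27641, CRNMB = 5419, MB = 2979, mb_mortality = 350),
    denominator = 36039
  )
  expect_equal(tab$pct_rounded[tab$category == "CRNMB"], 15.04)
  expect_equal(tab$pct_rounded[tab$category == "none"], 76.70)
  expect_equal(round_half_away(tab$pct[tab$category == "MB in-hospital mortality"], 1), 1.0)
  zero <- cohort_prevalence(counts = c(none = 10, CRNMB = 0, MB = 0, mb_mortality = 0),
                            denominator = 10)
  expect_equal(zero$pct_rounded, c(100, 0, 0, 0))
  small <- cohort_prevalence(counts = c(none = 1, CRNMB = 1, MB = 2, mb_mortality = 1),
                             denominator = 4)
  expect_equal(small$pct_rounded[small$category == "MB"], 50.00)
  expect_error(
    cohort_prevalence(counts = c(none = 1, CRNMB = 1, MB = 1, mb_mortality = 0),
                      denominator = 4),
    "sum"
  )
})
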