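# Fixture builders shared across test files. Times are expressed as hours
# after a fixed admission instant so rule boundaries are easy to read.

TS0 <- as.POSIXct("2015-03-01 00:00:00", tz = "UTC")
hrs <- function(h) TS0 + h * 3600

mk_labs <- function(hours, values, stay = "S1") {
  tibble::tibble(stay_id = stay, analyte = "hemoglobin",
                 value = values, ts = hrs(hours))
}

# A single-stay bundle in the shape classify_stay() expects.
mk_bundle <- function(labs_hours = numeric(), labs_values = numeric(),
                      death_hour = NA_real_,
                      transfusions = NULL, agents = character(),
                      codes = character(), stay = "S1",
                      discharge_hour = NULL) {
  last <- if (length(labs_hours) > 0) max(labs_hours) else 0
  if (is.null(discharge_hour)) {
    discharge_hour <- max(last + 24, if (is.na(death_hour)) 48 else death_hour)
  }
  stay_tab <- tibble::tibble(
    stay_id = stay, patient_id = paste0("P", stay),
    admission_ts = TS0, discharge_ts = hrs(discharge_hour),
    death_ts = if (is.na(death_hour)) as.POSIXct(NA) else hrs(death_hour),
    age_years = 80L, sex = "female", hospital_id = "T1"
  )
  tf <- if (is.null(transfusions)) {
    tibble::tibble(stay_id = character(), product = character(),
                   units = integer(), ts = hrs(numeric()))
  } else {
    tibble::tibble(stay_id = stay, product = transfusions$product,
                   units = transfusions$units, ts = hrs(transfusions$hour))
  }
  rx <- tibble::tibble(stay_id = rep(stay, length(agents)),
                       atc_code = rep("", length(agents)),
                       agent_name = tolower(agents),
                       ts = hrs(rep(2, length(agents))))
  dx <- tibble::tibble(stay_id = rep(stay, length(codes)),
                       icd10gm_code = vapply(codes, bleedr::icd_normalize, character(1)),
                       present_on_admission = rep(NA, length(codes)))
  list(stay = stay_tab,
       labs = mk_labs(labs_hours, labs_values, stay),
       transfusions = tf, prescriptions = rx, diagnoses = dx)
}

# All-pairs brute-force oracle for the windowed maximum hemoglobin drop.
brute_max_drop <- function(hours, values, window = 48) {
  best <- NULL
  n <- length(hours)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      gap <- hours[j] - hours[i]
      if (gap <= 0 || gap > window) next
      drop <- values[i] - values[j]
      if (drop <= 0) next
      better <- is.null(best) ||
        drop > best$drop ||
        (drop == best$drop && (hours[j] < best$end ||
                                 (hours[j] == best$end && hours[i] < best$start)))
      if (better) best <- list(drop = drop, start = hours[i], end = hours[j])
    }
  }
  best
}

# Vectorized variant of the same oracle, for large batches.
brute_max_drop_vec <- function(hours, values, window = 48) {
  gaps <- outer(hours, hours, function(a, b) b - a)   # row i -> col j
  drops <- outer(values, values, function(a, b) a - b)
  ok <- gaps > 0 & gaps <= window & drops > 0
  if (!any(ok)) return(NULL)
  md <- max(drops[ok])
  idx <- which(ok & drops == md, arr.ind = TRUE)
  ord <- order(hours[idx[, 2]], hours[idx[, 1]])
  i <- idx[ord[1], 1]
  j <- idx[ord[1], 2]
  list(drop = md, start = hours[i], end = hours[j])
}

# Tiny in-memory cohort: two stays, one eligible bleeder, one clean.
mk_mini_cohort <- function() {
  stays <- tibble::tibble(
    stay_id = c("A", "B"),
    patient_id = c("pa", "pb"),
    admission_ts = c("2015-03-01T00:00:00", "2015-04-01T08:00:00"),
    discharge_ts = c("2015-03-05T00:00:00", "2015-04-03T08:00:00"),
    death_ts = c("", ""),
    age_years = c(80L, 71L),
    sex = c("female", "male"),
    hospital_id = c("H", "H")
  )
  labs <- tibble::tibble(
    stay_id = c("A", "A", "B"),
    analyte = "hemoglobin",
    value = c(14, 9.5, 12.1),
    ts = c("2015-03-01T06:00:00", "2015-03-02T06:00:00", "2015-04-01T12:00:00")
  )
  rx <- tibble::tibble(
    stay_id = c("A", "B"), atc_code = c("B01AF01", "B01AB05"),
    agent_name = c("rivaroxaban", "enoxaparin"),
    ts = c("2015-03-01T02:00:00", "2015-04-01T10:00:00")
  )
  bleedr::cohort(stays, labs, prescriptions = rx)
}
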