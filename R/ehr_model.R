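# Domain model and readers for structured inpatient EHR extracts.
#
# A cohort is a list of five tibbles (stays, labs, transfusions,
# prescriptions, diagnoses) sharing a stay_id key. Hemoglobin is stored in
# g/dL; timestamps are POSIXct in a single timezone per cohort.

COHORT_TABLES <- c("stays", "labs", "transfusions", "prescriptions", "diagnoses")

#' Default antithrombotic ATC prefixes
#'
#' Prefix set covering the eligibility definition: vitamin K antagonists
#' (B01AA), heparin group (B01AB), platelet aggregation inhibitors (B01AC),
#' direct thrombin inhibitors (B01AE), direct factor Xa inhibitors (B01AF),
#' and fondaparinux (B01AX05).
#'
#' @return character vector of ATC code prefixes
#' @export
antithrombotic_atc <- function() {
  c("B01AA", "B01AB", "B01AC", "B01AE", "B01AF", "B01AX05")
}

parse_ts <- function(x, tz = "UTC", what = "timestamp") {
  if (inherits(x, "POSIXct")) {
    return(x)
  }
  x <- as.character(x)
  out <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01", tz = tz)
  ok <- !is.na(x) & nzchar(x)
  if (any(ok)) {
    parsed <- as.POSIXct(x[ok], tz = tz,
                         tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                                        "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M", "%Y-%m-%d"))
    if (anyNA(parsed)) {
      bad <- x[ok][is.na(parsed)][1]
      abort(paste0("unparseable ", what, ": '", bad, "' (expected ISO-8601)"))
    }
    out[ok] <- parsed
  }
  out
}

hours_between <- function(later, earlier) {
  as.numeric(difftime(later, earlier, units = "hours"))
}

#' Construct a cohort object from in-memory tables
#'
#' Validates cross-table consistency (every child row must reference a known
#' stay), stay invariants (discharge after admission, in-hospital death within
#' the stay, nonnegative age), and the hemoglobin value range. Labs are sorted
#' by stay and timestamp.
#'
#' @param stays tibble: stay_id, patient_id, admission_ts, discharge_ts,
#'   death_ts, age_years, sex, hospital_id
#' @param labs tibble: stay_id, analyte, value (g/dL), ts
#' @param transfusions tibble: stay_id, product, units, ts
#' @param prescriptions tibble: stay_id, atc_code, agent_name, ts
#' @param diagnoses tibble: stay_id, icd10gm_code, present_on_admission
#' @param tz timezone applied to all character timestamps
#' @param lab_tolerance_hours labs outside stay bounds by more than this many
#'   hours are dropped with a warning (pre-admission values would corrupt the
#'   48-hour drop computation)
#' @return object of class `bleed_cohort`
#' @export
cohort <- function(stays,
                   labs = NULL, transfusions = NULL,
                   prescriptions = NULL, diagnoses = NULL,
                   tz = "UTC", lab_tolerance_hours = 24) {
  stays <- as_tibble(stays)
  need <- c("stay_id", "patient_id", "admission_ts", "discharge_ts",
            "death_ts", "age_years", "sex", "hospital_id")
  miss <- setdiff(need, names(stays))
  if (length(miss) > 0) abort(paste0("stays table missing columns: ", paste(miss, collapse = ", ")))
  stays$stay_id <- as.character(stays$stay_id)
  if (anyDuplicated(stays$stay_id)) abort("duplicate stay_id in stays table")
  stays$admission_ts <- parse_ts(stays$admission_ts, tz, "admission_ts")
  stays$discharge_ts <- parse_ts(stays$discharge_ts, tz, "discharge_ts")
  stays$death_ts <- parse_ts(stays$death_ts, tz, "death_ts")
  bad <- which(stays$discharge_ts < stays$admission_ts)
  if (length(bad) > 0) {
    abort(paste0("stays row ", bad[1], " (", stays$stay_id[bad[1]],
                 "): discharge_ts before admission_ts"))
  }
  dead <- which(!is.na(stays$death_ts))
  out_of_stay <- dead[stays$death_ts[dead] < stays$admission_ts[dead] |
                        stays$death_ts[dead] > stays$discharge_ts[dead]]
  if (length(out_of_stay) > 0) {
    abort(paste0("stays row ", out_of_stay[1], " (", stays$stay_id[out_of_stay[1]],
                 "): death_ts outside [admission_ts, discharge_ts]"))
  }
  if (any(stays$age_years < 0, na.rm = TRUE)) abort("negative age_years in stays table")

  empty_child <- function(cols) as_tibble(setNames(rep(list(character()), length(cols)), cols))
  attach_child <- function(tab, cols, name) {
    if (is.null(tab)) {
      return(list(tab = empty_child(cols), orphans = 0L))
    }
    tab <- as_tibble(tab)
    miss <- setdiff(cols, names(tab))
    if (length(miss) > 0) abort(paste0(name, " table missing columns: ", paste(miss, collapse = ", ")))
    tab$stay_id <- as.character(tab$stay_id)
    orphan <- !tab$stay_id %in% stays$stay_id
    if (any(orphan)) {
      warn(paste0(sum(orphan), " ", name, " row(s) reference unknown stay_id; dropped"))
    }
    list(tab = tab[!orphan, , drop = FALSE], orphans = sum(orphan))
  }

  lb <- attach_child(labs, c("stay_id", "analyte", "value", "ts"), "labs")
  tf <- attach_child(transfusions, c("stay_id", "product", "units", "ts"), "transfusions")
  rx <- attach_child(prescriptions, c("stay_id", "atc_code", "agent_name", "ts"), "prescriptions")
  dx <- attach_child(diagnoses, c("stay_id", "icd10gm_code"), "diagnoses")

  labs <- lb$tab
  if (nrow(labs) > 0) {
    labs$ts <- parse_ts(labs$ts, tz, "lab ts")
    labs$value <- as.numeric(labs$value)
    bad <- which(!is.finite(labs$value) | labs$value <= 0 | labs$value > 25)
    if (length(bad) > 0) {
      abort(paste0("labs row ", bad[1], ": hemoglobin value ", labs$value[bad[1]],
                   " g/dL outside (0, 25]; check the unit declaration"))
    }
    bounds <- stays[, c("stay_id", "admission_ts", "discharge_ts")]
    labs <- left_join(labs, bounds, by = "stay_id")
    out <- hours_between(labs$ts, labs$admission_ts) < -lab_tolerance_hours |
      hours_between(labs$ts, labs$discharge_ts) > lab_tolerance_hours
    if (any(out)) {
      warn(paste0(sum(out), " lab row(s) more than ", lab_tolerance_hours,
                  " h outside stay bounds; dropped"))
      labs <- labs[!out, , drop = FALSE]
    }
    labs <- labs[order(labs$stay_id, labs$ts), !names(labs) %in% c("admission_ts", "discharge_ts")]
  }

  transfusions <- tf$tab
  if (nrow(transfusions) > 0) {
    transfusions$ts <- parse_ts(transfusions$ts, tz, "transfusion ts")
    transfusions$units <- as.integer(transfusions$units)
    if (any(transfusions$units < 1, na.rm = TRUE)) abort("transfusion units must be >= 1")
    known <- c("whole_blood", "red_blood_cells", "plasma")
    bad <- setdiff(unique(transfusions$product), known)
    if (length(bad) > 0) abort(paste0("unknown transfusion product: ", bad[1]))
  }

  prescriptions <- rx$tab
  if (nrow(prescriptions) > 0) {
    prescriptions$ts <- parse_ts(prescriptions$ts, tz, "prescription ts")
    prescriptions$atc_code <- toupper(trimws(as.character(prescriptions$atc_code)))
    prescriptions$agent_name <- tolower(trimws(as.character(prescriptions$agent_name)))
    empty <- !nzchar(prescriptions$atc_code) & !nzchar(prescriptions$agent_name)
    empty[is.na(empty)] <- TRUE
    if (any(empty)) abort("prescription rows need at least one of atc_code / agent_name")
  }

  diagnoses <- dx$tab
  if (nrow(diagnoses) > 0) {
    diagnoses$icd10gm_code <- vapply(diagnoses$icd10gm_code, icd_normalize, character(1))
    if (!"present_on_admission" %in% names(diagnoses)) {
      diagnoses$present_on_admission <- NA
    }
  } else if (!"present_on_admission" %in% names(diagnoses)) {
    diagnoses$present_on_admission <- logical()
  }

  structure(
    list(stays = stays, labs = labs, transfusions = transfusions,
         prescriptions = prescriptions, diagnoses = diagnoses, tz = tz),
    orphans = lb$orphans + tf$orphans + rx$orphans + dx$orphans,
    class = "bleed_cohort"
  )
}

#' @export
print.bleed_cohort <- function(x, ...) {
  cat("<bleed_cohort> ", nrow(x$stays), " stays | ",
      nrow(x$labs), " labs | ", nrow(x$transfusions), " transfusions | ",
      nrow(x$prescriptions), " prescriptions | ", nrow(x$diagnoses),
      " diagnoses\n", sep = "")
  invisible(x)
}

#' Load a cohort from CSV tables
#'
#' Expects `stays.csv`, and optionally `labs.csv`, `transfusions.csv`,
#' `prescriptions.csv`, `diagnoses.csv` in `dir`. Hemoglobin values are
#' canonicalized to g/dL: each lab row's `unit` column must declare `g/dl` or
#' `g/l` (values in g/L are divided by 10). Units are never guessed from the
#' magnitude of the value.
#'
#' @param dir directory containing the CSV tables
#' @param tz timezone for all timestamps in this cohort
#' @param lab_tolerance_hours see [cohort()]
#' @return a `bleed_cohort`
#' @export
read_cohort <- function(dir, tz = "UTC", lab_tolerance_hours = 24) {
  path <- function(name) file.path(dir, paste0(name, ".csv"))
  if (!file.exists(path("stays"))) abort(paste0("stays.csv not found in ", dir))
  read1 <- function(name) {
    p <- path(name)
    if (!file.exists(p)) {
      return(NULL)
    }
    readr::read_csv(p, col_types = readr::cols(.default = readr::col_character()),
                    progress = FALSE, na = character())
  }
  stays <- read1("stays")
  stays$age_years <- as.integer(stays$age_years)
  labs <- read1("labs")
  if (!is.null(labs) && nrow(labs) > 0) {
    if (!"unit" %in% names(labs)) {
      abort("labs.csv: 'unit' column is mandatory (g/dl or g/l); units are never guessed")
    }
    unit <- tolower(trimws(labs$unit))
    bad <- which(!unit %in% c("g/dl", "g/l"))
    if (length(bad) > 0) {
      abort(paste0("labs.csv row ", bad[1], ": unit '", labs$unit[bad[1]],
                   "' is not a declared hemoglobin unit (g/dl or g/l)"))
    }
    labs$value <- as.numeric(labs$value) / ifelse(unit == "g/l", 10, 1)
    labs$unit <- NULL
  }
  cohort(stays, labs, read1("transfusions"), read1("prescriptions"),
         read1("diagnoses"), tz = tz, lab_tolerance_hours = lab_tolerance_hours)
}

fmt_ts <- function(ts, tz) {
  ifelse(is.na(ts), "", format(ts, "%Y-%m-%dT%H:%M:%S", tz = tz))
}

#' Write a cohort back to CSV tables
#'
#' Inverse of [read_cohort()] up to canonical units (labs are written in g/dL
#' with an explicit `unit` column) and row order.
#'
#' @param x a `bleed_cohort`
#' @param dir output directory (created if absent)
#' @return `dir`, invisibly
#' @export
write_cohort <- function(x, dir) {
  stopifnot(inherits(x, "bleed_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  st <- x$stays
  st$admission_ts <- fmt_ts(st$admission_ts, x$tz)
  st$discharge_ts <- fmt_ts(st$discharge_ts, x$tz)
  st$death_ts <- fmt_ts(st$death_ts, x$tz)
  readr::write_csv(st, file.path(dir, "stays.csv"))
  lb <- x$labs
  if (nrow(lb) > 0) {
    lb$unit <- "g/dl"
    lb$ts <- fmt_ts(lb$ts, x$tz)
  }
  readr::write_csv(lb, file.path(dir, "labs.csv"))
  tf <- x$transfusions
  if (nrow(tf) > 0) tf$ts <- fmt_ts(tf$ts, x$tz)
  readr::write_csv(tf, file.path(dir, "transfusions.csv"))
  rx <- x$prescriptions
  if (nrow(rx) > 0) rx$ts <- fmt_ts(rx$ts, x$tz)
  readr::write_csv(rx, file.path(dir, "prescriptions.csv"))
  readr::write_csv(x$diagnoses, file.path(dir, "diagnoses.csv"))
  invisible(dir)
}

#' Extract all records for one stay
#'
#' @param x a `bleed_cohort`
#' @param stay_id stay identifier
#' @return list with elements stay (one-row tibble), labs, transfusions,
#'   prescriptions, diagnoses
#' @export
stay_bundle <- function(x, stay_id) {
  stopifnot(inherits(x, "bleed_cohort"))
  if (!stay_id %in% x$stays$stay_id) abort(paste0("unknown stay_id: ", stay_id))
  pick <- function(tab) tab[tab$stay_id == stay_id, , drop = FALSE]
  list(stay = pick(x$stays), labs = pick(x$labs),
       transfusions = pick(x$transfusions),
       prescriptions = pick(x$prescriptions),
       diagnoses = pick(x$diagnoses))
}

#' Apply the study eligibility filter
#'
#' Keeps stays of patients aged 65 or older at admission, with at least one
#' prescription whose ATC code starts with an antithrombotic prefix, and a
#' stay length of at least `min_stay_hours` (exactly 24 h is eligible). The
#' filter is total, idempotent, and order-preserving; all child tables are
#' subset to the retained stays.
#'
#' @param x a `bleed_cohort`
#' @param min_age minimum admission age in years
#' @param min_stay_hours minimum stay duration in hours (inclusive)
#' @param atc_prefixes antithrombotic ATC prefixes, see [antithrombotic_atc()]
#' @return filtered `bleed_cohort`
#' @export
filter_eligible <- function(x, min_age = 65, min_stay_hours = 24,
                            atc_prefixes = antithrombotic_atc()) {
  stopifnot(inherits(x, "bleed_cohort"))
  rx <- x$prescriptions
  has_at <- character()
  if (nrow(rx) > 0) {
    hit <- Reduce(`|`, lapply(atc_prefixes, function(p) startsWith(rx$atc_code, p)))
    has_at <- unique(rx$stay_id[hit])
  }
  st <- x$stays
  keep <- st$age_years >= min_age &
    st$stay_id %in% has_at &
    hours_between(st$discharge_ts, st$admission_ts) >= min_stay_hours
  ids <- st$stay_id[keep]
  sub <- function(tab) tab[tab$stay_id %in% ids, , drop = FALSE]
  out <- x
  out$stays <- st[keep, , drop = FALSE]
  out$labs <- sub(x$labs)
  out$transfusions <- sub(x$transfusions)
  out$prescriptions <- sub(x$prescriptions)
  out$diagnoses <- sub(x$diagnoses)
  out
}
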