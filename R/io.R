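#' Read a visit-level administrative table
#'
#' Reads a `visits.csv`-style file into a validated visit table. One row is
#' one healthcare encounter (inpatient admission, specialist outpatient
#' consultation, emergency attendance or therapy visit) with its billed cost,
#' primary diagnosis code and dispensed medications.
#'
#' Expected columns: `patient_id`, `visit_id`, `visit_type` (one of
#' `inpatient`, `soc`, `ed`, `therapy`), `admission_date` and
#' `discharge_date` (ISO 8601; discharge may be blank for same-day
#' ambulatory visits), `cost` (non-negative, S$), `primary_diagnosis`,
#' `medications` (semicolon-delimited codes, may be blank), `subsidised` and
#' `short_stay` (logical). Row-level invariants enforced: discharge on or
#' after admission; `short_stay` only for inpatient visits; cost
#' non-negative.
#'
#' @param path Path to a CSV file.
#' @param skip_bad_rows If `TRUE`, rows violating an invariant are dropped
#'   with a warning listing the row numbers; if `FALSE` (default) any bad row
#'   aborts the read with row-numbered diagnostics.
#' @return A `data.frame` of validated visit records with `Date` date
#'   columns and logical flag columns.
#' @seealso [write_visits()], [read_patients()]
#' @export
read_visits <- function(path, skip_bad_rows = FALSE) {
  if (!file.exists(path)) stop_husegment("visits file does not exist: ", path)
  raw <- utils::read.csv(path, colClasses = "character",
                         na.strings = c("NA", ""), check.names = FALSE)
  need <- c("patient_id", "visit_id", "visit_type", "admission_date",
            "discharge_date", "cost", "primary_diagnosis", "medications",
            "subsidised", "short_stay")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols)) {
    stop_husegment("visits file is missing required column(s): ",
                   paste(missing_cols, collapse = ", "))
  }
  n <- nrow(raw)
  errs <- character(0)
  add_err <- function(rows, what) {
    if (length(rows)) {
      errs <<- c(errs, paste0("row ", rows, ": ", what))
    }
    rows
  }
  bad <- logical(n)
  adm <- as_iso_date(raw$admission_date)
  bad_adm <- union(attr(adm, "bad_rows"), which(is.na(raw$admission_date)))
  bad[add_err(bad_adm, "admission_date missing or not ISO 8601")] <- TRUE
  dis <- as_iso_date(raw$discharge_date)
  bad[add_err(attr(dis, "bad_rows"), "discharge_date not ISO 8601")] <- TRUE
  cost <- suppressWarnings(as.numeric(raw$cost))
  bad[add_err(which(is.na(cost) & !is.na(raw$cost)), "cost not numeric")] <- TRUE
  bad[add_err(which(is.na(raw$cost)), "cost missing")] <- TRUE
  bad[add_err(which(!is.na(cost) & cost < 0), "cost must be >= 0")] <- TRUE
  ok_type <- raw$visit_type %in% c("inpatient", "soc", "ed", "therapy")
  bad[add_err(which(!ok_type), "visit_type outside {inpatient, soc, ed, therapy}")] <- TRUE
  subs <- parse_flag(raw$subsidised)
  bad[add_err(which(is.na(subs)), "subsidised not TRUE/FALSE")] <- TRUE
  shrt <- parse_flag(raw$short_stay)
  bad[add_err(which(is.na(shrt)), "short_stay not TRUE/FALSE")] <- TRUE
  bad[add_err(which(!is.na(adm) & !is.na(dis) & dis < adm),
              "discharge_date before admission_date")] <- TRUE
  bad[add_err(which(shrt %in% TRUE & raw$visit_type != "inpatient"),
              "short_stay = TRUE on a non-inpatient visit")] <- TRUE
  bad[add_err(which(is.na(raw$patient_id)), "patient_id missing")] <- TRUE

  if (length(errs)) {
    if (!skip_bad_rows) {
      stop_husegment("invalid rows in ", path, ":\n  ",
                     paste(errs, collapse = "\n  "))
    }
    warning(sprintf("dropped %d invalid row(s) from %s", sum(bad), path),
            call. = FALSE)
  }
  keep <- !bad
  data.frame(
    patient_id = raw$patient_id[keep],
    visit_id = raw$visit_id[keep],
    visit_type = raw$visit_type[keep],
    admission_date = adm[keep],
    discharge_date = dis[keep],
    cost = cost[keep],
    primary_diagnosis = ifelse(is.na(raw$primary_diagnosis[keep]), "",
                               raw$primary_diagnosis[keep]),
    medications = ifelse(is.na(raw$medications[keep]), "",
                         raw$medications[keep]),
    subsidised = subs[keep],
    short_stay = shrt[keep],
    stringsAsFactors = FALSE
  )
}

#' @noRd
parse_flag <- function(x) {
  out <- rep(NA, length(x))
  out[tolower(x) %in% c("true", "t", "1")] <- TRUE
  out[tolower(x) %in% c("false", "f", "0")] <- FALSE
  out
}

#' Write a visit table to CSV
#'
#' Inverse of [read_visits()]: dates are serialized as ISO 8601 strings and
#' logical flags as `TRUE`/`FALSE`, so that a write/read round trip
#' reproduces the table field-for-field.
#'
#' @param visits A visit `data.frame` as returned by [read_visits()] or
#'   [generate_cohort()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_visits <- function(visits, path) {
  out <- visits
  out$admission_date <- format(out$admission_date, "%Y-%m-%d")
  out$discharge_date <- ifelse(is.na(visits$discharge_date), "",
                               format(visits$discharge_date, "%Y-%m-%d"))
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a patient-level table
#'
#' Reads a `patients.csv`-style file: one row per patient with birth date,
#' gender, race, nationality, a housing-type socio-economic proxy and an
#' optional death date. Housing values outside the documented set
#' (`rental_1_2room`, `flat_3room_plus`, `private`, `unknown`) degrade to
#' `unknown` with a warning; gender/race/nationality values outside their
#' sets become `NA` (downstream persistence models exclude such patients as
#' having missing socio-demographics).
#'
#' @param path Path to a CSV file with columns `patient_id`, `birth_date`,
#'   `gender`, `race`, `nationality`, `housing_type`, `death_date`.
#' @return A validated patient `data.frame`.
#' @export
read_patients <- function(path) {
  if (!file.exists(path)) stop_husegment("patients file does not exist: ", path)
  raw <- utils::read.csv(path, colClasses = "character",
                         na.strings = c("NA", ""), check.names = FALSE)
  need <- c("patient_id", "birth_date", "gender", "race", "nationality",
            "housing_type", "death_date")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols)) {
    stop_husegment("patients file is missing required column(s): ",
                   paste(missing_cols, collapse = ", "))
  }
  birth <- as_iso_date(raw$birth_date)
  death <- as_iso_date(raw$death_date)
  bad <- unique(c(attr(birth, "bad_rows"), attr(death, "bad_rows")))
  if (length(bad)) {
    stop_husegment("unparseable date(s) in ", path, " at row(s): ",
                   paste(bad, collapse = ", "))
  }
  bad_death <- which(!is.na(death) & !is.na(birth) & death < birth)
  if (length(bad_death)) {
    stop_husegment("death_date before birth_date at row(s): ",
                   paste(bad_death, collapse = ", "))
  }
  housing <- raw$housing_type
  known_housing <- c("rental_1_2room", "flat_3room_plus", "private", "unknown")
  odd <- !is.na(housing) & !(housing %in% known_housing)
  if (any(odd)) {
    warning(sprintf("%d housing_type value(s) outside the documented set; set to 'unknown'",
                    sum(odd)), call. = FALSE)
    housing[odd] <- "unknown"
  }
  housing[is.na(housing)] <- "unknown"
  norm_enum <- function(x, levels, field) {
    odd <- !is.na(x) & !(x %in% levels)
    if (any(odd)) {
      warning(sprintf("%d %s value(s) outside the documented set; set to NA",
                      sum(odd), field), call. = FALSE)
      x[odd] <- NA_character_
    }
    x
  }
  data.frame(
    patient_id = raw$patient_id,
    birth_date = birth,
    gender = norm_enum(raw$gender, c("female", "male"), "gender"),
    race = norm_enum(raw$race, c("chinese", "indian", "malay", "others"), "race"),
    nationality = norm_enum(raw$nationality, c("singaporean", "foreigner"),
                            "nationality"),
    housing_type = housing,
    death_date = death,
    stringsAsFactors = FALSE
  )
}

#' Write a patient table to CSV
#'
#' @param patients A patient `data.frame` as returned by [read_patients()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_patients <- function(patients, path) {
  out <- patients
  out$birth_date <- format(out$birth_date, "%Y-%m-%d")
  out$death_date <- ifelse(is.na(patients$death_date), "",
                           format(patients$death_date, "%Y-%m-%d"))
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}
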