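#' Identify index visits
#'
#' The index visit is a patient's first visit on or after `study_start` and
#' strictly before `study_end`; it anchors the two one-year observation
#' windows. Patients with no qualifying visit are absent from the result.
#'
#' @param visits A validated visit table ([read_visits()]).
#' @param study_start,study_end Enrolment window bounds (half-open,
#'   `[study_start, study_end)`).
#' @return A `data.frame` with columns `patient_id`, `index_date`.
#' @export
find_index_visits <- function(visits, study_start, study_end) {
  study_start <- as.Date(study_start)
  study_end <- as.Date(study_end)
  sel <- visits$admission_date >= study_start & visits$admission_date < study_end
  v <- visits[sel, , drop = FALSE]
  if (nrow(v) == 0L) {
    return(data.frame(patient_id = character(0),
                      index_date = as.Date(character(0))))
  }
  idx <- tapply(as.integer(v$admission_date), v$patient_id, min)
  data.frame(patient_id = names(idx),
             index_date = as.Date(as.integer(idx), origin = "1970-01-01"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Apply cohort inclusion criteria
#'
#' Retains patients aged at least `min_age` completed years at their index
#' date. Having at least one qualifying record is implied by possessing an
#' index visit. Patients with a missing birth date are excluded (their count
#' is reported in a message).
#'
#' @param patients A validated patient table ([read_patients()]).
#' @param index_dates Output of [find_index_visits()].
#' @param min_age Minimum age in completed years (default 21).
#' @return Character vector of included `patient_id`s.
#' @export
apply_inclusion <- function(patients, index_dates, min_age = 21) {
  m <- merge(index_dates, patients[, c("patient_id", "birth_date")],
             by = "patient_id")
  no_birth <- is.na(m$birth_date)
  if (any(no_birth)) {
    message(sum(no_birth), " patient(s) excluded for missing birth_date")
  }
  m <- m[!no_birth, , drop = FALSE]
  keep <- age_at(m$birth_date, m$index_date) >= min_age
  m$patient_id[keep]
}

#' Build the two one-year observation windows
#'
#' Year 1 is the half-open interval `[index, index + 365)` and Year 2 is
#' `[index + 365, index + 730)`: fixed 365-day windows, disjoint and
#' contiguous, with no leap-day special-casing.
#'
#' @param index_dates Output of [find_index_visits()], optionally restricted
#'   to included patients.
#' @return A `data.frame` with the window bounds per patient.
#' @export
build_windows <- function(index_dates) {
  data.frame(
    patient_id = index_dates$patient_id,
    index_date = index_dates$index_date,
    y1_start = index_dates$index_date,
    y1_end = index_dates$index_date + 365L,
    y2_start = index_dates$index_date + 365L,
    y2_end = index_dates$index_date + 730L,
    stringsAsFactors = FALSE)
}

#' Aggregate cost and utilization within an observation window
#'
#' Produces one row per patient with annual totals. Attribution rules: a
#' visit belongs to the window containing its admission date (boundary-
#' spanning stays are attributed whole, no proration); `cost_total` sums
#' billed cost over all visit types (therapy visits contribute cost only);
#' `admissions` counts inpatient visits including short stays; `los_total`
#' sums length of stay (discharge minus admission in days, minimum 1) over
#' non-short-stay inpatient visits, so same-day non-short admissions count 1
#' day; `soc_visits` and `ed_attendances` count the respective settings.
#' `died_in_window` flags a death date inside the window. Year-2 rows are
#' not produced for patients who died in Year 1; patients with no visits in
#' the window get a zero row.
#'
#' @param visits A validated visit table.
#' @param windows Output of [build_windows()].
#' @param patients A validated patient table (for death dates and age).
#' @param which `"year1"` or `"year2"`.
#' @return A `data.frame` of per-patient-year aggregates.
#' @export
aggregate_window <- function(visits, windows, patients, which = c("year1", "year2")) {
  which <- match.arg(which)
  pt <- patients[match(windows$patient_id, patients$patient_id), , drop = FALSE]
  if (which == "year2") {
    died_y1 <- !is.na(pt$death_date) &
      pt$death_date >= windows$y1_start & pt$death_date < windows$y1_end
    windows <- windows[!died_y1, , drop = FALSE]
    pt <- pt[!died_y1, , drop = FALSE]
  }
  ws <- if (which == "year1") windows$y1_start else windows$y2_start
  we <- if (which == "year1") windows$y1_end else windows$y2_end

  ids <- windows$patient_id
  wrow <- match(visits$patient_id, ids)
  known <- !is.na(wrow)
  n_orphan <- length(unique(visits$patient_id[!known]))
  if (n_orphan > 0) {
    message(n_orphan, " patient(s) in visits have no observation window; ",
            "their visits were ignored")
  }
  inw <- known & visits$admission_date >= ws[wrow] &
    visits$admission_date < we[wrow]
  v <- visits[inw, , drop = FALSE]
  f <- factor(v$patient_id, levels = ids)

  los_visit <- numeric(nrow(v))
  ip <- v$visit_type == "inpatient" & !v$short_stay
  dur <- as.numeric(v$discharge_date - v$admission_date)
  dur[is.na(dur)] <- 1
  los_visit[ip] <- pmax(1, dur[ip])

  sum_by <- function(x) as.numeric(tapply(x, f, sum, default = 0))
  out <- data.frame(
    patient_id = ids,
    window = which,
    cost_total = sum_by(v$cost),
    admissions = sum_by(as.numeric(v$visit_type == "inpatient")),
    los_total = sum_by(los_visit),
    soc_visits = sum_by(as.numeric(v$visit_type == "soc")),
    ed_attendances = sum_by(as.numeric(v$visit_type == "ed")),
    stringsAsFactors = FALSE)
  out$had_admission <- out$admissions > 0
  out$died_in_window <- !is.na(pt$death_date) &
    pt$death_date >= ws & pt$death_date < we
  out$age_at_first_visit <- age_at(pt$birth_date, windows$index_date)
  rownames(out) <- NULL
  out
}

#' Per-patient treatment tier from visit subsidy flags
#'
#' Classifies each patient's Year-1 visits into `subsidised_only`,
#' `unsubsidised_only` or `both`, the three subsidy tiers used in group
#' profiles and as a persistence-model covariate.
#'
#' @param visits A validated visit table.
#' @param windows Output of [build_windows()].
#' @return `data.frame` with `patient_id`, `treatment_tier` (`NA` for
#'   patients with no Year-1 visits).
#' @export
treatment_tier <- function(visits, windows) {
  wrow <- match(visits$patient_id, windows$patient_id)
  inw <- !is.na(wrow) & visits$admission_date >= windows$y1_start[wrow] &
    visits$admission_date < windows$y1_end[wrow]
  v <- visits[inw, , drop = FALSE]
  f <- factor(v$patient_id, levels = windows$patient_id)
  any_sub <- as.logical(tapply(v$subsidised, f, any, default = NA))
  any_unsub <- as.logical(tapply(!v$subsidised, f, any, default = NA))
  tier <- rep(NA_character_, nrow(windows))
  tier[any_sub %in% TRUE & any_unsub %in% FALSE] <- "subsidised_only"
  tier[any_sub %in% FALSE & any_unsub %in% TRUE] <- "unsubsidised_only"
  tier[any_sub %in% TRUE & any_unsub %in% TRUE] <- "both"
  data.frame(patient_id = windows$patient_id, treatment_tier = tier,
             stringsAsFactors = FALSE)
}
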