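#' Charlson comorbidity index (Quan adaptation) for one code set
#'
#' Maps each diagnosis code to at most one comorbidity category via the
#' supplied quan-kind mapping, applies the mild/severe hierarchy pairs
#' (when both members of a pair are present only the severe one scores) and
#' returns the sum of category weights over the distinct scoring categories.
#' Unmapped codes are ignored, so the score depends only on the set of
#' mapped categories, never on code multiplicity.
#'
#' @param dx_codes Character vector (set) of diagnosis codes.
#' @param mapping A quan-kind `code_mapping` from [load_code_mapping()].
#' @return A non-negative integer score.
#' @export
compute_ccmi <- function(dx_codes, mapping) {
  stopifnot(inherits(mapping, "code_mapping"))
  if (mapping$kind != "quan") {
    stop_husegment("compute_ccmi needs a quan-kind mapping")
  }
  cats <- unique(stats::na.omit(map_code(dx_codes, mapping)))
  if (!length(cats)) return(0L)
  pairs <- attr(mapping, "hierarchy")
  for (i in seq_len(nrow(pairs))) {
    if (all(pairs[i, ] %in% cats)) cats <- setdiff(cats, pairs[i, "mild"])
  }
  as.integer(sum(mapping$weights[cats]))
}

#' Per-patient comorbidity index over Year-1 visits
#'
#' Computes [compute_ccmi()] from each patient's Year-1 primary diagnoses
#' (the profiling window), vectorized over the cohort.
#'
#' @param visits A validated visit table.
#' @param windows Output of [build_windows()].
#' @param mapping A quan-kind `code_mapping`.
#' @return `data.frame` with `patient_id`, `ccmi`.
#' @export
ccmi_table <- function(visits, windows, mapping) {
  stopifnot(inherits(mapping, "code_mapping"), mapping$kind == "quan")
  wrow <- match(visits$patient_id, windows$patient_id)
  inw <- !is.na(wrow) & visits$admission_date >= windows$y1_start[wrow] &
    visits$admission_date < windows$y1_end[wrow]
  v <- visits[inw, , drop = FALSE]
  cat <- map_code(v$primary_diagnosis, mapping)
  keep <- !is.na(cat)
  pc <- unique(data.frame(patient_id = v$patient_id[keep], category = cat[keep],
                          stringsAsFactors = FALSE))
  pairs <- attr(mapping, "hierarchy")
  for (i in seq_len(nrow(pairs))) {
    has_severe <- pc$patient_id[pc$category == pairs[i, "severe"]]
    drop <- pc$category == pairs[i, "mild"] & pc$patient_id %in% has_severe
    pc <- pc[!drop, , drop = FALSE]
  }
  f <- factor(pc$patient_id, levels = windows$patient_id)
  score <- tapply(as.numeric(mapping$weights[pc$category]), f, sum, default = 0)
  data.frame(patient_id = windows$patient_id,
             ccmi = as.integer(score), stringsAsFactors = FALSE)
}

#' Polypharmacy score
#'
#' The polypharmacy score (PPS) is the highest number of unique dispensed
#' medication codes a patient ever received in a single visit: the maximum
#' over visits of the size of the visit's medication set (0 with no visits
#' or no medications). By default all supplied visits count ("ever"); pass
#' `windows` to restrict to Year-1 visits.
#'
#' @param visits A validated visit table.
#' @param patient_ids Patients to score (defaults to those present in
#'   `visits`).
#' @param windows Optional [build_windows()] output restricting the visits
#'   considered to Year 1.
#' @return `data.frame` with `patient_id`, `pps`.
#' @export
compute_pps <- function(visits, patient_ids = unique(visits$patient_id),
                        windows = NULL) {
  v <- visits
  if (!is.null(windows)) {
    wrow <- match(v$patient_id, windows$patient_id)
    inw <- !is.na(wrow) & v$admission_date >= windows$y1_start[wrow] &
      v$admission_date < windows$y1_end[wrow]
    v <- v[inw, , drop = FALSE]
  }
  nmed <- med_set_size(v$medications)
  f <- factor(v$patient_id, levels = patient_ids)
  pps <- tapply(nmed, f, max, default = 0)
  pps[is.na(pps)] <- 0
  data.frame(patient_id = patient_ids, pps = as.integer(pps),
             stringsAsFactors = FALSE)
}

# number of unique codes in each ";"-delimited medication field
#' @noRd
med_set_size <- function(meds) {
  if (!length(meds)) return(integer(0))
  vapply(strsplit(meds, ";", fixed = TRUE), function(x) {
    length(unique(x[nzchar(x)]))
  }, integer(1))
}

#' Condition groups sought in Year 1
#'
#' Maps each Year-1 visit's primary diagnosis to its reporting category via
#' a ccs-kind mapping and counts visits per patient and category. Unmapped
#' codes fall into the `"Residual codes; unclassified"` category. The
#' per-category visit counts support both ranking modes of
#' [rank_conditions()] (patients ever diagnosed, and visit frequency).
#'
#' @param visits A validated visit table.
#' @param windows Output of [build_windows()].
#' @param mapping A ccs-kind `code_mapping`.
#' @return `data.frame` with `patient_id`, `category`, `n_visits`.
#' @export
assign_conditions <- function(visits, windows, mapping) {
  stopifnot(inherits(mapping, "code_mapping"))
  wrow <- match(visits$patient_id, windows$patient_id)
  inw <- !is.na(wrow) & visits$admission_date >= windows$y1_start[wrow] &
    visits$admission_date < windows$y1_end[wrow]
  v <- visits[inw, , drop = FALSE]
  if (nrow(v) == 0L) {
    return(data.frame(patient_id = character(0), category = character(0),
                      n_visits = integer(0)))
  }
  cat <- map_code(v$primary_diagnosis, mapping)
  cat[is.na(cat)] <- "Residual codes; unclassified"
  agg <- stats::aggregate(list(n_visits = rep(1L, nrow(v))),
                          by = list(patient_id = v$patient_id, category = cat),
                          FUN = sum)
  agg <- agg[order(agg$patient_id, agg$category), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}
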