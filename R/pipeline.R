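#' Run the full segmentation and persistence pipeline
#'
#' Simulate (or accept) a cohort, segment it, score comorbidity and
#' polypharmacy, build the group profile tables and condition rankings, fit
#' the staged persistence models, and write every artifact to a directory.
#' With a fixed `(config, seed)` the run is deterministic: two invocations
#' produce byte-identical output files.
#'
#' Outputs written to `out_dir`: `visits.csv`, `patients.csv`,
#' `aggregates_y1.csv`, `aggregates_y2.csv`, `segmentation.csv`,
#' `thresholds.json`, `group_utilization.csv` (cost/utilization profile),
#' `group_characteristics.csv` (socio-demographic profile),
#' `conditions_by_patients.csv`, `conditions_by_visits.csv`,
#' `persistence_models.csv` and `manifest.json`.
#'
#' @param config A [cohort_config()].
#' @param out_dir Output directory (created if needed).
#' @param seed RNG seed (defaults to `config$seed`).
#' @param quan_map,ccs_map `code_mapping` objects; default to the packaged
#'   toy mappings.
#' @param alpha Backward-elimination significance level.
#' @param fit_models Set `FALSE` to skip the persistence regressions.
#' @return Invisibly, a list with the in-memory results (`cohort`, `seg`,
#'   `scores`, `conditions`, `profile`, `rank_patients`, `rank_visits`,
#'   `models`).
#' @export
run_hu_pipeline <- function(config, out_dir, seed = config$seed,
                            quan_map = NULL, ccs_map = NULL,
                            alpha = 0.001, fit_models = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(quan_map)) {
    quan_map <- load_code_mapping(
      system.file("extdata", "quan_ccmi_toy.csv", package = "husegment"),
      kind = "quan")
  }
  if (is.null(ccs_map)) {
    ccs_map <- load_code_mapping(
      system.file("extdata", "ccs_toy.csv", package = "husegment"),
      kind = "ccs")
  }
  cohort <- generate_cohort(config, seed = seed)
  write_cohort(cohort, config, out_dir, seed = seed)

  seg <- hu_segment(cohort$visits, cohort$patients,
                    study_start = config$study_start,
                    study_end = config$study_end)
  scores <- merge(ccmi_table(cohort$visits, seg$windows, quan_map),
                  compute_pps(cohort$visits,
                              patient_ids = seg$windows$patient_id),
                  by = "patient_id")
  conditions <- assign_conditions(cohort$visits, seg$windows, ccs_map)
  profile <- summarize_groups(seg, cohort$patients, scores = scores)
  rank_patients <- rank_conditions(seg, conditions, mode = "patients_ever")
  rank_visits <- rank_conditions(seg, conditions, mode = "visit_frequency")
  models <- NULL
  if (fit_models) {
    models <- hu_persistence(seg, cohort$patients, scores, conditions,
                             alpha = alpha)
  }

  wcsv <- function(x, f) utils::write.csv(x, file.path(out_dir, f),
                                          row.names = FALSE, na = "")
  wcsv(seg$aggregates_y1, "aggregates_y1.csv")
  wcsv(seg$aggregates_y2, "aggregates_y2.csv")
  wcsv(seg$segmentation, "segmentation.csv")
  jsonlite::write_json(
    list(cost_p90 = seg$thresholds$cost_p90, los_p90 = seg$thresholds$los_p90,
         soc_p90 = seg$thresholds$soc_p90, q = seg$thresholds$q,
         method = seg$thresholds$method,
         n_total = seg$thresholds$n_total,
         n_admitted = seg$thresholds$n_admitted),
    file.path(out_dir, "thresholds.json"), auto_unbox = TRUE, digits = NA)
  util_cols <- c("group", "n", "pct_of_patients", "pct_of_total_cost",
                 grep("^(cost|admissions|los|soc|ed)_",
                      names(profile), value = TRUE))
  wcsv(profile[, util_cols], "group_utilization.csv")
  wcsv(profile[, setdiff(names(profile),
                         setdiff(util_cols, c("group", "n")))],
       "group_characteristics.csv")
  wcsv(rank_patients, "conditions_by_patients.csv")
  wcsv(rank_visits, "conditions_by_visits.csv")
  if (!is.null(models)) {
    wcsv(models$report, "persistence_models.csv")
  }
  manifest <- list(
    seed = seed,
    n_patients = config$n_patients,
    n_included = nrow(seg$segmentation),
    thresholds = list(cost_p90 = seg$thresholds$cost_p90,
                      los_p90 = seg$thresholds$los_p90,
                      soc_p90 = seg$thresholds$soc_p90),
    quantile_rule = seg$thresholds$method,
    exceedance_rule = "strict (value > threshold)",
    window_days = 365,
    stay_attribution = "admission-date window, whole stay, no proration",
    short_stay_admissions = "counted in admissions, excluded from LOS",
    ccmi_window = "year1 primary diagnoses",
    pps_window = "all visits (ever)",
    group_counts = as.list(stats::setNames(as.integer(seg$counts),
                                           names(seg$counts))),
    alpha = alpha,
    config_hash = config_hash(config))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(cohort = cohort, seg = seg, scores = scores,
                 conditions = conditions, profile = profile,
                 rank_patients = rank_patients, rank_visits = rank_visits,
                 models = models))
}
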