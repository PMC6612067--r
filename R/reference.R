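#' Published reference tables for the source cohort
#'
#' Group-level counts reported for the original hospital cohort this method
#' was developed on (an academic medical centre's adult patient population,
#' N = 388,162): group sizes and the numerators of the persistence and
#' within-year death proportions, plus the per-group top-5 condition lists
#' by patients ever diagnosed. The underlying patient data are not
#' distributable; these printed summaries support arithmetic cross-checks
#' (recomputing the published percentages from their numerators and group
#' sizes) and define the published common high-utilizer condition pool.
#'
#' @return `reference_group_stats()`: `data.frame` with `group`, `n`,
#'   `persistence_n`, `death_n`. `reference_top5_conditions()`:
#'   `data.frame` with `group`, `rank`, `condition`, `patients_ever`.
#' @export
reference_group_stats <- function() {
  utils::read.csv(system.file("extdata", "reference_group_stats.csv",
                              package = "husegment"),
                  stringsAsFactors = FALSE)
}

#' @rdname reference_group_stats
#' @export
reference_top5_conditions <- function() {
  utils::read.csv(system.file("extdata", "reference_top5_conditions.csv",
                              package = "husegment"),
                  stringsAsFactors = FALSE)
}
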