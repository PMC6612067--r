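#' The eight mutually exclusive utilizer group labels
#'
#' @return Character vector of group labels in reporting order.
#' @export
hu_group_levels <- function() {
  c("Non-HU", "Cost", "LOS", "SOC", "LOS-SOC", "Cost-LOS", "Cost-SOC",
    "Cost-LOS-SOC")
}

#' Compute high-utilization thresholds
#'
#' Estimates the per-metric cutoffs defining high utilization: the `q`th
#' percentile (default 0.90) of annual cost and of SOC visits over all
#' included patients, and of total LOS over patients with at least one
#' admission only. The percentile estimator is linear interpolation between
#' adjacent order statistics at rank `1 + (n - 1) q`; a nearest-rank variant
#' is available for sensitivity checks. With no admitted patients the LOS
#' threshold is undefined (`NA`, with a warning) and classification then
#' ignores the LOS criterion.
#'
#' @param aggregates Year-1 aggregates from [aggregate_window()].
#' @param q Percentile defining high utilization (default 0.90).
#' @param method `"interpolate"` (default) or `"nearest"`.
#' @return An object of class `hu_thresholds` with elements `cost_p90`,
#'   `los_p90`, `soc_p90`, `n_total`, `n_admitted`, `q`, `method`.
#' @export
compute_thresholds <- function(aggregates, q = 0.90,
                               method = c("interpolate", "nearest")) {
  method <- match.arg(method)
  if (nrow(aggregates) < 1L) stop_husegment("need at least one aggregate row")
  adm <- aggregates[aggregates$had_admission, , drop = FALSE]
  los_p90 <- if (nrow(adm) == 0L) {
    warning("no admitted patients: LOS threshold undefined; ",
            "LOS criterion will be ignored", call. = FALSE)
    NA_real_
  } else {
    interp_quantile(adm$los_total, q, method)
  }
  structure(list(
    cost_p90 = interp_quantile(aggregates$cost_total, q, method),
    los_p90 = los_p90,
    soc_p90 = interp_quantile(aggregates$soc_visits, q, method),
    n_total = nrow(aggregates),
    n_admitted = nrow(adm),
    q = q, method = method
  ), class = "hu_thresholds")
}

#' @export
print.hu_thresholds <- function(x, ...) {
  cat(sprintf("HU thresholds (%sth percentile, %s):\n", format(100 * x$q),
              x$method))
  cat(sprintf("  cost  > S$%s  (n = %d)\n", format(round(x$cost_p90, 2)),
              x$n_total))
  cat(sprintf("  LOS   > %s days (admitted only, n = %d)\n",
              format(round(x$los_p90, 2)), x$n_admitted))
  cat(sprintf("  SOC   > %s visits (n = %d)\n", format(round(x$soc_p90, 2)),
              x$n_total))
  invisible(x)
}

#' Classify patient-years into the eight utilizer groups
#'
#' A patient exceeds a metric when strictly greater than its threshold
#' (values exactly at the threshold do not exceed); the combination of the
#' three exceedance indicators yields exactly one of the eight mutually
#' exclusive labels (all false = `Non-HU`). Patients with no admissions
#' carry `los_total = 0` and are compared against the LOS threshold like
#' everyone else.
#'
#' @param aggregates Aggregates from [aggregate_window()] (any window).
#' @param thresholds An `hu_thresholds` object.
#' @return Factor of group labels, levels [hu_group_levels()].
#' @export
classify_hu <- function(aggregates, thresholds) {
  stopifnot(inherits(thresholds, "hu_thresholds"))
  hc <- aggregates$cost_total > thresholds$cost_p90
  hl <- if (is.na(thresholds$los_p90)) {
    rep(FALSE, nrow(aggregates))
  } else {
    aggregates$los_total > thresholds$los_p90
  }
  hs <- aggregates$soc_visits > thresholds$soc_p90
  lab <- rep("Non-HU", nrow(aggregates))
  any_hu <- hc | hl | hs
  part <- function(i) {
    paste(c("Cost", "LOS", "SOC")[c(hc[i], hl[i], hs[i])], collapse = "-")
  }
  lab[any_hu] <- vapply(which(any_hu), part, character(1))
  factor(lab, levels = hu_group_levels())
}

#' Label Year-2 persistence against frozen Year-1 thresholds
#'
#' A patient persists when their Year-2 aggregate is classified into any HU
#' group using the *Year-1* thresholds (frozen, not re-estimated). Patients
#' with no Year-2 utilization have zero aggregates and are therefore
#' subsumed under Non-HU (`persisted = FALSE`). Year-1 decedents must be
#' excluded upstream (no Year-2 aggregate rows).
#'
#' @param aggregates_y2 Year-2 aggregates from [aggregate_window()].
#' @param thresholds_y1 The Year-1 `hu_thresholds`.
#' @return `data.frame` with `patient_id`, `persisted`.
#' @export
classify_persistence <- function(aggregates_y2, thresholds_y1) {
  grp <- classify_hu(aggregates_y2, thresholds_y1)
  data.frame(patient_id = aggregates_y2$patient_id,
             persisted = grp != "Non-HU", stringsAsFactors = FALSE)
}

#' Segment a cohort into high-utilizer groups
#'
#' The package's central estimator. From visit- and patient-level tables it
#' identifies index visits, applies the age inclusion rule, builds the two
#' 365-day observation windows, aggregates Year-1 and Year-2 cost and
#' utilization, estimates the three 90th-percentile thresholds on Year-1
#' data (LOS over admitted patients only; thresholds include patients who
#' later die), assigns each patient exactly one of the eight mutually
#' exclusive utilizer groups, and labels Year-2 persistence against the
#' frozen Year-1 thresholds (persistence is undefined, `NA`, for Year-1
#' decedents).
#'
#' @param visits A validated visit table ([read_visits()]).
#' @param patients A validated patient table ([read_patients()]).
#' @param study_start,study_end Enrolment window (defaults 2006-01-01 to
#'   2013-01-01).
#' @param q High-utilization percentile (default 0.90).
#' @param min_age Minimum age at index (default 21).
#' @param quantile_method Percentile estimator, `"interpolate"` or
#'   `"nearest"`.
#' @return An object of class `hu_segmentation`: list with `segmentation`
#'   (patient_id, group, persisted, died_y1, treatment_tier), `thresholds`,
#'   `aggregates_y1`, `aggregates_y2`, `windows`, `counts` and `call`.
#' @seealso [summary.hu_segmentation()], [summarize_groups()],
#'   [hu_persistence()]
#' @examples
#' cfg <- cohort_config(400, seed = 7)
#' coh <- generate_cohort(cfg)
#' seg <- hu_segment(coh$visits, coh$patients)
#' seg
#' @export
hu_segment <- function(visits, patients,
                       study_start = "2006-01-01", study_end = "2013-01-01",
                       q = 0.90, min_age = 21,
                       quantile_method = c("interpolate", "nearest")) {
  quantile_method <- match.arg(quantile_method)
  if (anyDuplicated(patients$patient_id)) {
    stop_husegment("duplicate patient_id rows in patients table")
  }
  index <- find_index_visits(visits, study_start, study_end)
  included <- apply_inclusion(patients, index, min_age = min_age)
  index <- index[index$patient_id %in% included, , drop = FALSE]
  windows <- build_windows(index)
  if (nrow(windows) == 0L) {
    seg <- data.frame(patient_id = character(0), group = factor(character(0),
                      levels = hu_group_levels()), persisted = logical(0),
                      died_y1 = logical(0), treatment_tier = character(0))
    out <- list(segmentation = seg, thresholds = NULL,
                aggregates_y1 = NULL, aggregates_y2 = NULL, windows = windows,
                counts = table(factor(character(0), hu_group_levels())),
                q = q, call = match.call())
    class(out) <- "hu_segmentation"
    return(out)
  }
  agg1 <- aggregate_window(visits, windows, patients, "year1")
  thresholds <- compute_thresholds(agg1, q = q, method = quantile_method)
  group <- classify_hu(agg1, thresholds)
  agg2 <- aggregate_window(visits, windows, patients, "year2")
  pers <- classify_persistence(agg2, thresholds)
  seg <- data.frame(patient_id = agg1$patient_id, group = group,
                    died_y1 = agg1$died_in_window, stringsAsFactors = FALSE)
  seg$persisted <- pers$persisted[match(seg$patient_id, pers$patient_id)]
  seg$persisted[seg$died_y1] <- NA
  tier <- treatment_tier(visits, windows)
  seg$treatment_tier <- tier$treatment_tier[match(seg$patient_id,
                                                  tier$patient_id)]
  out <- list(segmentation = seg[, c("patient_id", "group", "persisted",
                                     "died_y1", "treatment_tier")],
              thresholds = thresholds,
              aggregates_y1 = agg1, aggregates_y2 = agg2, windows = windows,
              counts = table(group), q = q, call = match.call())
  class(out) <- "hu_segmentation"
  out
}

#' @export
print.hu_segmentation <- function(x, ...) {
  n <- nrow(x$segmentation)
  cat(sprintf("High-utilizer segmentation of %d patients\n", n))
  if (!is.null(x$thresholds)) print(x$thresholds)
  if (n) {
    tab <- x$counts
    pct <- 100 * tab / n
    cat("Group sizes:\n")
    for (g in names(tab)) {
      cat(sprintf("  %-13s %7d (%.1f%%)\n", g, tab[[g]], pct[[g]]))
    }
    alive <- !x$segmentation$died_y1
    if (any(alive)) {
      cat(sprintf("Overall persistence (survivors): %.1f%%\n",
                  100 * mean(x$segmentation$persisted[alive])))
    }
  }
  invisible(x)
}

#' Summary of a high-utilizer segmentation
#'
#' @param object An `hu_segmentation`.
#' @param ... Unused.
#' @return A `data.frame` with one row per group: size, share of patients,
#'   share of total Year-1 cost, and death and persistence proportions
#'   (denominators are the group size; persistence is among all group
#'   members, decedents counting as non-persistent is *not* assumed —
#'   decedents are excluded from the persistence numerator and the group N
#'   denominator convention follows the profiling tables).
#' @export
summary.hu_segmentation <- function(object, ...) {
  seg <- object$segmentation
  n <- nrow(seg)
  agg <- object$aggregates_y1
  groups <- hu_group_levels()
  total_cost <- sum(agg$cost_total)
  rows <- lapply(groups, function(g) {
    sel <- seg$group == g
    ng <- sum(sel)
    data.frame(
      group = g, n = ng,
      pct_of_patients = if (n) 100 * ng / n else NA_real_,
      pct_of_total_cost = if (total_cost > 0) {
        100 * sum(agg$cost_total[sel]) / total_cost
      } else 0,
      deaths = sum(seg$died_y1[sel]),
      deaths_pct = if (ng) 100 * sum(seg$died_y1[sel]) / ng else NA_real_,
      persisted = sum(seg$persisted[sel], na.rm = TRUE),
      persisted_pct = if (ng) {
        100 * sum(seg$persisted[sel], na.rm = TRUE) / ng
      } else NA_real_,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Plot group sizes and cost concentration
#'
#' @param x An `hu_segmentation`.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.hu_segmentation <- function(x, ...) {
  s <- summary(x)
  old <- graphics::par(mfrow = c(1, 2), mar = c(7, 4, 2, 1))
  on.exit(graphics::par(old))
  graphics::barplot(s$pct_of_patients, names.arg = s$group, las = 2,
                    ylab = "% of patients", main = "Group size", ...)
  graphics::barplot(s$pct_of_total_cost, names.arg = s$group, las = 2,
                    ylab = "% of total Year-1 cost", main = "Cost share", ...)
  invisible(x)
}
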