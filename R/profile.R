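#' Group profile tables
#'
#' Builds the per-group profile used for reporting: group size and shares,
#' median and interquartile range (Q1-Q3, same order-statistic interpolation
#' rule as the thresholds) of cost, admissions, LOS, SOC visits, ED
#' attendances, age, comorbidity index and polypharmacy score, categorical
#' breakdowns (gender, race, treatment tier, housing type), and death and
#' persistence counts. Every percentage uses the group size as denominator,
#' decedents included. Groups with no members are emitted with `NA`
#' statistics.
#'
#' @param seg An [hu_segment()] result.
#' @param patients A validated patient table.
#' @param scores Optional `data.frame` with `patient_id`, `ccmi`, `pps`
#'   (see [ccmi_table()], [compute_pps()]).
#' @param include_total Prepend a `Total` row over all included patients.
#' @return A `data.frame`, one row per group, class `hu_group_summary`.
#' @export
summarize_groups <- function(seg, patients, scores = NULL,
                             include_total = TRUE) {
  stopifnot(inherits(seg, "hu_segmentation"))
  s <- seg$segmentation
  agg <- seg$aggregates_y1
  agg <- agg[match(s$patient_id, agg$patient_id), , drop = FALSE]
  pt <- patients[match(s$patient_id, patients$patient_id), , drop = FALSE]
  if (!is.null(scores)) {
    sc <- scores[match(s$patient_id, scores$patient_id), , drop = FALSE]
  }
  n_all <- nrow(s)
  total_cost <- sum(agg$cost_total)

  med_iqr <- function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) return(c(NA_real_, NA_real_, NA_real_))
    c(interp_quantile(x, 0.5), interp_quantile(x, 0.25), interp_quantile(x, 0.75))
  }
  cat_counts <- function(x, levels) {
    tab <- table(factor(x, levels = levels))
    as.integer(tab)
  }

  one_group <- function(sel, label) {
    ng <- sum(sel)
    qs <- list(
      cost = med_iqr(agg$cost_total[sel]),
      admissions = med_iqr(agg$admissions[sel]),
      los = med_iqr(agg$los_total[sel]),
      soc = med_iqr(agg$soc_visits[sel]),
      ed = med_iqr(agg$ed_attendances[sel]),
      age = med_iqr(agg$age_at_first_visit[sel]),
      ccmi = if (is.null(scores)) rep(NA_real_, 3) else med_iqr(sc$ccmi[sel]),
      pps = if (is.null(scores)) rep(NA_real_, 3) else med_iqr(sc$pps[sel]))
    gcount <- cat_counts(pt$gender[sel], c("female", "male"))
    rcount <- cat_counts(pt$race[sel], c("chinese", "indian", "malay", "others"))
    tcount <- cat_counts(s$treatment_tier[sel],
                         c("subsidised_only", "unsubsidised_only", "both"))
    hcount <- cat_counts(pt$housing_type[sel],
                         c("rental_1_2room", "flat_3room_plus", "private",
                           "unknown"))
    deaths <- sum(s$died_y1[sel])
    persisted <- sum(s$persisted[sel], na.rm = TRUE)
    row <- data.frame(
      group = label, n = ng,
      pct_of_patients = if (n_all) 100 * ng / n_all else NA_real_,
      pct_of_total_cost = if (total_cost > 0) {
        100 * sum(agg$cost_total[sel]) / total_cost
      } else 0,
      stringsAsFactors = FALSE)
    for (m in names(qs)) {
      row[[paste0(m, "_median")]] <- qs[[m]][1]
      row[[paste0(m, "_q1")]] <- qs[[m]][2]
      row[[paste0(m, "_q3")]] <- qs[[m]][3]
    }
    pctg <- function(cnt) if (ng) 100 * cnt / ng else NA_real_
    row$female_n <- gcount[1]; row$female_pct <- pctg(gcount[1])
    row$male_n <- gcount[2]; row$male_pct <- pctg(gcount[2])
    races <- c("chinese", "indian", "malay", "others")
    for (i in seq_along(races)) {
      row[[paste0(races[i], "_n")]] <- rcount[i]
      row[[paste0(races[i], "_pct")]] <- pctg(rcount[i])
    }
    tiers <- c("subsidised_only", "unsubsidised_only", "both")
    for (i in seq_along(tiers)) {
      row[[paste0(tiers[i], "_n")]] <- tcount[i]
      row[[paste0(tiers[i], "_pct")]] <- pctg(tcount[i])
    }
    housings <- c("rental_1_2room", "flat_3room_plus", "private", "unknown")
    for (i in seq_along(housings)) {
      row[[paste0("housing_", housings[i], "_n")]] <- hcount[i]
      row[[paste0("housing_", housings[i], "_pct")]] <- pctg(hcount[i])
    }
    row$deaths_n <- deaths; row$deaths_pct <- pctg(deaths)
    row$persistence_n <- persisted; row$persistence_pct <- pctg(persisted)
    row
  }

  rows <- list()
  if (include_total) {
    rows[["Total"]] <- one_group(rep(TRUE, n_all), "Total")
    rows[["Total"]]$pct_of_patients <- 100
  }
  for (g in hu_group_levels()) {
    rows[[g]] <- one_group(s$group == g, g)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("hu_group_summary", "data.frame")
  out
}

#' Share of total Year-1 cost by group
#'
#' @param seg An [hu_segment()] result.
#' @return Named numeric vector: percentage of total Year-1 cost incurred by
#'   each group (sums to 100 when total cost is positive; all zero with a
#'   warning when the cohort incurred no cost).
#' @export
pct_of_total_cost <- function(seg) {
  stopifnot(inherits(seg, "hu_segmentation"))
  s <- seg$segmentation
  agg <- seg$aggregates_y1
  cost <- agg$cost_total[match(s$patient_id, agg$patient_id)]
  total <- sum(cost)
  by_group <- tapply(cost, s$group, sum, default = 0)
  if (total <= 0) {
    warning("total cost is zero; all shares set to 0", call. = FALSE)
    return(stats::setNames(rep(0, length(by_group)), names(by_group)))
  }
  100 * by_group / total
}

#' Rank the most common conditions per group
#'
#' For each utilizer group, ranks condition categories either by the number
#' of patients ever diagnosed (`mode = "patients_ever"`) or by the number of
#' visits attributed to the condition (`mode = "visit_frequency"`), and
#' keeps the top `k`. Ties are broken lexicographically by category label so
#' the output is deterministic. Percentages are count over group size.
#'
#' @param seg An [hu_segment()] result.
#' @param conditions Output of [assign_conditions()].
#' @param mode Ranking mode.
#' @param k Number of entries per group (default 5).
#' @return `data.frame` with `group`, `rank`, `category`, `count`, `pct`.
#' @export
rank_conditions <- function(seg, conditions,
                            mode = c("patients_ever", "visit_frequency"),
                            k = 5) {
  stopifnot(inherits(seg, "hu_segmentation"))
  mode <- match.arg(mode)
  s <- seg$segmentation
  cond <- conditions
  cond$group <- s$group[match(cond$patient_id, s$patient_id)]
  cond <- cond[!is.na(cond$group), , drop = FALSE]
  rows <- list()
  for (g in hu_group_levels()) {
    cg <- cond[cond$group == g, , drop = FALSE]
    ng <- sum(s$group == g)
    if (nrow(cg) == 0L) next
    cnt <- if (mode == "patients_ever") {
      tapply(cg$patient_id, cg$category, function(p) length(unique(p)))
    } else {
      tapply(cg$n_visits, cg$category, sum)
    }
    df <- data.frame(category = names(cnt), count = as.integer(cnt),
                     stringsAsFactors = FALSE)
    df <- df[order(-df$count, df$category), , drop = FALSE]
    df <- utils::head(df, k)
    rows[[g]] <- data.frame(group = g, rank = seq_len(nrow(df)),
                            category = df$category, count = df$count,
                            pct = 100 * df$count / ng,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pool the common high-utilizer conditions
#'
#' The deduplicated union of the per-group top-5 condition lists (in
#' patients-ever mode). These pooled conditions are the candidate covariates
#' added in the final persistence model.
#'
#' @param rankings Output of [rank_conditions()] covering the eight groups.
#' @return Sorted character vector of distinct condition labels.
#' @export
common_hu_conditions <- function(rankings) {
  sort(unique(rankings$category))
}
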