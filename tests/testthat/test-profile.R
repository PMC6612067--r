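# hand-built segmentation of 12 patients across 3 groups, used in several blocks
profile_fixture <- function() {
  ids <- sprintf("F%02d", 1:12)
  groups <- factor(c(rep("Non-HU", 6), rep("Cost", 4), rep("SOC", 2)),
                   levels = hu_group_levels())
  segdf <- data.frame(
    patient_id = ids, group = groups,
    persisted = c(FALSE, FALSE, TRUE, FALSE, FALSE, NA,
                  TRUE, TRUE, FALSE, FALSE, TRUE, FALSE),
    died_y1 = c(rep(FALSE, 5), TRUE, rep(FALSE, 6)),
    treatment_tier = c(rep("subsidised_only", 4), "both", "both",
                       rep("unsubsidised_only", 3), "both",
                       "subsidised_only", "both"),
    stringsAsFactors = FALSE)
  agg <- make_agg(cost = c(100, 200, 300, 400, 500, 600,
                           5000, 6000, 7000, 8000, 900, 1100),
                  los = 0, soc = c(rep(0, 10), 9, 11),
                  patient_id = ids)
  agg$age_at_first_visit <- c(30, 40, 50, 60, 70, 80, 55, 65, 75, 85, 25, 35)
  list(seg = make_seg(segdf, agg),
       patients = make_patients(ids,
                                gender = rep(c("female", "male"), 6),
                                housing_type = "flat_3room_plus"))
}

test_that("group summaries match hand-computed statistics", {
  fx <- profile_fixture()
  s <- summarize_groups(fx$seg, fx$patients, include_total = FALSE)
  nh <- s[s$group == "Non-HU", ]
  expect_equal(nh$n, 6)
  expect_equal(nh$pct_of_patients, 100 * 6 / 12)
  expect_equal(nh$cost_median, median(c(100, 200, 300, 400, 500, 600)))
  expect_equal(nh$cost_q1, unname(quantile(c(100, 200, 300, 400, 500, 600), 0.25)))
  # denominator convention: percentages always use group N, decedents included
  expect_equal(nh$deaths_pct, 100 * 1 / 6)
  expect_equal(nh$persistence_pct, 100 * 1 / 6)
  co <- s[s$group == "Cost", ]
  expect_equal(co$persistence_n, 2)
  expect_equal(co$persistence_pct, 50)
  expect_equal(co$unsubsidised_only_pct, 75)
  # cost shares: hand computation and conservation
  total <- sum(fx$seg$aggregates_y1$cost_total)
  expect_equal(co$pct_of_total_cost, 100 * 26000 / total)
  expect_equal(sum(s$pct_of_total_cost), 100, tolerance = 1e-8)
  expect_equal(sum(s$pct_of_patients), 100, tolerance = 1e-8)
  expect_equal(s$soc_median[s$group == "SOC"], 10)
  # empty group rows are emitted with NA statistics
  expect_true(is.na(s$cost_median[s$group == "LOS"]))
  expect_equal(s$n[s$group == "LOS"], 0)
  # a one-patient group has median equal to the value and a degenerate IQR
  seg1 <- make_seg(
    data.frame(patient_id = "Z1",
               group = factor("LOS", hu_group_levels()),
               persisted = FALSE, died_y1 = FALSE, treatment_tier = "both",
               stringsAsFactors = FALSE),
    make_agg(cost = 42, los = 15, soc = 1, admissions = 2L, patient_id = "Z1"))
  s1 <- summarize_groups(seg1, make_patients("Z1"), include_total = FALSE)
  expect_equal(unlist(s1[s1$group == "LOS",
                         c("cost_median", "cost_q1", "cost_q3")],
                      use.names = FALSE), c(42, 42, 42))
})

test_that("published-style percentage arithmetic reproduces on the fixture", {
  fx <- profile_fixture()
  s <- summarize_groups(fx$seg, fx$patients, include_total = FALSE)
  # 1-decimal rounding of count/group-N percentages, as reported
  expect_equal(round(s$persistence_pct[s$group == "Cost"], 1), 50.0)
  expect_equal(round(100 * 1863 / 5270, 1), 35.4)
})

test_that("condition rankings respect mode, ties and the group-N denominator", {
  fx <- profile_fixture()
  # Non-HU patients: F01 visits flu 3x; others one visit each
  cond <- data.frame(
    patient_id = c("F01", "F01", "F02", "F03", "F07", "F08", "F11"),
    category = c("Flu", "Alpha", "Alpha", "Alpha", "Cardiac", "Cardiac",
                 "Pregnancy"),
    n_visits = c(3L, 1L, 1L, 1L, 1L, 1L, 1L),
    stringsAsFactors = FALSE)
  by_pat <- rank_conditions(fx$seg, cond, mode = "patients_ever")
  nh <- by_pat[by_pat$group == "Non-HU", ]
  expect_equal(nh$category[1], "Alpha")      # 3 patients beat 1 patient
  expect_equal(nh$count[1], 3L)
  expect_equal(nh$pct[1], 100 * 3 / 6)       # denominator is group N = 6
  by_vis <- rank_conditions(fx$seg, cond, mode = "visit_frequency")
  nhv <- by_vis[by_vis$group == "Non-HU", ]
  # visit mode reorders: Alpha ties Flu at 3 visits, tie broken by label
  expect_equal(nhv$count[1:2], c(3L, 3L))
  expect_equal(nhv$category[1:2], c("Alpha", "Flu"))

  # single shared condition: one entry at 100%
  cond2 <- data.frame(patient_id = sprintf("F%02d", 1:6),
                      category = "Alpha", n_visits = 1L,
                      stringsAsFactors = FALSE)
  r2 <- rank_conditions(fx$seg, cond2)
  expect_equal(nrow(r2[r2$group == "Non-HU", ]), 1L)
  expect_equal(r2$pct[r2$group == "Non-HU"], 100)
})

test_that("the common-condition pool is the deduplicated union of top lists", {
  same <- data.frame(group = rep(c("A", "B"), each = 5),
                     rank = rep(1:5, 2),
                     category = rep(letters[1:5], 2))
  expect_length(common_hu_conditions(same), 5L)
  disjoint <- data.frame(group = rep(1:8, each = 5), rank = rep(1:5, 8),
                         category = as.character(1:40))
  expect_length(common_hu_conditions(disjoint), 40L)
})

test_that("cost share handles single-group concentration and zero totals", {
  ids <- c("A", "B")
  segdf <- data.frame(patient_id = ids,
                      group = factor(c("Cost", "Non-HU"),
                                     levels = hu_group_levels()),
                      persisted = FALSE, died_y1 = FALSE,
                      treatment_tier = "both", stringsAsFactors = FALSE)
  seg <- make_seg(segdf, make_agg(cost = c(1000, 0), patient_id = ids))
  shares <- pct_of_total_cost(seg)
  expect_equal(unname(shares[["Cost"]]), 100)
  seg0 <- make_seg(segdf, make_agg(cost = c(0, 0), patient_id = ids))
  expect_warning(z <- pct_of_total_cost(seg0), "zero")
  expect_true(all(z == 0))
})
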