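# logistic fits on constructed designs, checked against closed forms

design_from_counts <- function(events, totals, labels = names(events)) {
  # one-factor patient-level design from per-level event counts
  d <- do.call(rbind, lapply(seq_along(events), function(i) {
    data.frame(persisted = rep(c(1L, 0L), c(events[i], totals[i] - events[i])),
               g = labels[i], stringsAsFactors = FALSE)
  }))
  d$g <- factor(d$g, levels = labels)
  list(data = d, terms = "g", forced = character(0))
}

test_that("a saturated 2x2 fit reproduces the cross-product odds ratio", {
  des <- design_from_counts(c(ref = 10, exp = 20), c(ref = 100, exp = 100))
  fit <- fit_logistic(des)
  expect_equal(fit$or_table$or, (20 / 80) / (10 / 90), tolerance = 1e-6)
  # 99% Wald CI from the analytic standard error of a 2x2 log odds ratio
  # (solver precision on the SE is looser than on the estimate)
  se <- sqrt(1 / 20 + 1 / 80 + 1 / 10 + 1 / 90)
  z <- qnorm(0.995)
  expect_equal(fit$or_table$lo, exp(log(2.25) - z * se), tolerance = 1e-3)
  expect_equal(fit$or_table$hi, exp(log(2.25) + z * se), tolerance = 1e-3)
})

test_that("a null covariate gives OR near 1 with CI covering 1", {
  set.seed(12)
  d <- data.frame(persisted = rbinom(2000, 1, 0.3),
                  x = rbinom(2000, 1, 0.5))
  fit <- fit_logistic(list(data = d, terms = "x"))
  expect_lt(abs(log(fit$or_table$or)), 0.5)
  expect_true(fit$or_table$lo < 1 && fit$or_table$hi > 1)
})

test_that("the intercept-only model has zero pseudo-R-squared", {
  d <- data.frame(persisted = rep(c(1L, 0L), c(30, 70)))
  fit <- fit_logistic(list(data = d, terms = character(0)))
  expect_equal(fit$mcfadden_r2, 0)
  expect_equal(fit$loglik, fit$null_loglik, tolerance = 1e-10)
})

test_that("group-only fits equal cross-product ratios against the reference", {
  set.seed(31)
  events <- c(40, 25, 9, 60, 7, 31, 55, 42)
  totals <- c(900, 120, 40, 300, 25, 90, 150, 95)
  des <- design_from_counts(events, totals, labels = hu_group_levels())
  names(des$data)[2] <- "hu_group"; des$terms <- "hu_group"
  fit <- fit_logistic(des)
  odds <- events / (totals - events)
  oracle <- odds[-1] / odds[1]
  got <- fit$or_table$or[match(paste0("hu_group", hu_group_levels()[-1]),
                               fit$or_table$term)]
  expect_equal(got, oracle, tolerance = 1e-6)
})

test_that("likelihood-ratio tests match the chi-square tail", {
  d <- data.frame(persisted = rbinom(500, 1, 0.4), x = rnorm(500))
  f0 <- fit_logistic(list(data = d, terms = character(0)))
  f1 <- fit_logistic(list(data = d, terms = "x"))
  same <- likelihood_ratio_test(f0, f0)
  expect_equal(same$chi2, 0)
  expect_equal(same$p, 1)
  lrt <- likelihood_ratio_test(f0, f1)
  expect_equal(lrt$df, 1L)
  expect_equal(lrt$p, pchisq(lrt$chi2, 1, lower.tail = FALSE))
  # frozen oracle value: chi2 = 10 on 1 df
  expect_equal(pchisq(10, 1, lower.tail = FALSE), 1.565402e-3,
               tolerance = 1e-6)
  # deviance is non-increasing from nested to full
  expect_gte(lrt$chi2, 0)
  expect_lte(f1$deviance, f0$deviance)
  # a planted strong predictor is detected decisively
  set.seed(8)
  x <- rnorm(2000)
  y <- rbinom(2000, 1, plogis(-1 + 1.5 * x))
  dd <- data.frame(persisted = y, x = x)
  g0 <- fit_logistic(list(data = dd, terms = character(0)))
  g1 <- fit_logistic(list(data = dd, terms = "x"))
  expect_lt(likelihood_ratio_test(g0, g1)$p, 1e-6)
  # non-nested inputs are rejected
  d2 <- dd; d2$z <- rnorm(2000)
  fz <- fit_logistic(list(data = d2, terms = "z"))
  expect_error(likelihood_ratio_test(g1, fz), "not nested")
})

test_that("backward elimination removes noise, keeps signal, honours forcing", {
  set.seed(55)
  n <- 4000
  x <- rbinom(n, 1, 0.5)
  noise <- factor(sample(letters[1:4], n, TRUE))
  y <- rbinom(n, 1, plogis(-1.5 + 1.0 * x))
  d <- data.frame(persisted = y, x = x, noise = noise)
  res <- backward_eliminate(list(data = d, terms = c("x", "noise"),
                                 forced = character(0)), alpha = 0.001)
  expect_equal(res$design$terms, "x")
  expect_equal(res$trace$term, "noise")
  expect_gte(res$trace$p_value, 0.001)

  # a forced exposure survives even when unrelated to the outcome
  d2 <- data.frame(persisted = rbinom(n, 1, 0.3),
                   hu_group = factor(sample(c("Non-HU", "Cost"), n, TRUE),
                                     levels = c("Non-HU", "Cost")))
  res2 <- backward_eliminate(list(data = d2, terms = "hu_group",
                                  forced = "hu_group"), alpha = 0.001)
  expect_equal(res2$design$terms, "hu_group")
  expect_equal(nrow(res2$trace), 0L)
})

test_that("design construction applies exclusions and the missing-CCMI rule", {
  cfg <- cohort_config(1500, seed = 23)
  coh <- generate_cohort(cfg)
  seg <- suppressMessages(hu_segment(coh$visits, coh$patients))
  w <- seg$windows
  scores <- merge(ccmi_table(coh$visits, w, packaged_quan()),
                  compute_pps(coh$visits, patient_ids = w$patient_id),
                  by = "patient_id")
  # blank out some CCMI values: design must impute zero
  scores$ccmi[1:5] <- NA
  d1 <- build_design(seg, coh$patients, scores, model = "m1")
  expect_true(all(d1$data$ccmi[d1$data$patient_id %in%
                                 scores$patient_id[1:5]] == 0))
  # year-1 decedents are absent from the design
  dead <- seg$segmentation$patient_id[seg$segmentation$died_y1]
  expect_false(any(dead %in% d1$data$patient_id))
  # patients with missing socio-demographics are excluded
  pts_na <- coh$patients
  pts_na$gender[1] <- NA
  d1b <- suppressMessages(build_design(seg, pts_na, scores, model = "m1"))
  expect_false(pts_na$patient_id[1] %in% d1b$data$patient_id)

  # model-2 candidate count: model-1 terms plus one indicator per condition
  conds <- assign_conditions(coh$visits, w, packaged_ccs())
  rk <- rank_conditions(seg, conds)
  cc <- common_hu_conditions(rk)
  d2 <- build_design(seg, coh$patients, scores, model = "m2",
                     conditions = conds, common_conditions = cc)
  expect_length(d2$terms, length(d1$terms) + length(cc))
})

test_that("the staged model report formats references, blanks and parses back", {
  cfg <- cohort_config(4000, seed = 29)
  coh <- generate_cohort(cfg)
  seg <- suppressMessages(hu_segment(coh$visits, coh$patients))
  scores <- merge(ccmi_table(coh$visits, seg$windows, packaged_quan()),
                  compute_pps(coh$visits, patient_ids = seg$windows$patient_id),
                  by = "patient_id")
  conds <- assign_conditions(coh$visits, seg$windows, packaged_ccs())
  fits <- suppressWarnings(
    hu_persistence(seg, coh$patients, scores, conds, alpha = 0.001))
  rep <- fits$report
  # reference levels print 1.00 wherever the factor is in the model
  expect_equal(rep$model0[rep$level == "Non-HU"], "1.00")
  expect_equal(rep$model1[rep$level == "Non-HU"], "1.00")
  # factors eliminated from a model leave blank cells
  removed <- intersect(fits$trace_m1$term, rep$factor)
  for (tm in removed) {
    expect_true(all(rep$model1[rep$factor == tm] == ""), label = tm)
  }
  # pseudo-R2 rises across the stages when added terms carry signal
  expect_gt(fits$m1$mcfadden_r2, fits$m0$mcfadden_r2)
  expect_gte(fits$m2$mcfadden_r2, fits$m1$mcfadden_r2)
  # staged models are nested with valid LRTs
  expect_gte(fits$lrt_01$chi2, 0)
  expect_gte(fits$lrt_12$chi2, 0)
  expect_gt(fits$lrt_01$df, 0)
  # serialization round trip
  path <- tempfile(fileext = ".csv")
  utils::write.csv(rep, path, row.names = FALSE, na = "")
  back <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  back[is.na(back)] <- ""
  expect_equal(as.matrix(back), as.matrix(rep), ignore_attr = TRUE)
})

test_that("apparent separation is surfaced, as a warning or an error", {
  d <- data.frame(persisted = c(rep(0:1, 50), rep(0L, 40)),
                  g = factor(rep(c("a", "b"), c(100, 40))))
  expect_warning(fit <- fit_logistic(list(data = d, terms = "g")),
                 "separation.*gb")
  expect_true(fit$or_table$or[fit$or_table$term == "gb"] < 1e-6)
  expect_error(fit_logistic(list(data = d, terms = "g"),
                            on_separation = "error"), "separation.*gb")
})
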