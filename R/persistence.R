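#' Build a persistence model design
#'
#' Assembles the analysis data set for the staged persistence logistic
#' models. Exclusions: Year-1 decedents (persistence undefined) and patients
#' with missing socio-demographics (gender, race or nationality; unknown
#' housing is its own level, not an exclusion). A missing comorbidity index
#' is assumed to be 0. Covariate sets: `m0` has the utilizer group only;
#' `m1` adds age at first visit, gender, race, nationality, treatment tier,
#' housing type, comorbidity index (CCMI) and polypharmacy score (PPS); `m2`
#' further adds one presence indicator per common high-utilizer condition.
#' Reference levels are fixed: group `Non-HU`, gender `female`, race
#' `chinese`, nationality `foreigner`, treatment tier `subsidised_only`,
#' housing `rental_1_2room`, condition indicators reference absence.
#'
#' @param seg An [hu_segment()] result.
#' @param patients A validated patient table.
#' @param scores `data.frame` with `patient_id`, `ccmi`, `pps` (needed for
#'   `m1`/`m2`).
#' @param model `"m0"`, `"m1"` or `"m2"`.
#' @param conditions [assign_conditions()] output (needed for `m2`).
#' @param common_conditions Character vector of condition labels
#'   ([common_hu_conditions()]; needed for `m2`).
#' @return An object of class `hu_design`: list with `data`, `terms`
#'   (term labels in order), `forced` (terms never eliminated) and `model`.
#' @export
build_design <- function(seg, patients, scores = NULL,
                         model = c("m0", "m1", "m2"),
                         conditions = NULL, common_conditions = NULL) {
  stopifnot(inherits(seg, "hu_segmentation"))
  model <- match.arg(model)
  s <- seg$segmentation
  keep <- !s$died_y1
  pt <- patients[match(s$patient_id, patients$patient_id), , drop = FALSE]
  missing_demo <- is.na(pt$gender) | is.na(pt$race) | is.na(pt$nationality)
  if (any(missing_demo & keep)) {
    message(sum(missing_demo & keep),
            " patient(s) excluded for missing socio-demographics")
  }
  keep <- keep & !missing_demo
  s <- s[keep, , drop = FALSE]
  pt <- pt[keep, , drop = FALSE]
  if (anyDuplicated(s$patient_id)) {
    stop_husegment("duplicate patient rows in segmentation")
  }
  d <- data.frame(
    patient_id = s$patient_id,
    persisted = as.integer(s$persisted),
    hu_group = factor(s$group, levels = hu_group_levels()),
    stringsAsFactors = FALSE)
  terms <- "hu_group"
  if (model %in% c("m1", "m2")) {
    agg <- seg$aggregates_y1
    d$age <- agg$age_at_first_visit[match(s$patient_id, agg$patient_id)]
    d$gender <- factor(pt$gender, levels = c("female", "male"))
    d$race <- factor(pt$race, levels = c("chinese", "indian", "malay", "others"))
    d$nationality <- factor(pt$nationality,
                            levels = c("foreigner", "singaporean"))
    d$treatment_tier <- factor(s$treatment_tier,
                               levels = c("subsidised_only",
                                          "unsubsidised_only", "both"))
    d$housing <- factor(pt$housing_type,
                        levels = c("rental_1_2room", "flat_3room_plus",
                                   "private", "unknown"))
    if (is.null(scores)) stop_husegment("scores required for m1/m2")
    sc <- scores[match(s$patient_id, scores$patient_id), , drop = FALSE]
    d$ccmi <- ifelse(is.na(sc$ccmi), 0, sc$ccmi)
    d$pps <- ifelse(is.na(sc$pps), 0, sc$pps)
    terms <- c(terms, "age", "gender", "race", "nationality",
               "treatment_tier", "housing", "ccmi", "pps")
  }
  if (model == "m2") {
    if (is.null(conditions) || is.null(common_conditions)) {
      stop_husegment("conditions and common_conditions required for m2")
    }
    for (j in seq_along(common_conditions)) {
      cc <- common_conditions[j]
      with_cc <- unique(conditions$patient_id[conditions$category == cc])
      col <- paste0("cond_", j)
      d[[col]] <- as.integer(d$patient_id %in% with_cc)
      attr(d[[col]], "label") <- cc
      terms <- c(terms, col)
    }
    attr(terms, "condition_labels") <- stats::setNames(
      common_conditions, paste0("cond_", seq_along(common_conditions)))
  }
  structure(list(data = d, terms = terms, forced = "hu_group", model = model),
            class = "hu_design")
}

#' Fit a persistence logistic regression
#'
#' Maximum-likelihood logistic fit of the persistence outcome on the design
#' terms (iteratively reweighted least squares, relative log-likelihood
#' tolerance 1e-8, at most 100 iterations). Reports, per non-reference
#' level, the odds ratio `exp(beta)` and its Wald 99% confidence interval
#' `exp(beta +/- z[0.995] se)`, the model and null log-likelihoods, residual
#' deviance and degrees of freedom, and McFadden's pseudo-R-squared
#' `1 - logLik / logLik_null`.
#'
#' @param design An [build_design()] result, or a list with elements `data`
#'   (containing a 0/1 `persisted` column) and `terms`.
#' @param ci_level Confidence level for the odds-ratio intervals (default
#'   0.99).
#' @param on_separation `"warn"` (default) or `"error"`: how to treat
#'   apparent separation (a |log-odds| estimate above 15, typically a factor
#'   level with no events). A warning keeps the fit — the affected level's
#'   interval is uninformatively wide — while `"error"` aborts naming the
#'   offending term.
#' @return An object of class `hu_logit`.
#' @export
fit_logistic <- function(design, ci_level = 0.99,
                         on_separation = c("warn", "error")) {
  on_separation <- match.arg(on_separation)
  d <- design$data
  terms <- setdiff(design$terms, character(0))
  if (length(unique(d$persisted[!is.na(d$persisted)])) < 2L) {
    stop_husegment("outcome is constant; cannot fit")
  }
  # factor levels with no observations carry no information: drop them so
  # they appear as blank (not aliased) rows in reports
  for (tm in terms) {
    if (is.factor(d[[tm]])) d[[tm]] <- droplevels(d[[tm]])
  }
  rhs <- if (length(terms)) paste(terms, collapse = " + ") else "1"
  fml <- stats::as.formula(paste("persisted ~", rhs))
  fit <- stats::glm(fml, family = stats::binomial(), data = d,
                    control = stats::glm.control(epsilon = 1e-8, maxit = 100))
  if (!fit$converged) {
    stop_husegment("logistic fit did not converge")
  }
  cf <- stats::coef(fit)
  aliased <- is.na(cf)
  if (any(aliased)) {
    warning("collinear column(s) dropped: ",
            paste(names(cf)[aliased], collapse = ", "), call. = FALSE)
  }
  big <- !aliased & abs(cf) > 15 & names(cf) != "(Intercept)"
  if (any(big)) {
    msg <- paste0("apparent separation (|log-odds| > 15) in term(s): ",
                  paste(names(cf)[big], collapse = ", "))
    if (on_separation == "error") stop_husegment(msg)
    warning(msg, call. = FALSE)
  }
  ll <- as.numeric(stats::logLik(fit))
  y <- d$persisted[!is.na(d$persisted)]
  p0 <- mean(y)
  null_ll <- sum(y) * log(p0) + sum(1 - y) * log(1 - p0)
  se <- summary(fit)$coefficients[, "Std. Error"]
  z <- stats::qnorm(1 - (1 - ci_level) / 2)
  est <- cf[!aliased]
  keep <- names(est) != "(Intercept)"
  or_table <- data.frame(
    term = names(est)[keep],
    or = exp(est[keep]),
    lo = exp(est[keep] - z * se[names(est)[keep]]),
    hi = exp(est[keep] + z * se[names(est)[keep]]),
    stringsAsFactors = FALSE)
  rownames(or_table) <- NULL
  mcfadden <- if (length(terms)) 1 - ll / null_ll else 0
  structure(list(
    glm = fit, terms = terms, forced = design$forced %||% character(0),
    coefficients = cf, or_table = or_table, ci_level = ci_level,
    loglik = ll, null_loglik = null_ll,
    deviance = -2 * ll, df_residual = fit$df.residual,
    mcfadden_r2 = mcfadden, n = stats::nobs(fit)
  ), class = "hu_logit")
}

#' @export
print.hu_logit <- function(x, ...) {
  cat(sprintf("Persistence logistic model: %d obs, terms: %s\n", x$n,
              paste(x$terms, collapse = ", ")))
  cat(sprintf("logLik %.2f  deviance %.2f  df %d  McFadden R2 %.4f\n",
              x$loglik, x$deviance, x$df_residual, x$mcfadden_r2))
  invisible(x)
}

#' @export
summary.hu_logit <- function(object, ...) {
  tab <- object$or_table
  tab$or <- round(tab$or, 2)
  tab$lo <- round(tab$lo, 2)
  tab$hi <- round(tab$hi, 2)
  cat(sprintf("Odds ratios with %g%% Wald confidence intervals (n = %d):\n",
              100 * object$ci_level, object$n))
  print(tab, row.names = FALSE)
  cat(sprintf("McFadden R2: %.4f\n", object$mcfadden_r2))
  invisible(tab)
}

#' @export
coef.hu_logit <- function(object, ...) object$coefficients

#' @export
logLik.hu_logit <- function(object, ...) stats::logLik(object$glm)

#' @export
predict.hu_logit <- function(object, newdata = NULL, type = "response", ...) {
  if (is.null(newdata)) {
    stats::predict(object$glm, type = type, ...)
  } else {
    stats::predict(object$glm, newdata = newdata, type = type, ...)
  }
}

#' Factor-level backward elimination
#'
#' Starting from the full design, repeatedly tests each removable factor
#' with a factor-level likelihood-ratio test (all dummy levels jointly, via
#' a single-term deletion chi-square test), removes the factor with the
#' largest p-value at or above `alpha`, refits, and stops when every
#' removable factor is significant at `alpha`. The utilizer-group exposure
#' (and any other forced term) is never eliminated. One factor is removed
#' per iteration, worst first.
#'
#' @param design An [build_design()] result.
#' @param alpha Significance level for retention (default 0.001).
#' @param forced Terms never removed (defaults to the design's forced
#'   terms).
#' @param ci_level Confidence level passed to [fit_logistic()].
#' @return List with `fit` (final `hu_logit`), `trace` (`data.frame` of
#'   removals: step, term, p_value) and `design` (the reduced design).
#' @export
backward_eliminate <- function(design, alpha = 0.001,
                               forced = design$forced, ci_level = 0.99) {
  cur <- design
  trace <- data.frame(step = integer(0), term = character(0),
                      p_value = numeric(0), stringsAsFactors = FALSE)
  step <- 0L
  repeat {
    fit <- fit_logistic(cur, ci_level = ci_level)
    removable <- setdiff(cur$terms, forced)
    if (!length(removable)) break
    scope <- stats::as.formula(paste("~", paste(removable, collapse = " + ")))
    dr <- stats::drop1(fit$glm, scope = scope, test = "Chisq")
    pv <- dr[["Pr(>Chi)"]]
    names(pv) <- rownames(dr)
    pv <- pv[removable]
    worst <- which.max(pv)
    if (length(worst) == 0L || pv[worst] < alpha) break
    step <- step + 1L
    trace <- rbind(trace, data.frame(step = step,
                                     term = names(pv)[worst],
                                     p_value = unname(pv[worst]),
                                     stringsAsFactors = FALSE))
    cur$terms <- setdiff(cur$terms, names(pv)[worst])
  }
  list(fit = fit, trace = trace, design = cur)
}

#' Likelihood-ratio test between nested persistence models
#'
#' @param nested,full `hu_logit` fits on the same observations, with the
#'   nested model's terms a subset of the full model's.
#' @return List with `chi2` (twice the log-likelihood difference), `df`
#'   (parameter-count difference) and `p` (upper chi-square tail).
#' @export
likelihood_ratio_test <- function(nested, full) {
  stopifnot(inherits(nested, "hu_logit"), inherits(full, "hu_logit"))
  if (!all(nested$terms %in% full$terms)) {
    stop_husegment("models are not nested (term sets)")
  }
  if (nested$n != full$n) {
    stop_husegment("models were fitted on different numbers of observations")
  }
  chi2 <- 2 * (full$loglik - nested$loglik)
  if (chi2 < 0 && chi2 > -1e-8) chi2 <- 0
  if (chi2 < 0) stop_husegment("full model has lower likelihood; not nested fits")
  df <- (full$n - full$df_residual) - (nested$n - nested$df_residual)
  p <- if (df == 0L) {
    # identical parameterizations: no evidence either way
    if (chi2 <= 1e-8) 1 else 0
  } else {
    stats::pchisq(chi2, df = df, lower.tail = FALSE)
  }
  list(chi2 = chi2, df = df, p = p)
}

#' Fit the staged persistence models
#'
#' Fits Model 0 (utilizer group only), Model 1 (Model 0 adjusted for
#' socio-demographics and multi-morbidity, backward-eliminated at `alpha`)
#' and Model 2 (Model 1 further adjusted for the common high-utilizer
#' conditions, backward-eliminated at `alpha`), with the group exposure
#' forced into every model, plus the likelihood-ratio tests between
#' successive models. Models 1 and 2 are fitted on the same exclusion set
#' (Year-1 decedents, missing socio-demographics); Model 0 keeps the same
#' observations so the staged models are comparable.
#'
#' @param seg An [hu_segment()] result.
#' @param patients A validated patient table.
#' @param scores `data.frame` with `patient_id`, `ccmi`, `pps`.
#' @param conditions [assign_conditions()] output.
#' @param common_conditions [common_hu_conditions()] output; computed from
#'   `conditions` rankings when `NULL`.
#' @param alpha Elimination significance level (default 0.001).
#' @return An object of class `hu_persistence`: list with fits `m0`, `m1`,
#'   `m2`, elimination traces, LRTs `lrt_01`, `lrt_12` and the
#'   [report_models()] table.
#' @export
hu_persistence <- function(seg, patients, scores, conditions,
                           common_conditions = NULL, alpha = 0.001) {
  if (is.null(common_conditions)) {
    rk <- rank_conditions(seg, conditions, mode = "patients_ever", k = 5)
    common_conditions <- common_hu_conditions(rk)
  }
  d1 <- build_design(seg, patients, scores, model = "m1")
  # Model 0 on the same analysis rows as Models 1-2, group exposure only
  d0 <- d1
  d0$terms <- "hu_group"
  d0$model <- "m0"
  m0 <- fit_logistic(d0)
  e1 <- backward_eliminate(d1, alpha = alpha)
  d2 <- build_design(seg, patients, scores, model = "m2",
                     conditions = conditions,
                     common_conditions = common_conditions)
  cond_labels <- attr(d2$terms, "condition_labels")
  d2$terms <- c(e1$design$terms,
                grep("^cond_", d2$terms, value = TRUE))
  # Model 2 retains Model 1's adjustment set; only the added condition
  # indicators are elimination candidates, keeping the staged models nested
  # (and the Model 1 vs Model 2 likelihood-ratio test valid)
  e2 <- backward_eliminate(d2, alpha = alpha, forced = e1$design$terms)
  lrt_01 <- likelihood_ratio_test(m0, e1$fit)
  lrt_12 <- likelihood_ratio_test(e1$fit, e2$fit)
  out <- list(m0 = m0, m1 = e1$fit, m2 = e2$fit,
              trace_m1 = e1$trace, trace_m2 = e2$trace,
              lrt_01 = lrt_01, lrt_12 = lrt_12,
              common_conditions = common_conditions,
              condition_labels = cond_labels,
              alpha = alpha)
  out$report <- report_models(out)
  class(out) <- "hu_persistence"
  out
}

#' @export
print.hu_persistence <- function(x, ...) {
  cat("Staged persistence models (odds ratios, 99% CI)\n\n")
  print(x$report, row.names = FALSE)
  invisible(x)
}

#' Tabulate the staged models
#'
#' One row per factor level with the formatted odds ratio and confidence
#' interval per model; cells are blank where a factor was eliminated,
#' reference levels print `1.00`. Footer rows report McFadden's
#' pseudo-R-squared, residual deviance, residual degrees of freedom and the
#' likelihood-ratio test p-values between successive models.
#'
#' @param fits An `hu_persistence` object (or a list with `m0`, `m1`, `m2`,
#'   `lrt_01`, `lrt_12`).
#' @return A `data.frame` with columns `factor`, `level`, `model0`,
#'   `model1`, `model2`.
#' @export
report_models <- function(fits) {
  m <- list(fits$m0, fits$m1, fits$m2)
  cond_labels <- fits$condition_labels
  fmt <- function(fit, coef_name) {
    tab <- fit$or_table
    i <- match(coef_name, tab$term)
    if (is.na(i)) return("")
    # a separation-degenerate level has no meaningful estimate
    if (!all(is.finite(c(tab$or[i], tab$lo[i], tab$hi[i]))) ||
        abs(log(tab$or[i])) > 15 || tab$hi[i] > 1e6 || tab$lo[i] < 1e-6) {
      return("n.e.")
    }
    sprintf("%.2f (%.2f-%.2f)", tab$or[i], tab$lo[i], tab$hi[i])
  }
  factor_rows <- function(fname, levels, ref) {
    rows <- list()
    present <- vapply(m, function(fit) fname %in% fit$terms, logical(1))
    rows[[ref]] <- data.frame(
      factor = fname, level = ref,
      model0 = if (present[1]) "1.00" else "",
      model1 = if (present[2]) "1.00" else "",
      model2 = if (present[3]) "1.00" else "", stringsAsFactors = FALSE)
    for (lv in setdiff(levels, ref)) {
      cn <- paste0(fname, lv)
      rows[[lv]] <- data.frame(
        factor = fname, level = lv,
        model0 = if (present[1]) fmt(m[[1]], cn) else "",
        model1 = if (present[2]) fmt(m[[2]], cn) else "",
        model2 = if (present[3]) fmt(m[[3]], cn) else "",
        stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  }
  num_row <- function(tname, label = tname) {
    data.frame(
      factor = label, level = "",
      model0 = if (tname %in% m[[1]]$terms) fmt(m[[1]], tname) else "",
      model1 = if (tname %in% m[[2]]$terms) fmt(m[[2]], tname) else "",
      model2 = if (tname %in% m[[3]]$terms) fmt(m[[3]], tname) else "",
      stringsAsFactors = FALSE)
  }
  rows <- list(factor_rows("hu_group", hu_group_levels(), "Non-HU"))
  if (length(m[[2]]$terms) > 1L || length(m[[3]]$terms) > 1L) {
    rows <- c(rows, list(
      num_row("age", "Age at first visit"),
      num_row("ccmi", "CCMI"),
      num_row("pps", "PPS"),
      factor_rows("gender", c("female", "male"), "female"),
      factor_rows("race", c("chinese", "indian", "malay", "others"), "chinese"),
      factor_rows("nationality", c("foreigner", "singaporean"), "foreigner"),
      factor_rows("treatment_tier",
                  c("subsidised_only", "unsubsidised_only", "both"),
                  "subsidised_only"),
      factor_rows("housing",
                  c("rental_1_2room", "flat_3room_plus", "private", "unknown"),
                  "rental_1_2room")))
  }
  if (!is.null(cond_labels)) {
    cond_rows <- lapply(names(cond_labels), function(cn) {
      data.frame(factor = "condition", level = unname(cond_labels[cn]),
                 model0 = "",
                 model1 = "",
                 model2 = if (cn %in% m[[3]]$terms) fmt(m[[3]], cn) else "",
                 stringsAsFactors = FALSE)
    })
    cond_rows <- cond_rows[vapply(cond_rows, function(r) nzchar(r$model2),
                                  logical(1))]
    rows <- c(rows, cond_rows)
  }
  footer <- data.frame(
    factor = c("McFadden R2", "Residual deviance", "Residual df", "LRT p"),
    level = "",
    model0 = c(sprintf("%.4f", m[[1]]$mcfadden_r2),
               sprintf("%.1f", m[[1]]$glm$deviance),
               sprintf("%d", m[[1]]$df_residual), ""),
    model1 = c(sprintf("%.4f", m[[2]]$mcfadden_r2),
               sprintf("%.1f", m[[2]]$glm$deviance),
               sprintf("%d", m[[2]]$df_residual),
               format_p(fits$lrt_01$p)),
    model2 = c(sprintf("%.4f", m[[3]]$mcfadden_r2),
               sprintf("%.1f", m[[3]]$glm$deviance),
               sprintf("%d", m[[3]]$df_residual),
               format_p(fits$lrt_12$p)),
    stringsAsFactors = FALSE)
  out <- rbind(do.call(rbind, rows), footer)
  rownames(out) <- NULL
  out
}

#' @noRd
format_p <- function(p) {
  if (p < 0.001) "< 0.001" else sprintf("%.3f", p)
}
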