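#' Define a patient archetype for the synthetic cohort generator
#'
#' An archetype is a latent patient class with its own annual visit rates,
#' length-of-stay and cost distributions, diagnosis pool, medication volume
#' and first-year death hazard. A cohort is a mixture of archetypes; each
#' patient also draws a mean-one log-normal frailty multiplier (sd
#' `frailty_sd` on the log scale) that scales all visit rates in both
#' observation years, producing overdispersed counts and year-to-year
#' persistence correlation.
#'
#' @param name Archetype label.
#' @param mix_weight Mixture probability; weights over all archetypes in a
#'   config must sum to 1.
#' @param admission_rate,soc_rate,ed_rate,therapy_rate Mean events per year
#'   for inpatient admissions, specialist outpatient (SOC) visits, emergency
#'   (ED) attendances and therapy visits.
#' @param los_meanlog,los_sdlog Log-normal parameters for length of stay per
#'   admission; stays are discretized with a 1-day minimum.
#' @param cost_meanlog,cost_sdlog Log-normal parameters for the billed cost
#'   (S$) of an inpatient visit; ambulatory visits are scaled down by fixed
#'   setting factors (SOC 0.15, ED 0.2, therapy 0.1).
#' @param dx_pool `data.frame` with columns `code`, `weight`: the primary
#'   diagnosis pool sampled per visit.
#' @param med_count_range Integer range (length 2) of dispensed medication
#'   codes per visit.
#' @param death_hazard_year1 Probability of death within the first year.
#' @param frailty_sd Log-scale standard deviation of the patient frailty.
#' @param subsidised_prob Probability a visit is billed at the subsidised
#'   rate.
#' @param short_stay_frac Fraction of inpatient stays that are short stays
#'   (day surgery / endoscopy style; excluded from LOS aggregation).
#' @param age_range Age range (years) at cohort entry.
#' @param female_prob Probability of female gender.
#' @param year2_decay Multiplier applied to all visit rates in Year 2
#'   (default 1 = stable utilization). Values below 1 model recovery /
#'   regression to the mean after an acute first year, so that most high
#'   utilizers do not persist — the dominant longitudinal pattern in
#'   hospital cohorts.
#' @return An object of class `archetype_spec`.
#' @seealso [default_archetypes()], [cohort_config()], [generate_cohort()]
#' @export
archetype_spec <- function(name, mix_weight, admission_rate, soc_rate, ed_rate,
                           therapy_rate = 0.2,
                           los_meanlog = log(4), los_sdlog = 0.6,
                           cost_meanlog = log(3000), cost_sdlog = 0.9,
                           dx_pool = data.frame(code = "R69", weight = 1),
                           med_count_range = c(0L, 5L),
                           death_hazard_year1 = 0.01,
                           frailty_sd = 0.5,
                           subsidised_prob = 0.7,
                           short_stay_frac = 0.15,
                           age_range = c(21, 85),
                           female_prob = 0.5,
                           year2_decay = 1) {
  rates <- c(mix_weight, admission_rate, soc_rate, ed_rate, therapy_rate)
  if (any(!is.finite(rates)) || any(rates < 0)) {
    stop_husegment("archetype '", name, "': weights and rates must be finite and >= 0")
  }
  probs <- c(death_hazard_year1, subsidised_prob, short_stay_frac, female_prob)
  if (any(probs < 0 | probs > 1)) {
    stop_husegment("archetype '", name, "': probabilities must lie in [0, 1]")
  }
  if (frailty_sd < 0) stop_husegment("frailty_sd must be >= 0")
  if (year2_decay < 0) stop_husegment("year2_decay must be >= 0")
  if (!is.data.frame(dx_pool) || !all(c("code", "weight") %in% names(dx_pool)) ||
      nrow(dx_pool) == 0L) {
    stop_husegment("dx_pool must be a non-empty data.frame with code, weight")
  }
  if (length(med_count_range) != 2L || med_count_range[1] > med_count_range[2] ||
      med_count_range[1] < 0) {
    stop_husegment("med_count_range must be a non-decreasing pair of counts >= 0")
  }
  structure(list(
    name = name, mix_weight = mix_weight,
    admission_rate = admission_rate, soc_rate = soc_rate, ed_rate = ed_rate,
    therapy_rate = therapy_rate,
    los_meanlog = los_meanlog, los_sdlog = los_sdlog,
    cost_meanlog = cost_meanlog, cost_sdlog = cost_sdlog,
    dx_pool = dx_pool,
    med_count_range = as.integer(med_count_range),
    death_hazard_year1 = death_hazard_year1,
    frailty_sd = frailty_sd,
    subsidised_prob = subsidised_prob,
    short_stay_frac = short_stay_frac,
    age_range = age_range,
    female_prob = female_prob,
    year2_decay = year2_decay
  ), class = "archetype_spec")
}

#' Default archetype mixture
#'
#' Five archetypes chosen to reproduce, qualitatively, the utilization
#' structure of a hospital-based adult cohort: a dominant routine low-use
#' class, a cardiac one-off high-cost class, a frail elderly multimorbid
#' class with heavy inpatient use and high mortality, a small psychiatric
#' long-stay class, and a high-SOC ambulatory class. The mixture is
#' qualitative (non-HU patients dominate; psychiatric stays are long but
#' cheap; high-SOC patients are mostly ambulatory), not a fit to any real
#' institution.
#'
#' @return A list of [archetype_spec()] objects whose weights sum to 1.
#' @export
default_archetypes <- function() {
  list(
    archetype_spec(
      "routine_low_use", mix_weight = 0.840,
      admission_rate = 0.08, soc_rate = 1.1, ed_rate = 0.7, therapy_rate = 0.2,
      los_meanlog = log(3), los_sdlog = 0.6,
      cost_meanlog = log(2500), cost_sdlog = 0.9,
      dx_pool = data.frame(
        code = c("S00", "J06", "S93", "K52", "S61", "K29", "S52", "I10",
                 "O80", "H25"),
        weight = c(4, 3, 3, 2.5, 2, 1.5, 1.5, 1, 1, 0.5)),
      med_count_range = c(0L, 5L), death_hazard_year1 = 0.012,
      frailty_sd = 0.7, subsidised_prob = 0.75, short_stay_frac = 0.30,
      age_range = c(18, 85), female_prob = 0.41, year2_decay = 1),
    archetype_spec(
      "cardiac_one_off", mix_weight = 0.050,
      admission_rate = 1.1, soc_rate = 3, ed_rate = 1.2, therapy_rate = 0.3,
      los_meanlog = log(6), los_sdlog = 0.6,
      cost_meanlog = log(9000), cost_sdlog = 0.8,
      dx_pool = data.frame(
        code = c("I25", "I21", "I63", "I10", "S72", "J18"),
        weight = c(3, 3, 1, 1, 0.7, 0.5)),
      med_count_range = c(4L, 16L), death_hazard_year1 = 0.09,
      frailty_sd = 0.5, subsidised_prob = 0.6, short_stay_frac = 0.10,
      age_range = c(42, 80), female_prob = 0.33, year2_decay = 0.12),
    archetype_spec(
      "frail_elderly", mix_weight = 0.030,
      admission_rate = 2.3, soc_rate = 6.5, ed_rate = 2, therapy_rate = 0.5,
      los_meanlog = log(11), los_sdlog = 0.8,
      cost_meanlog = log(14000), cost_sdlog = 0.8,
      dx_pool = data.frame(
        code = c("I63", "J18", "N39", "I25", "A41", "N17", "I10", "I50"),
        weight = c(2, 2, 1.5, 1, 1, 1, 1, 0.8)),
      med_count_range = c(8L, 30L), death_hazard_year1 = 0.20,
      frailty_sd = 0.5, subsidised_prob = 0.8, short_stay_frac = 0.08,
      age_range = c(55, 92), female_prob = 0.42, year2_decay = 0.45),
    archetype_spec(
      "psych_long_stay", mix_weight = 0.004,
      admission_rate = 1.3, soc_rate = 8, ed_rate = 1, therapy_rate = 1,
      los_meanlog = log(20), los_sdlog = 0.5,
      cost_meanlog = log(6000), cost_sdlog = 0.7,
      dx_pool = data.frame(
        code = c("F32", "F20", "R69", "S06"),
        weight = c(3, 2, 0.7, 0.5)),
      med_count_range = c(2L, 10L), death_hazard_year1 = 0.015,
      frailty_sd = 0.4, subsidised_prob = 0.85, short_stay_frac = 0.05,
      age_range = c(21, 60), female_prob = 0.5, year2_decay = 0.5),
    archetype_spec(
      "high_soc_ambulatory", mix_weight = 0.076,
      admission_rate = 0.25, soc_rate = 11, ed_rate = 0.4, therapy_rate = 0.4,
      los_meanlog = log(4), los_sdlog = 0.6,
      cost_meanlog = log(3500), cost_sdlog = 0.9,
      dx_pool = data.frame(
        code = c("O80", "H25", "O72", "S52", "K29", "C50", "N97", "I10",
                 "H57", "T30"),
        weight = c(2.5, 1.5, 1.5, 1.3, 1, 1.2, 1, 0.8, 0.6, 0.3)),
      med_count_range = c(1L, 8L), death_hazard_year1 = 0.006,
      frailty_sd = 0.6, subsidised_prob = 0.5, short_stay_frac = 0.20,
      age_range = c(23, 70), female_prob = 0.62, year2_decay = 0.55)
  )
}

#' Configure a synthetic cohort
#'
#' @param n_patients Number of patients to simulate (>= 1).
#' @param study_start,study_end Enrolment window (ISO dates). Each patient's
#'   latent entry date is uniform over the window; visits are generated over
#'   the two years following entry.
#' @param archetypes List of [archetype_spec()] objects; mixture weights
#'   must sum to 1 (tolerance 1e-9).
#' @param seed Default RNG seed used by [generate_cohort()].
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients,
                          study_start = "2006-01-01",
                          study_end = "2013-01-01",
                          archetypes = default_archetypes(),
                          seed = 1L) {
  if (length(archetypes) == 0L) {
    stop_husegment("config must define at least one archetype")
  }
  if (!all(vapply(archetypes, inherits, logical(1), "archetype_spec"))) {
    stop_husegment("archetypes must be archetype_spec objects")
  }
  if (!is.numeric(n_patients) || n_patients < 1) {
    stop_husegment("n_patients must be >= 1")
  }
  study_start <- as.Date(study_start)
  study_end <- as.Date(study_end)
  if (!(study_start < study_end)) {
    stop_husegment("study_start must precede study_end")
  }
  w <- vapply(archetypes, `[[`, numeric(1), "mix_weight")
  if (abs(sum(w) - 1) > 1e-9) {
    stop_husegment("archetype mix_weights must sum to 1 (got ", sum(w), ")")
  }
  nm <- vapply(archetypes, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop_husegment("archetype names must be unique")
  names(archetypes) <- nm
  structure(list(
    n_patients = as.integer(n_patients),
    study_start = study_start, study_end = study_end,
    archetypes = archetypes, seed = as.integer(seed),
    planting = NULL
  ), class = "cohort_config")
}

#' Plant persistence effects into a cohort configuration
#'
#' Rewrites the Year-2 behaviour of the named archetypes so that, in
#' expectation, their patients persist as high utilizers with odds scaled by
#' the given multiplier relative to a reference odds (`base_rate`,
#' interpreted as the persistence probability of the low-use reference
#' archetype). This makes the planted odds ratios recoverable by a Model-0
#' style logistic regression, enabling parameter-recovery experiments.
#'
#' Mechanism: each patient of a planted archetype draws a latent persist
#' flag with probability `p` where `odds(p) = multiplier x odds(base_rate)`.
#' Flagged patients receive Year-2 utilization far above any plausible
#' cohort threshold; unflagged patients receive near-zero Year-2
#' utilization. Archetypes not named keep their natural Year-2 behaviour
#' (same frailty-scaled rates as Year 1). If every supplied multiplier
#' equals 1 the config is returned unchanged (Year-2 generation identical in
#' distribution to Year 1).
#'
#' @param config A [cohort_config()].
#' @param odds_multipliers Named positive numeric vector; names are
#'   archetype names.
#' @param base_rate Reference persistence probability (default 0.02).
#' @return A modified `cohort_config`.
#' @export
plant_persistence <- function(config, odds_multipliers, base_rate = 0.02) {
  stopifnot(inherits(config, "cohort_config"))
  if (is.null(names(odds_multipliers)) ||
      !all(names(odds_multipliers) %in% names(config$archetypes))) {
    stop_husegment("odds_multipliers must be named after config archetypes")
  }
  if (any(odds_multipliers <= 0)) {
    stop_husegment("odds multipliers must be positive")
  }
  if (base_rate <= 0 || base_rate >= 1) {
    stop_husegment("base_rate must be in (0, 1)")
  }
  if (all(odds_multipliers == 1)) {
    return(config)
  }
  config$planting <- list(
    multipliers = odds_multipliers,
    base_rate = base_rate,
    persist_prob = stats::plogis(stats::qlogis(base_rate) + log(odds_multipliers)),
    heavy = list(admission_rate = 3, soc_rate = 30, ed_rate = 2,
                 therapy_rate = 0.3, los_meanlog = log(25), los_sdlog = 0.3,
                 cost_meanlog = log(40000), cost_sdlog = 0.4),
    quiet = list(admission_rate = 0.03, soc_rate = 0.08, ed_rate = 0.05,
                 therapy_rate = 0.02, los_meanlog = log(2), los_sdlog = 0.3,
                 cost_meanlog = log(150), cost_sdlog = 0.5)
  )
  config
}

#' Configuration for the planted-odds recovery experiment
#'
#' A three-archetype mixture built for parameter-recovery validation of the
#' persistence models: a dominant low-use class, a high-SOC ambulatory class
#' and a cardiac high-cost class, with rate distributions separated widely
#' enough that each realized utilizer group is dominated by a single
#' archetype (the default mixture, designed for realism, overlaps too much
#' for planted odds to be identified at the group level). Persistence odds
#' multipliers are planted via [plant_persistence()]: 8 for the high-SOC
#' archetype, 2 for the cardiac archetype, 1 (the reference rate) for the
#' low-use class, so a Model-0 logistic fit should recover an odds ratio
#' near 8 for the SOC group and the qualitative ordering
#' high-SOC groups > other HU groups > 1.
#'
#' @param n_patients Cohort size (default 20000).
#' @param seed Default seed.
#' @param multipliers Planted odds multipliers (named as the three
#'   archetypes).
#' @param base_rate Reference persistence probability.
#' @return A planted `cohort_config`.
#' @export
recovery_config <- function(n_patients = 20000, seed = 1,
                            multipliers = c(low_use = 1, high_soc = 8,
                                            cardiac = 2),
                            base_rate = 0.02) {
  arch <- list(
    archetype_spec(
      "low_use", mix_weight = 0.865,
      admission_rate = 0.05, soc_rate = 1, ed_rate = 0.7, therapy_rate = 0.1,
      los_meanlog = log(3), los_sdlog = 0.5,
      cost_meanlog = log(2000), cost_sdlog = 0.7,
      med_count_range = c(0L, 4L), death_hazard_year1 = 0.01,
      frailty_sd = 0.4, age_range = c(25, 80)),
    archetype_spec(
      "high_soc", mix_weight = 0.085,
      admission_rate = 0.2, soc_rate = 25, ed_rate = 0.5, therapy_rate = 0.3,
      los_meanlog = log(4), los_sdlog = 0.5,
      cost_meanlog = log(4000), cost_sdlog = 0.7,
      med_count_range = c(1L, 8L), death_hazard_year1 = 0.005,
      frailty_sd = 0.3, age_range = c(25, 70)),
    archetype_spec(
      "cardiac", mix_weight = 0.05,
      admission_rate = 1.2, soc_rate = 1, ed_rate = 1, therapy_rate = 0.2,
      los_meanlog = log(3), los_sdlog = 0.5,
      cost_meanlog = log(12000), cost_sdlog = 0.7,
      med_count_range = c(3L, 12L), death_hazard_year1 = 0.06,
      frailty_sd = 0.4, age_range = c(45, 80)))
  cfg <- cohort_config(n_patients, archetypes = arch, seed = seed)
  plant_persistence(cfg, multipliers, base_rate = base_rate)
}

# billed-cost scaling of ambulatory settings relative to an inpatient visit
visit_cost_factor <- c(inpatient = 1, soc = 0.15, ed = 0.2, therapy = 0.1)

#' Generate a synthetic visit- and patient-level cohort
#'
#' Simulates a two-year visit history for `config$n_patients` patients drawn
#' from the configured archetype mixture. Event counts per setting and year
#' are mixed-Poisson with a patient-level mean-one log-normal frailty shared
#' across both years; inpatient stays draw a discretized log-normal length
#' of stay (minimum 1 day) and a configurable fraction are flagged as short
#' stays; per-visit billed costs are log-normal with setting-specific scale
#' factors; deaths within Year 1 truncate all subsequent visits. Each
#' patient with any Year-1 utilization has their earliest visit placed at
#' the entry date, which downstream becomes the index visit anchoring the
#' observation windows. Identical `(config, seed)` yields byte-identical
#' output tables.
#'
#' @param config A [cohort_config()].
#' @param seed RNG seed (defaults to `config$seed`). The caller's RNG state
#'   is preserved.
#' @return A list with elements `patients` and `visits` (validated tables as
#'   from [read_patients()] / [read_visits()]) and `meta` (per-patient
#'   archetype assignment, frailty, entry date and, when persistence effects
#'   are planted, the latent persist flag).
#' @export
generate_cohort <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "cohort_config"))
  if (length(config$archetypes) == 0L) {
    stop_husegment("config must define at least one archetype")
  }
  with_seed(seed, generate_cohort_impl(config))
}

#' @noRd
generate_cohort_impl <- function(config) {
  arch <- config$archetypes
  k <- length(arch)
  n <- config$n_patients
  afield <- function(f) vapply(arch, `[[`, numeric(1), f)
  aint <- function(f, i) vapply(arch, function(a) as.numeric(a[[f]][i]), numeric(1))

  n_days <- as.integer(config$study_end - config$study_start)

  # -- patient-level draws (fixed order for determinism) --
  a_idx <- sample.int(k, n, replace = TRUE, prob = afield("mix_weight"))
  sd_a <- afield("frailty_sd")[a_idx]
  frailty <- exp(stats::rnorm(n, 0, sd_a) - sd_a^2 / 2)
  entry <- config$study_start + floor(stats::runif(n) * n_days)
  age <- stats::runif(n, aint("age_range", 1)[a_idx], aint("age_range", 2)[a_idx])
  birth <- entry - floor(age * 365.25)
  gender <- ifelse(stats::runif(n) < afield("female_prob")[a_idx],
                   "female", "male")
  race <- sample(c("chinese", "indian", "malay", "others"), n, TRUE,
                 prob = c(0.58, 0.13, 0.12, 0.17))
  nationality <- sample(c("singaporean", "foreigner"), n, TRUE,
                        prob = c(0.9, 0.1))
  housing <- sample(c("rental_1_2room", "flat_3room_plus", "private", "unknown"),
                    n, TRUE, prob = c(0.026, 0.633, 0.118, 0.223))
  died <- stats::runif(n) < afield("death_hazard_year1")[a_idx]
  death_date <- as.Date(rep(NA_integer_, n), origin = "1970-01-01")
  death_date[died] <- entry[died] + floor(stats::runif(sum(died)) * 365)

  # latent persistence flag: 0 = natural year 2, 1 = planted heavy, 2 = planted quiet
  plant_state <- integer(n)
  z <- rep(NA, n)
  if (!is.null(config$planting)) {
    pp <- config$planting$persist_prob
    planted_arch <- match(names(pp), names(arch))
    u <- stats::runif(n)
    for (j in seq_along(planted_arch)) {
      sel <- a_idx == planted_arch[j]
      z[sel] <- u[sel] < pp[j]
      plant_state[sel] <- ifelse(z[sel], 1L, 2L)
    }
  }

  # -- per-setting, per-year rates --
  settings <- c("inpatient", "soc", "ed", "therapy")
  rate_field <- c(inpatient = "admission_rate", soc = "soc_rate",
                  ed = "ed_rate", therapy = "therapy_rate")
  lam1 <- matrix(unlist(lapply(settings, function(s) {
    afield(rate_field[s])[a_idx] * frailty
  })), nrow = n, dimnames = list(NULL, settings))
  # Year-1 counts are drawn first: a planted patient with no Year-1
  # utilization has no index year to persist from, so the heavy Year-2
  # profile is withheld (they fall back to the quiet profile and, with no
  # visits at all, never enter the cohort)
  cnt1 <- matrix(0L, nrow = n, ncol = length(settings),
                 dimnames = list(NULL, settings))
  for (s in settings) cnt1[, s] <- stats::rpois(n, lam1[, s])
  if (!is.null(config$planting)) {
    plant_state[plant_state == 1L & rowSums(cnt1) == 0L] <- 2L
  }
  lam2 <- lam1 * afield("year2_decay")[a_idx]
  if (!is.null(config$planting)) {
    hv <- config$planting$heavy
    qt <- config$planting$quiet
    for (s in settings) {
      lam2[plant_state == 1L, s] <- hv[[rate_field[s]]]
      lam2[plant_state == 2L, s] <- qt[[rate_field[s]]]
    }
  }
  cnt2 <- matrix(0L, nrow = n, ncol = length(settings),
                 dimnames = list(NULL, settings))
  for (s in settings) cnt2[, s] <- stats::rpois(n, lam2[, s])

  # -- visit skeleton --
  pieces <- vector("list", 2L * length(settings))
  ii <- 1L
  for (year in 1:2) {
    cnt_y <- if (year == 1) cnt1 else cnt2
    for (s in settings) {
      cnt <- cnt_y[, s]
      m <- sum(cnt)
      if (m > 0) {
        pid <- rep.int(seq_len(n), cnt)
        pieces[[ii]] <- data.frame(
          p = pid, year = year, type = s,
          day = (year - 1L) * 365L + floor(stats::runif(m) * 365),
          stringsAsFactors = FALSE)
      }
      ii <- ii + 1L
    }
  }
  v <- do.call(rbind, pieces[!vapply(pieces, is.null, logical(1))])

  patients <- data.frame(
    patient_id = sprintf("P%06d", seq_len(n)),
    birth_date = birth, gender = gender, race = race,
    nationality = nationality, housing_type = housing,
    death_date = death_date, stringsAsFactors = FALSE)
  meta <- data.frame(
    patient_id = patients$patient_id,
    archetype = names(arch)[a_idx],
    frailty = frailty, entry_date = entry,
    planted_persist = z, stringsAsFactors = FALSE)

  if (is.null(v) || nrow(v) == 0L) {
    return(list(patients = patients, visits = empty_visits(), meta = meta))
  }

  # anchor each patient's earliest Year-1 visit at the entry date (index visit)
  y1 <- v$year == 1L
  if (any(y1)) {
    o <- order(v$p[y1], v$day[y1])
    first_of_p <- o[!duplicated(v$p[y1][o])]
    idx <- which(y1)[first_of_p]
    v$day[idx] <- 0L
  }

  nv <- nrow(v)
  va <- a_idx[v$p]                      # archetype per visit
  vstate <- ifelse(v$year == 2L, plant_state[v$p], 0L)

  # cost
  cm <- afield("cost_meanlog")[va]
  cs <- afield("cost_sdlog")[va]
  if (!is.null(config$planting)) {
    cm[vstate == 1L] <- config$planting$heavy$cost_meanlog
    cs[vstate == 1L] <- config$planting$heavy$cost_sdlog
    cm[vstate == 2L] <- config$planting$quiet$cost_meanlog
    cs[vstate == 2L] <- config$planting$quiet$cost_sdlog
  }
  cost <- round(stats::rlnorm(nv, cm + log(visit_cost_factor[v$type]), cs), 2)

  # primary diagnosis: sample per archetype pool (config order, deterministic)
  dx <- character(nv)
  for (j in seq_len(k)) {
    sel <- which(va == j)
    if (length(sel)) {
      pool <- arch[[j]]$dx_pool
      dx[sel] <- sample(as.character(pool$code), length(sel), TRUE,
                        prob = pool$weight)
    }
  }

  # medications: fixed-width codes, vectorized assembly
  kmin <- aint("med_count_range", 1)[va]
  kmax <- aint("med_count_range", 2)[va]
  kmed <- kmin + floor(stats::runif(nv) * (kmax - kmin + 1))
  maxk <- max(kmed)
  meds <- character(nv)
  if (maxk > 0) {
    med_pool <- sprintf("M%03d", 1:150)
    mm <- matrix(sample(med_pool, nv * maxk, TRUE), nrow = nv)
    full <- do.call(paste, c(as.data.frame(mm, stringsAsFactors = FALSE),
                             list(sep = ";")))
    meds <- substr(full, 1L, pmax(0L, kmed * 5L - 1L))
  }

  subsidised <- stats::runif(nv) < afield("subsidised_prob")[va]

  # inpatient structure: LOS + short-stay flag
  is_ip <- v$type == "inpatient"
  lm <- afield("los_meanlog")[va]
  ls <- afield("los_sdlog")[va]
  if (!is.null(config$planting)) {
    lm[vstate == 1L] <- config$planting$heavy$los_meanlog
    ls[vstate == 1L] <- config$planting$heavy$los_sdlog
    lm[vstate == 2L] <- config$planting$quiet$los_meanlog
    ls[vstate == 2L] <- config$planting$quiet$los_sdlog
  }
  los <- pmax(1, ceiling(stats::rlnorm(nv, lm, ls)))
  short <- is_ip & (stats::runif(nv) < afield("short_stay_frac")[va])

  admission_date <- entry[v$p] + v$day
  discharge_date <- as.Date(rep(NA_integer_, nv), origin = "1970-01-01")
  discharge_date[is_ip] <- admission_date[is_ip] +
    ifelse(short[is_ip], 0, los[is_ip])

  # death truncation: no visit after death; stays clamp at the death date
  dd <- death_date[v$p]
  keep <- is.na(dd) | admission_date <= dd
  clamp <- keep & !is.na(dd) & !is.na(discharge_date) & discharge_date > dd
  discharge_date[clamp] <- dd[clamp]

  visits <- data.frame(
    patient_id = patients$patient_id[v$p],
    visit_id = NA_character_,
    visit_type = v$type,
    admission_date = admission_date,
    discharge_date = discharge_date,
    cost = cost,
    primary_diagnosis = dx,
    medications = meds,
    subsidised = subsidised,
    short_stay = is_ip & short,
    stringsAsFactors = FALSE)[keep, , drop = FALSE]

  ord <- order(visits$patient_id, visits$admission_date,
               match(visits$visit_type, settings), visits$cost)
  visits <- visits[ord, , drop = FALSE]
  visits$visit_id <- sprintf("V%08d", seq_len(nrow(visits)))
  rownames(visits) <- NULL

  list(patients = patients, visits = visits, meta = meta)
}

#' @noRd
empty_visits <- function() {
  data.frame(patient_id = character(0), visit_id = character(0),
             visit_type = character(0),
             admission_date = as.Date(character(0)),
             discharge_date = as.Date(character(0)),
             cost = numeric(0), primary_diagnosis = character(0),
             medications = character(0), subsidised = logical(0),
             short_stay = logical(0), stringsAsFactors = FALSE)
}

#' Write a generated cohort to a directory
#'
#' Writes `visits.csv`, `patients.csv` and a `manifest.json` recording the
#' seed, cohort size, archetype weights and a hash of the configuration.
#'
#' @param cohort Result of [generate_cohort()].
#' @param config The [cohort_config()] used.
#' @param dir Output directory (created if absent).
#' @param seed The seed used.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, config, dir, seed = config$seed) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_visits(cohort$visits, file.path(dir, "visits.csv"))
  write_patients(cohort$patients, file.path(dir, "patients.csv"))
  manifest <- list(
    seed = seed,
    n_patients = config$n_patients,
    n_visits = nrow(cohort$visits),
    study_start = format(config$study_start),
    study_end = format(config$study_end),
    archetypes = stats::setNames(
      lapply(config$archetypes, function(a) list(mix_weight = a$mix_weight)),
      names(config$archetypes)),
    config_hash = config_hash(config))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' @noRd
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  flat <- rapply(unclass(config), function(x) {
    if (inherits(x, "Date")) format(x) else x
  }, how = "replace")
  jsonlite::write_json(flat, tmp, auto_unbox = TRUE, force = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}
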