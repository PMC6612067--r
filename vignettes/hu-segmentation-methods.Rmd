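---
title: "Segmenting high healthcare utilizers and modelling their persistence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting high healthcare utilizers and modelling their persistence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(husegment)
```

## The problem

A small fraction of a hospital's patients accounts for a disproportionate
share of its cost and utilization. Because healthcare cost distributions are
strongly right-skewed, these *high utilizers* (HUs) are conventionally
defined as the patients above a high percentile — most commonly the 90th —
of a utilization metric. A single metric hides structure: a patient can be
expensive without long admissions, or occupy a bed for months at modest
cost, or consume intensive specialist outpatient care with no admissions at
all. `husegment` implements a multi-metric segmentation of a hospital
cohort and the longitudinal analysis of whether each segment *persists* in
high utilization the following year.

## The procedure

**Cohort and windows.** Each patient's *index visit* is their first visit
inside the enrolment window (defaults: 2006-01-01 to 2013-01-01, half-open).
Patients at least 21 completed years old at index are included. Two
fixed-length 365-day observation windows follow the index date:
`[index, index+365)` and `[index+365, index+730)`. Fixed-length windows,
rather than calendar years, make first- and second-year utilization
comparable across patients; we deliberately avoid leap-day special-casing.
A stay that spans a window boundary is attributed whole — cost and length
of stay — to the window containing its admission date; the rule is recorded
in the run manifest.

**Metrics.** Within each window the package aggregates, per patient: total
billed cost over all settings (inpatient, specialist outpatient clinic
(SOC), emergency (ED), therapy); inpatient admissions (short stays
included); total length of stay (LOS) in days, *excluding* short stays such
as day surgery and endoscopy, following the OECD convention for
hospital-stay statistics (a same-day non-short admission counts one day);
SOC visits; and ED attendances. ED attendance is deliberately *not* a
threshold metric: frequent ED users are only about 5% of a cohort, so a
90th-percentile cut on ED visits would not isolate them.

**Thresholds and groups.** The high-utilization cutoffs are the 90th
percentiles of Year-1 annual cost and SOC visits over all included
patients, and of Year-1 LOS over patients with at least one admission
(LOS percentiles over a mostly-zero variable would be meaningless).
The percentile estimator interpolates linearly between order statistics at
rank $1+(n-1)q$ (`stats::quantile` type 7); a nearest-rank variant is
available as a sensitivity switch. A patient *exceeds* a metric when
strictly greater than its threshold — equality does not exceed, so a
degenerate metric where every patient ties the threshold yields no HUs.
The three exceedance indicators define eight mutually exclusive labels:
`Non-HU`, `Cost`, `LOS`, `SOC`, `LOS-SOC`, `Cost-LOS`, `Cost-SOC` and
`Cost-LOS-SOC`; they partition the cohort by construction. Thresholds are
estimated on the full included Year-1 cohort, including patients who die
during the year, because group profiles report within-group mortality.

**Persistence.** A patient persists when their Year-2 aggregates, compared
against the *frozen* Year-1 thresholds, land in any HU group. Patients with
no Year-2 utilization have zero aggregates and are therefore Non-HU
(non-persistent); Year-1 decedents have no defined persistence and are
excluded from all persistence analyses.

**Profiles.** Group profile tables report medians and interquartile ranges
(the same order-statistic interpolation as the thresholds) of cost,
admissions, LOS, SOC, ED, age at first visit, the Quan adaptation of the
Charlson Comorbidity Index (CCMI), and a polypharmacy score (PPS, the
largest number of unique medications dispensed in any single visit);
categorical breakdowns of gender, race, subsidy tier (subsidised-only /
unsubsidised-only / both, derived from per-visit subsidy flags) and housing
type (a socio-economic proxy, with an explicit `unknown` level); and death
and persistence counts. Every percentage uses the group size as
denominator, decedents included. Top-5 condition lists per group are
computed twice — by patients ever diagnosed and by visit frequency — with
ties broken lexicographically so the output is deterministic.

**Comorbidity scoring.** Diagnosis codes are opaque strings resolved
against user-loadable mapping files (exact entries beat prefix entries;
the longest prefix wins), so either ICD revision can be used by supplying
the corresponding crosswalk. The packaged Quan/Charlson weight file covers
the 17 comorbidity categories with the original weights (1, 2, 3, 6) and is
deliberately a small, editable subset of the full published code lists; the
three mild/severe hierarchy pairs (liver disease, diabetes complications,
malignancy/metastasis) score only their severe member when both are
present. CCMI uses Year-1 primary diagnoses — the single diagnosis field
the data model carries; PPS uses all available visits ("ever"), restrictable
to the window. A missing CCMI downstream is taken as 0.

## The staged persistence models

Persistence (yes/no) is modelled by maximum-likelihood logistic regression
(`stats::glm`, IRLS, relative tolerance 1e-8, at most 100 iterations) in
three stages:

* **Model 0**: utilizer group only (reference `Non-HU`) — the unadjusted
  association between Year-1 segment and persistence.
* **Model 1**: Model 0 plus age at first visit, gender (ref `female`), race
  (ref `chinese`), nationality (ref `foreigner`), subsidy tier (ref
  `subsidised_only`), housing (ref `rental_1_2room`; unknown housing is a
  level, not an exclusion), CCMI and PPS, followed by backward elimination
  at $\alpha = 0.001$.
* **Model 2**: Model 1 plus one presence indicator per *common HU
  condition* (the deduplicated union of the eight groups' top-5 lists),
  again eliminated at $\alpha = 0.001$.

Elimination removes whole factors, not individual dummy levels: each
removable factor is tested by a likelihood-ratio test of all its levels
jointly (`drop1(test = "Chisq")`), the worst factor with $p \ge \alpha$ is
removed, the model refitted, and so on. Per-level Wald removal would
fragment categorical factors; the factor-level LRT is the defensible
reading and the Wald alternative can be had by eliminating on a design with
indicator terms. The group exposure is never eliminated. At the Model-2
stage only the newly added condition indicators are candidates: the Model-1
adjustment set is retained, which keeps Models 0, 1, 2 nested and the
reported likelihood-ratio tests between successive stages valid. Reports
give odds ratios with 99% Wald confidence intervals, McFadden's
pseudo-$R^2$ ($1 - \ell/\ell_0$), residual deviance and degrees of freedom.

Patients who died in Year 1 or have missing gender, race or nationality are
excluded from all three models, so the stages are fitted on identical
observations. A factor level with no events produces an infinite odds-ratio
estimate in theory; in practice the solver stops at a large finite value,
and the package flags any |log-odds| above 15 as apparent separation — a
warning by default (the level's interval is uninformative but the rest of
the fit is usable), or an error naming the term via
`on_separation = "error"`.

## The synthetic cohort generator

Real hospital administrative data of this kind cannot be shared, so the
package ships a generator that emulates the statistical structure the
analysis relies on, making every downstream stage testable end to end.

A cohort is a mixture of *archetypes* (`archetype_spec()`): latent patient
classes with annual visit rates per setting, a log-normal length-of-stay
distribution (discretized, minimum 1 day), a log-normal inpatient cost
distribution with fixed setting scale factors (SOC 0.15, ED 0.2, therapy
0.1 of an inpatient bill), a diagnosis pool, a medication-count range, a
short-stay fraction, a first-year death hazard and demographic ranges. Each
patient draws a mean-one log-normal *frailty* multiplier applied to all
rates in both years: a single mechanism that yields overdispersed
(mixed-Poisson) counts, right-skewed annual costs, and year-to-year
persistence correlation. The mixing law had to be chosen — the frailty
parameter is specified on the log scale, so log-normal mixing is the
natural reading; a gamma-frailty variant would differ only in the tail
shape of the count distribution. A per-archetype Year-2 decay multiplier
models recovery after an acute first year, reproducing the dominant
longitudinal pattern in hospital cohorts: most high utilizers do not
persist, with the cardiac "one-off" archetype decaying hardest.

Each patient's latent entry date is uniform over the enrolment window, and
their earliest Year-1 visit is placed exactly at entry, so the downstream
index date equals the entry date and the generator's two years align with
the analysis windows. Deaths truncate all later visits. Identical
`(config, seed)` input produces byte-identical CSV output.

The default five-archetype mixture (dominant routine low-use class, cardiac
one-off, frail elderly multimorbid, small psychiatric long-stay class,
high-SOC ambulatory class) mirrors the qualitative structure of a real
hospital cohort — Non-HU patients dominate headcount but a quarter of
cost; psychiatric stays are long but cheap; high-SOC patients are
ambulatory — and was fixed once on those grounds. It is *not* a fit to any
institution's joint distribution: passing tests on synthetic data show the
pipeline's logic and calibration are correct, not that any particular
hospital's numbers will be reproduced. Real data differ in ways the
generator does not emulate: coded diagnosis breadth, within-year
non-stationarity, transfers and cross-cluster utilization, billing
idiosyncrasies.

### Planted persistence effects

`plant_persistence()` turns the generator into a parameter-recovery rig.
Each listed archetype receives a latent persist flag with probability $p$
such that $\mathrm{odds}(p)$ equals the requested multiplier times a
reference odds (`base_rate`, default 0.02, the natural persistence level of
the low-use class). Flagged patients get Year-2 utilization far above any
plausible threshold; unflagged patients get near-zero Year-2 utilization,
so the realized persistence odds of an archetype equal the planted odds
almost exactly. Two design points matter. First, if every multiplier is 1
the configuration is returned unchanged — planting nothing means natural
Year-2 behaviour. Second, a planted patient with zero Year-1 visits is
forced to the quiet profile: they have no index year to persist *from*, and
giving them the heavy profile would anchor their index on the Year-2 burst
and contaminate the Year-1 groups with guaranteed non-persisters.

`recovery_config()` packages the validation experiment: a three-archetype
mixture (low-use 86.5%, high-SOC 8.5%, cardiac 5%) with multipliers 1, 8
and 2. The mixture is intentionally more separated than the realistic
default: with a 90th-percentile threshold, almost exactly 10% of included
patients exceed the SOC cut, so the high-SOC archetype's share of the
*included* cohort is set just above 10% — below that, low-use patients
contaminate the SOC groups; far above it, planted persisters leak into the
Non-HU reference and attenuate every odds ratio. With this design a
group-only (Model 0) fit at $n = 20{,}000$ recovers the planted multiplier
8 inside the SOC group's 99% confidence interval, and the qualitative
ordering high-SOC groups > other HU groups > 1, in well over 90% of
replicates (the acceptance suite runs 50).

## Numerical and engineering choices

* Dates are ISO 8601 in files and `Date` internally; window arithmetic is
  whole days. Medication sets serialize as one semicolon-delimited field,
  keeping one row per visit.
* Unknown categorical values degrade to an explicit `unknown` level
  (housing) or `NA` (gender/race/nationality, which the models treat as an
  exclusion); invalid rows are rejected with row-numbered diagnostics, or
  dropped under `skip_bad_rows = TRUE` with a count.
* Money is rounded to cents by the generator so that write/read round trips
  are exact; reporting rounds percentages to one decimal and odds ratios to
  two, matching conventional table formatting.
* Short stays count as admissions but contribute no LOS; whether a study
  counts them among "admissions" is genuinely ambiguous, so the choice is
  recorded in the run manifest.
* The 2x2-table oracle (`OR = ad/bc`) and the chi-square tail are used in
  the test suite as independent checks of the fitting and testing code
  paths; the implementation itself always goes through the likelihood.
* Problem sizes in the test suite were chosen for statistical resolution at
  interactive speed: calibration loops use 100 replicates of 10,000 draws,
  elimination calibration 100 replicates at $n = 5{,}000$, parameter
  recovery 50 replicates at $n = 20{,}000$, and the end-to-end determinism
  check a 3,000-patient cohort.

## Known limitations

* The packaged Quan and condition mappings are illustrative subsets; real
  analyses must load full crosswalks (`load_code_mapping()`).
* Cost shares and thresholds assume pre-adjusted (inflation-corrected)
  billed amounts; no deflator is applied.
* The generator does not model transfers between institutions, within-year
  rate changes, or coding drift; persistence correlation comes entirely
  from frailty, decay and planting.
* With very small groups the persistence models are fragile by nature:
  zero-event levels yield separation warnings and uninformative intervals,
  which is a property of the data, not of the solver.

## A worked run

```{r example, eval = FALSE}
cfg <- cohort_config(20000, seed = 42)
out <- run_hu_pipeline(cfg, "hu_run", seed = 42)
out$seg                      # thresholds and group sizes
summary(out$seg)             # shares, cost concentration, persistence
head(out$models$report, 10)  # staged odds-ratio table
```

The same pipeline is exposed on the command line via
`inst/scripts/husegment.R` (subcommands `simulate` and `pipeline`), and
`scripts/acceptance.R` at the repository root recomputes the package's
headline quantities from scratch into a JSON file.
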