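# husegment

Segmentation of a hospital patient population into mutually exclusive
**high-utilizer (HU) groups**, and logistic modelling of whether each group
**persists** in high utilization into the following year.

Healthcare cost and utilization are strongly right-skewed: a small group of
patients accounts for a disproportionate share of resources, and most of
them regress to the mean within a year. `husegment` is written for health
services researchers and biostatisticians working with visit-level hospital
administrative records (EMR/claims extracts). It implements:

* **Cohort construction** — index-visit identification inside an enrolment
  window, an age-≥21 inclusion rule, and two fixed 365-day observation
  windows anchored at the index date.
* **Multi-metric segmentation** — per-patient Year-1 totals of billed cost
  (all settings), inpatient length of stay (LOS, short stays excluded per
  the OECD convention) and specialist outpatient clinic (SOC) visits; the
  high-utilization threshold for each metric is its cohort 90th percentile
  (LOS percentile over admitted patients only), estimated by linear
  interpolation between order statistics at rank `1 + (n-1)q`. A patient
  strictly exceeding the threshold on a metric is an HU on that metric, and
  the three indicators define eight mutually exclusive labels:

  `Non-HU, Cost, LOS, SOC, LOS-SOC, Cost-LOS, Cost-SOC, Cost-LOS-SOC`

* **Persistence** — a patient persists if their Year-2 aggregates exceed
  the *frozen* Year-1 thresholds on any metric; no Year-2 utilization means
  Non-HU.
* **Group profiles** — median/IQR utilization, socio-demographics, subsidy
  tier, housing-type SES proxy, Quan-adapted Charlson Comorbidity Index
  (CCMI), polypharmacy score (PPS), death and persistence proportions, and
  top-5 condition lists per group (by patients ever diagnosed and by visit
  frequency).
* **Staged persistence models** — logistic regressions of persistence:
  Model 0 (HU group only), Model 1 (plus socio-demographics and
  multi-morbidity), Model 2 (plus common HU-condition indicators), with
  factor-level likelihood-ratio backward elimination at α = 0.001, odds
  ratios with 99% Wald CIs, McFadden's pseudo-R², and likelihood-ratio
  tests between successive models:

  McFadden R² = 1 − ℓ/ℓ₀,  OR = exp(β),  99% CI = exp(β ± z₀.₉₉₅·SE)

* **A synthetic EMR cohort generator** — archetype mixtures with log-normal
  patient frailty, heavy-tailed LOS and cost, archetype-specific diagnosis
  pools, within-year mortality and plantable persistence odds, so that the
  whole pipeline is testable without access to confidential hospital data.

## Worked example

```r
library(husegment)

cfg <- cohort_config(20000, seed = 42)      # default archetype mixture
out <- run_hu_pipeline(cfg, "hu_run", seed = 42)
out$seg
```

```
High-utilizer segmentation of 17364 patients
HU thresholds (90th percentile, interpolate):
  cost  > S$11906.48  (n = 17364)
  LOS   > 34 days (admitted only, n = 2684)
  SOC   > 6 visits (n = 17364)
Group sizes:
  Non-HU          14961 (86.2%)
  Cost              782 (4.5%)
  LOS                 3 (0.0%)
  SOC               663 (3.8%)
  LOS-SOC             0 (0.0%)
  Cost-LOS          120 (0.7%)
  Cost-SOC          693 (4.0%)
  Cost-LOS-SOC      142 (0.8%)
Overall persistence (survivors): 7.1%
```

Of 20,000 simulated patients, 17,364 qualify (an index visit and age ≥ 21
at index). About 14% are HUs on at least one metric; the `Cost-LOS-SOC`
group — high on every metric — is under 1% of patients. The staged models
quantify how strongly Year-1 group membership predicts persisting:

```r
head(out$models$report, 8)
```

```
    factor        level                 model0              model1            model2
1 hu_group       Non-HU                   1.00                1.00              1.00
2 hu_group         Cost    14.58 (10.78-19.71)    1.93 (1.23-3.03)  1.41 (0.88-2.28)
3 hu_group          LOS                   n.e.                n.e.              n.e.
4 hu_group          SOC    33.66 (25.65-44.18) 14.88 (11.03-20.07)  2.49 (1.67-3.73)
5 hu_group      LOS-SOC
6 hu_group     Cost-LOS    58.20 (34.49-98.20)    3.23 (1.58-6.60)  1.29 (0.62-2.67)
7 hu_group     Cost-SOC  125.10 (95.44-163.98) 36.89 (26.97-50.46)  5.19 (3.40-7.92)
8 hu_group Cost-LOS-SOC 310.67 (168.07-574.24)  20.02 (9.32-42.96) 5.36 (2.39-12.01)
```

Every HU group is far more likely than Non-HUs to persist (Model 0), the
associations shrink once age, comorbidity, polypharmacy and
socio-demographics are adjusted for (Model 1) and shrink further after the
common-condition indicators enter (Model 2) — the confounding structure the
staged design is meant to expose. Empty groups print blank cells; `n.e.`
marks a separation-degenerate level (here a 3-patient group). The footer
rows carry McFadden's R² (0.42 / 0.46 / 0.51 in this run), residual
deviance and the LRT p-values between stages. All artifacts (CSV tables,
thresholds JSON, run manifest) are written to the output directory, and a
rerun with the same seed is byte-identical.

Real data enter through `read_visits()` / `read_patients()` (documented CSV
schemas) with diagnosis-code crosswalks supplied via `load_code_mapping()`;
the packaged Quan and condition mappings are small illustrative subsets.

A thin command-line wrapper is included:

```sh
Rscript inst/scripts/husegment.R pipeline --n 20000 --seed 42 --out hu_run
```

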