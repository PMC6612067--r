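Package: husegment
Title: Segmentation and Persistence Analysis of High Healthcare Utilizers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Segments a hospital patient population into mutually exclusive
    high-utilizer (HU) groups from visit-level administrative records, using
    90th-percentile thresholds on annual cost, inpatient length of stay and
    specialist outpatient visits, and models persistence of high utilization
    into a subsequent year with staged logistic regressions (odds ratios with
    99% confidence intervals, McFadden's pseudo-R-squared, likelihood-ratio
    tests, factor-level backward elimination). Includes readers and writers
    for visit- and patient-level tables, a Quan-adapted Charlson comorbidity
    index, a polypharmacy score, diagnosis grouping via user-loadable code
    mappings, group profiling tables, and a synthetic cohort generator with
    archetype mixtures, patient-level frailty and plantable persistence
    effects for validation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
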