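Package: wristpd
Title: Digital Severity Biomarkers from Wrist-Worn Accelerometry in
    Parkinson's Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates free-living smartwatch accelerometer recordings paired
    with patient-reported Parkinson's symptom diaries (medication on/off,
    dyskinesia, tremor) across two harmonizable cohorts, and implements a
    complete severity-modelling benchmark on top of them: label harmonization
    and eligibility filtering, stratified within-subject train/test splits,
    windowed signal-feature extraction (generic single-channel and actigraphy
    feature families), per-subject and global random-forest severity models
    against a subject-mean null baseline, sqrt(n)-weighted mean-squared-error
    scoring with paired bootstrap significance, heterogeneous ensembling
    (unsupervised aggregation, stacking, greedy ensemble selection, exhaustive
    regularized-subset search), and post-hoc subject-level lift, covariate
    association with fixed-effect meta-analysis, and clinician-rating
    validation statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    xgboost
Suggests:
    metafor,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
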