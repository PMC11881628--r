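Package: cogdynrisk
Title: Dynamic Lifetime Alzheimer's Disease Risk Prediction from
    Longitudinal Cognitive Assessments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-stage dynamic risk prediction for incident Alzheimer's
    disease from longitudinal cognitive-domain composites. Stage one fits
    per-domain linear mixed models (random intercept and slope, restricted
    maximum likelihood) and extracts empirical best linear unbiased
    predictions of subject-specific trajectories; stage two feeds those
    trajectory summaries, with demographics, into a logistic risk model
    refitted at yearly landmarks as data accrue. Includes a longitudinal
    cohort simulator with known ground truth, eligibility and landmark
    dataset construction, time-updated AUC with bootstrap confidence
    intervals, DeLong comparison of correlated AUCs, Brier score and
    decile calibration, and AUC-based stepwise selection of cognitive
    domains.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    stats,
    utils,
    generics,
    ggplot2,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    lme4,
    pROC,
    withr
Config/testthat/edition: 3
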