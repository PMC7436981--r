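Package: ftrcop
Title: Functional Time Ratios for Center-of-Pressure Limit-of-Stability Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing centre-of-pressure (CoP) recordings from a
    calibrated limit-of-stability (LoS) balance task. Builds the three nested
    rectangular functional areas (RFAs) centred on the CoP median, computes the
    functional time ratios FTR1, FTR2, FTR3 and the FTR1/2 index, and provides
    the surrounding clinical machinery: zero-phase Butterworth preprocessing,
    per-direction calibration and target placement, trial scoring with timeouts
    and home holds, ICC(2,k) reliability with SEM, convergent-validity
    correlations, logistic classification of fear-of-falling groups with
    ROC/Youden cutoffs, corrected-AIC model comparison and stratified fivefold
    cross-validation. A seeded CoP simulator generates calibration attempts,
    LoS trials and whole cohorts so that every stage of the pipeline can be
    exercised without patient data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
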