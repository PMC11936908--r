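Package: immersr
Title: Session-Level Neurophysiologic Immersion Analytics for Retail Purchase Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for analysing 1 Hz neurophysiologic Immersion traces recorded
    from sales associates during retail service encounters. Computes session-level
    Immersion statistics (total, average, and the peak-over-threshold Peak
    Immersion fraction), implements a procedural-utility choice model linking
    experiential value to dwell time and spending, simulates calibrated two-store
    shopper cohorts, expands cohorts by sequential parametric synthesis with
    Kolmogorov-Smirnov fidelity diagnostics, estimates Peak Immersion -> dwell
    time -> purchase mediation with bootstrap indirect effects, and evaluates an
    ensemble of tree classifiers for purchase prediction with stratified
    cross-validation. A seeded pipeline orchestrates all stages into
    reproducible CSV/JSON artifacts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    purrr,
    readr,
    rlang,
    jsonlite,
    digest,
    randomForest,
    ranger,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
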