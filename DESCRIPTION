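Package: fedrisk
Title: Federated, Differentially Private Risk Prediction for Multi-Site Clinical Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates and analyses multi-site clinical cohorts for rare-outcome
    risk prediction without pooling patient-level data. Provides a synthetic
    multi-site cohort generator with controllable inter-site covariate shift,
    federated gradient-boosting feature selection with an early-stopped top-N
    search, a Deep & Cross Network risk model trained with differentially
    private stochastic gradient descent (per-example gradient clipping plus
    Gaussian noise) under federated averaging, a Renyi differential-privacy
    accountant with (epsilon, delta) conversion, cross-site and
    class-balanced bootstrap evaluation with Brier scores and Monte-Carlo
    Shapley attributions, and baseline-characteristics tables with
    continuity-corrected chi-square tests.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    graphics,
    methods,
    stats,
    utils,
    jsonlite,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
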