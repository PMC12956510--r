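Package: fatiguelab
Title: Multi-Sensor Training-Load Monitoring and Fatigue Prediction for Team-Sport Athletes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for wearable-sensor athlete monitoring analytics:
    a synthetic monitoring-cohort generator driven by a latent fitness-fatigue
    impulse-response state (Gaussian-copula session marginals calibrated to
    published team-sport load distributions), external/internal/derived
    training-load indicators (Banister TRIMP, session-RPE, percent heart-rate
    reserve, Player Load, EWMA acute:chronic workload ratio, training monotony
    and strain, rolling individual baselines), a rolling-baseline multi-criteria
    operational fatigue labeler, tiered quality control and imputation, a
    cross-validated model-comparison harness (stratified dummy baseline, L2
    logistic regression, random forest, gradient boosting; stratified 10-fold
    and leave-one-subject-out schemes) with ROC/Youden analysis and exact
    tree-Shapley attributions, and descriptive/inferential reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    generics,
    stats,
    utils,
    glmnet,
    ranger,
    xgboost,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
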