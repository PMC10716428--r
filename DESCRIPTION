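Package: ckdprog
Title: Chronic Kidney Disease Progression Prediction from Longitudinal EHR Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for predicting progression of chronic
    kidney disease (CKD) from stages II/III to stages IV/V using longitudinal
    electronic health records (EHRs). Detects stable CKD-stage periods on
    irregular eGFR series, assigns case/control status with the transition
    point to the late stage, assembles fixed-interval feature-vector time
    series (binning, gap and prediction windows, truncation, imputation),
    matches cases to controls on race, sex, age and sequence length, and
    trains an LSTM recurrent network classifier alongside four baselines
    (static and dynamic Cox proportional hazards, random forest,
    gradient-boosted trees) under a repeated stratified ten-fold
    cross-validation harness reporting AUROC, AUPRC, MCC and race-stratified
    performance. Includes sequential forward variable selection with
    selection-frequency reporting, and a synthetic longitudinal EHR generator
    so that the whole pipeline is runnable and testable without access to
    protected health data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    survival,
    randomForest,
    xgboost
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite
Config/testthat/edition: 3
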