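Package: crcoupling
Title: Cardiorespiratory Coupling Features and Health-Status Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for classifying pediatric health status (cardiac patient,
    healthy, trained athlete) from short static cardiorespiratory recordings.
    Provides a calibrated synthetic generator of coupled respiration and
    RR-interval recordings (respiratory sinus arrhythmia with controllable
    coupling strength), signal preprocessing (band-pass respiration filtering,
    cubic tachogram interpolation, stationarity checks, downsampling), a
    157-feature battery spanning demographic, cardiac (time, frequency,
    nonlinear, symbolic-dynamics HRV), respiratory, and causal/information
    domains (linear, kernel, large-scale nonlinear and ML-based Granger
    causality, transfer entropy, cross entropies, lagged correlation),
    SMOTE-balanced 10-fold cross-validated multi-model comparison with
    accuracy, precision, recall, F1, multiclass MCC and one-vs-rest AUC,
    pairwise Wilcoxon dataset comparison, and explainability (Monte-Carlo
    Shapley attributions, permutation variable importance) driving reduced
    feature-set selection.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    signal,
    jsonlite,
    nnet,
    rpart,
    e1071,
    randomForest,
    xgboost,
    glmnet,
    caret,
    S4Vectors,
    SummarizedExperiment,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
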