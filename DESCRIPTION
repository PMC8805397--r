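Package: nivstack
Title: Stacked Ensemble with Modified SMOTE for Noninvasive Ventilation
    Failure Prediction
Version: 0.1.0
Authors@R:
    person("NIV", "Modelling Group", email = "nivstack@example.org",
           role = c("aut", "cre"))
Description: Tools for predicting failure of noninvasive ventilation (NIV)
    in ICU cohorts from paired pre-treatment (H0) and one-hour (H1)
    physiological measurements. Implements a seeded synthetic-cohort
    generator, a leakage-safe preprocessing chain (3-sigma outlier masking,
    median imputation, z-score standardization, one-hot encoding with
    rare-category collapse), temporal and expert feature engineering
    including an LSTM autoencoder for two-point time series, a modified
    SMOTE oversampler that clusters SVM-mined hard minority instances and
    interpolates between cluster centroids and members, a three-learner
    stacking classifier (logistic regression, random forest,
    gradient-boosted trees) with an out-of-fold logistic meta learner, the
    standard confusion-matrix metric suite with ROC AUC, and additive
    (SHAP-style) per-patient and global explanations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
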