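Package: immunoPET
Title: Noninvasive Tumor Immune Profiling from FDG-PET with a 3-D Convolutional Regressor
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to estimate the cytolytic activity score (CytAct), a
    two-gene (GZMA/PRF1) transcriptomic signature of cytotoxic T-cell
    activity, directly from FDG-PET images of lung adenocarcinoma.
    Provides adaptive-threshold tumor segmentation with conventional PET
    features (SUVmax, SUVmean, metabolic tumor volume), cube extraction
    with random three-axis rotation augmentation, a compact 3-D
    convolutional neural network trained by k-fold cross-validation to
    regress CytAct from uptake patterns, per-patient multi-lesion
    biomarkers for immune checkpoint blockade (minimum predicted CytAct,
    inter-lesion variance), the statistical toolkit used to evaluate them
    (Spearman, Wilcoxon rank-sum, logistic regression with an optional
    Firth penalty, ROC/AUC with Youden cutoff, Kaplan-Meier, log-rank,
    Cox), and a seeded synthetic phantom generator that links a latent
    immune score to lesion uptake texture, paired gene expression and
    multi-lesion treatment outcomes so the whole pipeline can be
    exercised end to end without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    RNifti,
    jsonlite,
    pROC,
    survival
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
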