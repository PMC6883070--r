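Package: downstrap
Title: Downsampling-Based Extrapolation of Achievable Classifier Performance
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Decides, from a limited two-class feature table, whether the
    features carry information relevant to a classification task and what
    Youden index or AUC a model could reach with enough patients. Builds
    downsampling learning curves of univariate ROC and multivariate
    classifier performance, fits standard-deviation decay and logarithmic
    performance-growth models, solves for the convergence sample size and
    extrapolates the expected performance at convergence. Includes the
    univariate Youden-index/AUC screen, nine linear classifier protocols
    with stratified K-fold cross-validation, permutation-null cohort
    construction and quality-of-prediction metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    glmnet,
    e1071
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
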