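Package: mlwsvm
Title: Multilevel Weighted Support Vector Machines for Imbalanced Data with
    Missing Values
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Multilevel framework for (cost-sensitive) support vector
    machine classification of large, imbalanced datasets. Training data are
    recursively coarsened per class through independent-set selection on
    approximate k-nearest-neighbor graphs, a weighted SVM is tuned at the
    coarsest level with a nested uniform-design search over (C, gamma), and
    the support vectors are refined back up the hierarchy, retraining either
    directly or on pairs of nearest opposite-class clusters. Includes
    regularized expectation-maximization imputation of missing values by
    iterated ridge regression, stratified cross-validation with leakage-free
    per-fold imputation, imbalance-aware performance measures (sensitivity,
    specificity, G-mean, accuracy), synthetic Gaussian-mixture benchmark
    generators, and CSV/LIBSVM readers and writers.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    kernlab,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
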