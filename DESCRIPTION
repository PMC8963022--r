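Package: harsmote
Title: Hybrid SMOTE-Family Oversampling for Imbalanced Human Activity Recognition
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for tackling class imbalance in wearable-sensor human
    activity recognition. Implements six SMOTE-family oversamplers (SMOTE,
    Random-SMOTE, SMOTE with Tomek-link cleaning, MSMOTE, cluster-based
    synthetic oversampling, and proximity-weighted synthetic oversampling)
    and three hybrid strategies that concatenate the synthetic output of two
    constituents: a distance-based method (DBM), a noise-detection-based
    method (NDBM) and a cluster-based method (CBM). Also provides
    accelerometer preprocessing (magnitude signal, non-overlapping windows,
    six time-domain features), a leakage-safe stratified cross-validation
    harness with pluggable classifiers including a ReLU/Adam multilayer
    perceptron, and the statistical comparison machinery (Anderson-Darling
    normality screening routing to one-way ANOVA or the Friedman rank test)
    used to compare sampling strategies across classifiers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    class,
    nnet,
    e1071,
    randomForest,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    nortest,
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
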