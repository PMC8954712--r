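Package: fragminer
Title: Privileged-Fragment Mining and Imbalance-Aware Classification of
    Kinase Inhibitor Fingerprints
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for qualitative structure-activity classification of
    kinase inhibitors from binary molecular fingerprints, built around the
    DYRK1A inhibitor potency problem. Provides IC50/pIC50 potency labeling
    and stratified train/test splitting; from-scratch SMOTE oversampling,
    Tomek-link detection and the SMOTE+Tomek-link hybrid for class
    balancing; a seven-algorithm classifier grid (SVM, logistic regression,
    k-nearest neighbors, neural network, naive Bayes, random forest,
    decision tree) evaluated by pooled stratified cross-validation; the
    standard confusion-matrix metric suite (sensitivity, specificity,
    accuracy, Matthews correlation, balanced accuracy, ROC AUC);
    privileged-substructure mining by information gain and class-frequency
    enrichment; chemical-space characterization (distance heat matrices,
    descriptor screening, principal-component projection, Lipinski
    profiles); and a seeded synthetic fingerprint-data generator so the
    whole pipeline runs and is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    class,
    e1071,
    jsonlite,
    nnet,
    ranger,
    rpart,
    stats,
    tools,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
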