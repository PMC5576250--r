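Package: putarget
Title: Positive-Unlabelled Prediction of Therapeutic Targets from
    Gene-Disease Association Evidence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A semi-supervised (positive-unlabelled) machine-learning
    pipeline for prioritising therapeutic drug targets from gene-disease
    association evidence. Aggregates per-data-type association scores into
    a per-gene feature matrix, labels genes from drug-development pipeline
    stages, trains bootstrap-aggregated classifiers (random forest, radial
    SVM, single-hidden-layer neural network, exponential-loss boosting,
    decision tree) with nested cross-validation for tuning and unbiased
    evaluation, nominates novel targets above a probability threshold, and
    validates predicted sets against external gene lists with Fisher's
    exact test and a permutation null. Includes a synthetic-data generator
    emulating sparse zero-inflated evidence with hidden positives in the
    unlabelled class for property-based testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    withr,
    randomForest,
    e1071,
    nnet,
    rpart
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
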