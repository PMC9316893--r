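Package: spiderVote
Title: Imbalance-Aware Hierarchical Voting Ensembles for Expression-Based
    Disease Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for binary disease classification from gene-expression-style
    feature tables with strong class imbalance. Implements a selective
    kNN-based over-sampler in the SPIDER family (noise flagging, weak/strong
    partition of the minority class, interpolation-based synthesis), a
    two-arm probability-voting ensemble whose arms are AdaBoost-style
    committees of random forests and support vector machines trained on
    class-balanced subsets, four feature-ranking strategies (chi-squared,
    recursive elimination with a linear SVM, gradient-boosted-tree
    importance, and a three-contrast differential-expression selector with
    Venn intersection), an evaluation-metric suite (accuracy, Matthews
    correlation, RMSE, F-score, ROC/AUC), a benchmark harness for KEEL-style
    datasets, and a synthetic-data generator so every stage is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    randomForest,
    e1071,
    xgboost,
    class,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
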