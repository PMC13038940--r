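Package: pvpstack
Title: Stacked Ensemble Classification of Phage Virion Proteins from
    PSSM-Derived Evolutionary Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies phage virion proteins (PVPs) from protein sequences
    and their PSI-BLAST position-specific scoring matrix (PSSM) profiles.
    Implements four PSSM-derived evolutionary descriptors (AAC-PSSM,
    DPC-PSSM, PSSM composition, pseudo-PSSM; 860 features), seven classical
    sequence descriptors (AAC, DPC, GAAC, GDPC, CTD
    composition/transition/distribution; 723 features), three feature
    selectors (ANOVA F-score, variance threshold, recursive feature
    elimination with cross-validation), and a two-layer stacked ensemble in
    which out-of-fold probabilities from a panel of base classifiers feed a
    logistic-regression, random-forest or support-vector meta-classifier.
    Includes a full binary-classification metric suite, a synthetic
    sequence/PSSM generator for end-to-end testing, and a command-line
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    caret,
    e1071,
    jsonlite,
    nnet,
    randomForest,
    ranger,
    rpart,
    stats,
    utils,
    xgboost
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
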