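Package: seqloop
Title: Predicting Open Chromatin Interactions from DNA Sequence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting chromatin interactions between open
    chromatin regions from DNA sequence and anchor distance. Builds
    distance-matched, extended and from-open-chromatin training datasets
    from loop files (BEDPE) and open chromatin peaks (BED); trains a small
    convolutional sequence feature extractor over both anchors in both
    orientations, couples it to gradient-boosted-tree classifiers, and
    scores all candidate anchor pairs genome wide. Includes interpretation
    utilities (convolutional kernels to position weight matrices, motif
    database matching, convergent-orientation importance analysis),
    precision-recall evaluation machinery, cohort-level statistics
    (conservation profiles, Fisher-exact differential interactions,
    promoter interaction fold changes), and a synthetic data generator
    with planted convergent motifs for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    IRanges,
    Rcpp,
    jsonlite,
    methods,
    stats,
    utils,
    xgboost
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
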