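Package: screenbo
Title: Batched Bayesian Optimization for Pool-Based Virtual Screening
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Active-learning prioritization of compounds in structure-based
    virtual screening. Iteratively trains a surrogate structure-score model
    (random forest, feedforward neural network with Monte-Carlo dropout, or
    directed message passing network with a mean-variance head) on evaluated
    molecules, scores the remaining pool, acquires the highest-utility batch
    under greedy, UCB, Thompson-sampling, EI, PI, or random acquisition, and
    evaluates it against a lookup-table objective such as precomputed docking
    scores, so that most top-scoring library members are found while
    evaluating a small fraction of the library. Includes 2048-bit atom-pair
    fingerprinting, top-k retrieval metrics, enrichment factors, and a
    synthetic structure-score landscape generator for download-free testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ChemmineR,
    ChemmineOB,
    ranger,
    Matrix,
    data.table,
    jsonlite,
    yaml,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
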