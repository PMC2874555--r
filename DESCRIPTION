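Package: ptmscan
Title: Prediction of Post-Translational Modification Sites in Protein
    Sequences
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies candidate post-translational modification (PTM)
    sites in protein sequences from sequence information alone.  Query
    proteins are dissected into overlapping 9-residue segments, each
    residue is described by ten physicochemical property scales drawn
    from the AAindex database, and the resulting 90-dimensional feature
    vectors are classified by per-PTM-type multilayer perceptrons
    trained with back-propagation and momentum.  For every PTM type
    three networks are trained, independently optimized for AUC, recall
    and precision on held-out test splits, and predictions carry a
    normalized-response confidence score.  Includes ratio-controlled
    random sub-sampling validation, hidden-layer size sweeps with
    test-set checkpointing, ROC/AUC evaluation, a synthetic motif
    dataset generator, and a two-phase command-line pipeline (sequence
    generator and predictor).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
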