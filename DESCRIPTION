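Package: aprscan
Title: Aggregation-Prone Region Prediction from Protein Sequence with
    Recurrent Network Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Predicts amyloid aggregation-prone regions (APRs) in protein
    sequences.  Trains ensembles of small bidirectional long short-term
    memory networks on experimentally labelled hexapeptides, scans whole
    sequences with overlapping hexapeptide windows to produce per-residue
    aggregation profiles, and calls APRs as contiguous above-threshold
    runs of at least six residues.  Ships the complete evaluation stack
    (confusion-matrix metrics, ROC and precision-recall curves, Youden-J
    threshold selection, per-class Segment OVerlap scores), stratified
    splitting and cross-validation utilities, a hyperparameter-search
    helper, and a synthetic-data generator so the whole
    train-profile-evaluate pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    knitr,
    optparse,
    pROC,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
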