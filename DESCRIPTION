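Package: seqslr
Title: Structured Logistic Regression for Protein Sequence Classification
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Classification of protein sequences with structured logistic
    regression: linear models over occurrence indicators of contiguous
    subsequence predictors of unrestricted length, trained by coordinate-wise
    gradient ascent with a branch-and-bound search over the substring lattice.
    Includes a one-vs-all multiclass cascade with a rejection class and
    iterative self-training, stratified cross-validation with ROC/AUC and
    true/false-positive rates, motif and length curation flags, decomposition
    of predicted transmembrane topologies into N-element/core/C-element
    architectures anchored on the DKTGT phosphorylation motif, and a
    synthetic-data generator with planted motifs for benchmarking. Developed
    for the P-type ATPase pump family but applicable to any sequence
    classification problem with extreme class imbalance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    methods,
    optparse,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
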