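Package: ubicnn
Title: Plant Ubiquitylation-Site Prediction with Bigram Embeddings and
    Convolutional Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts lysine ubiquitylation sites in plant proteins from
    31-residue sequence windows. Bigram (two-residue) tokens are embedded
    by unsupervised skip-gram pretraining on whole protein sequences; the
    embedding is transferred into a three-block one-dimensional
    convolutional network and fine-tuned under site labels. Also provides
    the comparative sequence statistics used to characterise
    ubiquitylation motifs (amino-acid composition, adjacent-dipeptide
    composition, positional count matrices with log-ratio contrasts, and
    two-sample-logo enrichment tests), an evaluation harness with
    repeated stratified cross-validation and rank-based AUC, and a
    synthetic-data generator with planted positional motifs so the whole
    pipeline is testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    Biostrings,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
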