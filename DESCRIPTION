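Package: rbpnet
Title: Convolutional BLSTM Models of Protein-RNA Binding from CLIP Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Trains context-aware neural models of RNA-binding protein (RBP)
    binding from CLIP-derived bound sequences and matched genomic backgrounds.
    A bank of small convolutional motif detectors with winner-takes-all
    enhancement feeds a bidirectional LSTM whose per-nucleotide outputs form a
    binding profile; the sigmoid-transformed profile sum is the classification
    score. Includes stratified data splitting and 10-fold cross-validation,
    same-gene genomic background sampling and sequence scrambling, pseudo
    position frequency matrix (motif) extraction ranked by information
    content, wild-type/mutant variant scoring, sliding-window profiling of
    long transcripts, profile-based binding-site calling, and a synthetic
    planted-motif data generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
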