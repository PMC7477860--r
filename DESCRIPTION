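Package: tcmner
Title: Semi-Supervised BiLSTM-CRF Extraction of Traditional Chinese
    Medicine Clinical Terms
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Character-level named entity recognition for Traditional
    Chinese Medicine (TCM) clinical text.  Implements a bidirectional LSTM
    encoder with an exact linear-chain conditional random field (CRF)
    output layer, character embedding tables that can be mixed from two
    pretrained sources and augmented with per-category feature-word
    dimensions, two-phase self-training on unlabeled text, span-level
    micro-averaged precision/recall/F1 evaluation, and a seeded synthetic
    corpus generator so the whole pipeline can be exercised end to end
    without any external corpus.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
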