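Package: peggnet
Title: Internal-Quality Classification and Grading of Preserved Eggs from
    Candling Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classification of the internal quality of preserved (century)
    eggs from transmitted-light (candling) images. Implements a configurable
    ConvNeXt feature extractor, a compact five-class grading network built on
    a reduced [64,128,256,512] backbone with two-step multi-scale feature
    fusion and global attention (sequential channel and spatial gating), a
    hybrid cross-entropy/focal loss for class imbalance, per-class 7:2:1
    dataset splitting with seeded tenfold augmentation, a confusion-matrix
    metric suite with five-class to three-grade consolidation, and a seeded
    synthetic candling-image generator emulating the five egg phenotypes so
    the full pipeline is testable without proprietary imagery. The network
    engine (convolution, normalisation, attention, backpropagation, AdamW)
    is implemented in R and C++.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
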