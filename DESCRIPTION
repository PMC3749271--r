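Package: anpca
Title: Adaptive Nonlinear Principal Component Analysis for Real-Time P300
    Extraction from Multichannel EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Blind source separation of event-related EEG by a four-stage
    adaptive nonlinear principal component analysis (ANPCA) pipeline:
    multi-stage PCA pre-separation (spatial whitening plus delayed-covariance
    rotation and an online eigenvector tracker), adaptive whitening with a
    self-normalizing learning rate, a nonlinear PCA separation rule with
    tanh nonlinearity, and stochastic mixing-matrix re-estimation.  Includes
    a synthetic oddball-paradigm ERP generator (seven-stimulus schedules,
    P300-like source, colored background and artifact sources, full-rank
    mixing, sensor noise), sixth-order band-pass preprocessing and epoch
    extraction, an Amari-style separation performance index with decibel
    reporting and convergence detection, block-wise target classification,
    SOBI and plain-NPCA reference algorithms, a five-layer autoencoder for
    nonlinear principal components, and EDF/delimited-text I/O.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
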