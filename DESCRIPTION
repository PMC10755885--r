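Package: mfocnn
Title: Moth-Flame Optimized One-Dimensional Convolutional Networks for
    EEG Seizure Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Automatic tuning of block-structured one-dimensional
    convolutional neural networks for multi-class electroencephalogram
    (EEG) seizure classification using the moth-flame optimization (MFO)
    metaheuristic.  Provides a from-scratch MFO optimizer over a mixed
    discrete-continuous six-dimensional hyperparameter space (filter
    count, kernel size, activation, dropout, learning rate, pooling
    window), a compact seeded 1D-CNN training engine with
    best-validation checkpointing, fixed sliding-window segmentation of
    long EEG records into one-second chunks, a reader for the Bonn
    University plain-text EEG corpus layout, a five-class synthetic EEG
    generator for download-free end-to-end runs, and confusion-matrix
    evaluation (accuracy, precision, recall, F1, Cohen's kappa).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    e1071,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
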