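Package: deepasym
Title: EEG Band-Power Asymmetry Images and Convolutional Classification
    for Depression Pre-Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Converts multi-channel EEG recordings into per-band 16x16
    pairwise hemispheric-asymmetry matrices, renders them as 64x64 RGB
    images, and classifies depressed-like versus control-like recordings
    with a compact three-layer convolutional neural network under k-fold
    cross-validation.  Includes an EDF reader/writer, Welch spectral
    estimation with Simpson band-power integration, a seeded synthetic
    EEG generator with controllable hemispheric alpha asymmetry, and
    confusion-matrix/ROC evaluation utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    png,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
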