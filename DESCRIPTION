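Package: eeger
Title: Single-Trial EEG Emotion Recognition with Kernel Fisher Features
    and an Imbalanced Quasiconformal-Kernel SVM
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A three-layer pipeline for classifying emotional valence and
    arousal from single-trial multi-channel EEG epochs. Layer 1 extracts
    spectral band powers (theta, alpha, low beta, high beta, gamma) with
    fifth-order Butterworth band-pass filters; layer 2 projects the
    band-power vectors with two-class kernel Fisher's discriminant
    analysis; layer 3 classifies the projections with a cost-sensitive
    support vector machine whose Gaussian kernel is re-shaped by a
    quasiconformal transformation built from the within-margin support
    vectors of an initial fit. Includes the balanced-loss evaluation
    protocol (stratified repeated 2-fold cross-validation, grid search,
    split-half and segment-consistency analyses), a k-nearest-neighbour
    baseline, and a synthetic EEG cohort generator so the whole pipeline
    can be exercised without access to recording hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    signal,
    stats,
    utils,
    withr
Suggests:
    kernlab,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
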