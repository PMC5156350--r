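Package: conveegnn
Title: Single-Trial EEG Prediction of Subsequent Memory with a Compact
    Convolutional Network
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Predicts whether a studied event will later be remembered or
    forgotten from single-trial EEG recorded around the event. Implements a
    five-layer convolutional network (ConvEEGNN) with a spatial convolution
    layer across channels and a temporal convolution-plus-subsampling layer,
    trained by per-sample stochastic gradient descent with early stopping on
    a validation split. Ships the full ERP preprocessing chain (linked-mastoid
    re-referencing, zero-phase band-pass filtering, EOG regression, epoching,
    baseline correction, amplitude-threshold artifact rejection), leave-pair-out
    cross-validation with exact binomial significance, six comparison
    classifiers (LDA, one- and two-hidden-layer perceptrons, cubic-polynomial
    SVM, a CSP/SVM + LDA fusion, and Morlet-wavelet band-power features with an
    L1-regularized linear classifier), channel weight-map analysis of the
    learned spatial kernels, and a calibrated synthetic generator of
    subsequent-memory-effect EEG sessions for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    e1071,
    glmnet,
    jsonlite,
    withr,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    MASS,
    signal,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
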