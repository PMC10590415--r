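Package: popMDSA
Title: Population Decoding and Multidecoder Subspace Analysis for
    Cross-Modal Context-Switching Experiments
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis pipeline for blocked two-context (audiovisual)
    go/no-go experiments with simultaneous population spike recordings.
    Provides behavioral performance statistics (d-prime with clipped
    rates, consistency-block detection with a Monte-Carlo null,
    Bernoulli choice-model fitting and comparison), conversion of spike
    times into Gaussian-smoothed baseline-standardized rate tensors,
    signal/noise variance decomposition across principal-component
    subspaces, time-resolved and cross-temporal cross-validated linear
    decoding with shuffled-label chance calibration, multidecoder
    subspace analysis (decision-vector geometry, skewed-basis
    projections, nullspace decoding with outer cross-validation), and
    movement-confound controls (run-speed distribution matching,
    two-stage video-motion PCA, stationarity selection, motion-level
    equalized decoding). A synthetic-session generator with
    configurable ground-truth population geometry makes every stage
    testable without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    glmnet,
    signal,
    jsonlite,
    tiff
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
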