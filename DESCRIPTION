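Package: posturenet
Title: Arm-Posture Tuning Curves and Random Feedforward Models of Motor Cortex
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis suite for single-neuron tuning to static 3D arm
    posture (27 hand-position targets at two forearm rotation angles) and a
    random-connectivity feedforward network model of primary motor cortex.
    Provides spatial linear, extended and multiplicative tuning-curve fits
    with preferred-position vectors, a nearest-neighbour spatial complexity
    statistic, signal/noise PCA with bootstrap noise floors for
    dimensionality estimation, pronation/supination interaction tests,
    sparse (LASSO) EMG decoding from pseudo-simultaneous populations, a
    synthetic surrogate-recording generator with stored ground truth, and a
    Gaussian-input / threshold-linear network model with coding-level and
    complexity calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    MASS,
    glmnet
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
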