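Package: charnet
Title: Continuous Human Activity Recognition from Wearable IMU Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for continuous human activity recognition (CHAR) from
    body-worn inertial measurement units. Implements a preprocessing chain
    (min-max normalization, annotation-driven segmentation, resampling to a
    multiple of the window width, overlapping windowing, magnetometer flip
    augmentation and magnitude-scaling class balancing), a multi-branch 1D
    convolutional neural network trained with Adam and early stopping, a
    grouped-window prediction-averaging classification strategy, a sensor
    combination evaluation harness with Friedman and Bonferroni-corrected
    post-hoc statistics, and a synthetic IMU signal generator emulating a
    separate-execution training protocol and a continuous-circuit test
    protocol for rehabilitation monitoring.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
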