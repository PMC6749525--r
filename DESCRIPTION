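Package: actigate
Title: Energy-Efficient Human Activity Recognition with SMA-Gated Deep Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for duty-cycled human activity recognition from
    tri-axial accelerometers. A cheap signal-magnitude-area (SMA) change
    detector decides, per sliding window, whether a convolutional classifier
    must be invoked or the previous prediction can be carried over, so the
    expensive model runs only when the wearer's activity plausibly changed.
    Includes readers for the WISDM raw and generic CSV stream formats,
    Butterworth body/gravity acceleration separation, fixed-size overlapping
    sliding-window segmentation, a signal-to-image encoder, a family of small
    fully convolutional classifiers trained by a built-in Adam optimiser, a
    synthetic stream generator for end-to-end testing, and evaluation tools
    for accuracy/usage-rate trade-off sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
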