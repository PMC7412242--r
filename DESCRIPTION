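Package: ppgabp
Title: Continuous Arterial Blood Pressure Waveforms from Photoplethysmography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Estimates the continuous arterial blood pressure (ABP) waveform,
    and from it systolic and diastolic pressure, from a single-channel
    photoplethysmogram (PPG). Implements two 1D convolutional autoencoders
    mapping 5-second PPG windows to aligned ABP windows (a LeNet-5-style
    encoder/decoder and a U-Net-style network with skip concatenations), a
    leave-testing-out cross-validation protocol, and a genetic-algorithm-
    selected, equally weighted waveform-averaging ensemble of the
    cross-validation models. Includes a seeded synthetic generator of paired
    quasi-periodic PPG/ABP records, window-level preprocessing with
    physiological range and signal-quality gates, and agreement metrics
    (MAE, RMSE, Pearson correlation, Bland-Altman limits of agreement).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    graphics,
    jsonlite,
    stats,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
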