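Package: mmgmotion
Title: Mechanomyography Extraction and Transformer-Based Joint Acceleration Estimation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Isolates mechanomyography (MMG, 10-50 Hz muscle vibration) from raw
    accelerometer traces by variational mode decomposition (VMD) whose mode count
    and bandwidth penalty are tuned by differential evolution under an
    envelope-entropy fitness, with an empirical mode decomposition (EMD) baseline
    and Marginal Hilbert Spectrum diagnostics. Provides the six-stage MMG/sEMG
    conditioning pipeline (DC removal, 10-450 Hz bandpass, full-wave
    rectification, linear envelope, normalization), sliding-window dataset
    construction (1000 ms windows at 200 ms increments summarized into length-20
    feature sequences), and an encoder-only transformer estimator of joint
    rotational acceleration with RNN and LSTM baselines, trained by Adam on mean
    squared error and evaluated by per-trial R-squared. A synthetic multimodal
    recording generator supplies ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    yaml,
    jsonlite,
    tibble,
    ggplot2,
    rlang,
    generics
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
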