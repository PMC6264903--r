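Package: gainfieldnet
Title: Self-Organising Gain-Field Networks for Eye- to Head-Centred
    Coordinate Transformation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rate-based simulator of a two-layer competitive neural network
    that learns to transform eye-centred (retinotopic) visual representations
    into head-centred representations from visual input neurons whose
    responses are gain modulated by eye position.  Implements peaked
    (Gaussian) and monotonic (sigmoidal) eye-position gain fields, trace and
    anti-Hebbian synaptic learning rules with optional transmission delays,
    saccade-and-fixation training protocols, a manually prewired reference
    network, input covariance analysis, and reference-frame classification of
    output neurons via head-centredness and eye-centredness correlation
    metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
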