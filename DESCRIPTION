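Package: mpdip
Title: Two-Stage Atomic Decomposition of Multichannel EEG with Dipole
    Modeling
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Sparse time-frequency-space parametrization of multichannel
    EEG recordings. Multivariate matching pursuit decomposes each epoch
    into Gabor atoms with a common envelope, frequency and phase and
    per-channel weights; a single equivalent current dipole is fitted to
    every atom's scalp topography in an analytic three-shell spherical
    head model; structures of interest (sleep spindles) are selected from
    the resulting dipole atoms by explicit amplitude, frequency, duration,
    goodness-of-fit and distance-to-cortex criteria. Includes a simulation
    benchmark (multivariate autoregressive background plus
    forward-projected spindles), event-detection scoring, and spatial
    frequency-gradient analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
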