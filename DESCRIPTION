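Package: esprox
Title: Explosive-Synchronization Proximity of Oscillator, Brain-Signal and
    Market Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates feedback-modified Stuart-Landau oscillator networks
    whose synchronization transition can be tuned continuously from gradual
    (second-order) to explosive (first-order), locates critical coupling by
    the peak of the pair correlation function, and estimates proximity to
    explosive synchronization from time series alone as the kurtosis of
    moving-window lagged autocorrelations of the instantaneous order
    parameter. Includes the perturbation protocol measuring time to loss and
    recovery of the baseline critical state, an end-to-end pipeline for
    band-limited multichannel recordings (Hilbert phases, order parameter,
    windowed ACF kurtosis), collapse/recovery-rate analysis of daily price
    panels, detrended fluctuation analysis as a comparator, and seeded
    synthetic-data generators for surrogate recordings and market panels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
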