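Package: thetasweeps
Title: Simulation, Decoding and Alternation Analysis of Theta Sweeps in
    Entorhinal-Hippocampal Population Activity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying left-right-alternating theta sweeps in
    spatially tuned neural populations. Provides a synthetic-session
    generator (grid, place and direction cells with Poisson spiking driven
    by latent within-theta-cycle sweep trajectories), preprocessing
    (temporal binning, cross-validated rate maps, population theta-phase
    estimation, burst and theta-cycle-skipping indices, grid-module
    identification, sleep staging), population-vector and Bayesian decoders
    of position and direction, per-theta-cycle sweep extraction with
    alternation statistics, cross-correlogram detection of putative
    excitatory connections, a Poisson GLM with a theta-phase-dependent
    shift of the position covariate, and an overlap-minimizing
    sweep-generating agent model.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    signal,
    igraph
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
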