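Package: spikenet
Title: Stochastic Spiking Network Simulation, State-Distribution Sampling,
    and Constraint Satisfaction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying stochastic computation in recurrent networks
    of spiking neurons. Provides a time-stepped simulator for escape-noise
    leaky integrate-and-fire neurons with conductance-based or rectangular
    current-pulse synapses, axonal delays, absolute refractoriness and
    Tsodyks-Markram short-term plasticity; extraction of windowed binary
    network states and estimation of stationary, phase-specific and
    trajectory distributions from spike trains; Gelman-Rubin univariate and
    multivariate convergence diagnostics over independent runs; an exact
    brute-force oracle for discretized tiny networks (transition kernels,
    total-variation contraction, stationary and periodically stationary
    distributions); constructors for laminar cortical-microcircuit,
    sparse, sequential and bistable network families; and a compiler from
    constraint-satisfaction problems with one-hot variables into
    winner-take-all spiking networks, demonstrated on Sudoku with an
    event-driven simulation backend.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
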