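Package: metaloop
Title: Two-Loop Meta-Optimization for Simulation-Based Neuroscience Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-loop (learning-to-learn style) optimization framework for
    simulation-based models. The inner loop runs an "optimizee" -- any
    simulation that maps a named parameter set (an individual) to a fitness
    vector -- over a population of individuals, optionally in parallel; the
    outer loop applies a population-based optimizer (ensemble Kalman
    inversion with rank-based replacement, genetic algorithm with a Hall of
    Fame, evolution strategies, gradient and multi-gradient ascent,
    simulated annealing, cross-entropy, grid search) to propose the next
    generation. Ships desk-scale computational-neuroscience testbeds that
    exercise every fitness function: a leaky integrate-and-fire (LIF)
    spiking-network simulator with a reservoir digit classifier, a spiking
    policy network for the mountain-car control task, an adaptive
    integrate-and-fire toy cell for electrophysiology trace fitting, and a
    coupled-oscillator surrogate for functional-vs-structural brain
    connectivity fitting.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    MASS,
    parallel,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
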