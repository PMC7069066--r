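Package: cloudwire
Title: Cloud-Based Connectome Null Models and Higher-Order Network
    Analysis of Cortical Microcircuits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to separate first-order from higher-order structure in
    directed synaptic connectomes. Builds control connectomes from
    type-averaged axon and dendrite density clouds (squared-overlap
    transfer and sequential weighted sampling without replacement),
    transplants them into a reference wiring with loss accounting, and
    provides matched-removal and path-length-shuffle controls. Includes
    directed flag-complex statistics (simplex and maximal-simplex counts,
    higher-order degrees, connection participation and polarity, Euler
    characteristic, Betti numbers on small graphs), directed clustering
    and small-worldness, triad censuses, first-order validation metrics
    (distance distributions, Kullback-Leibler divergence, reciprocity,
    macroconnectome comparison, common-neighbour bias), a seeded
    stochastic spiking simulator with a calcium-like excitability knob,
    and spike-train analytics (firing rates, spike-time reliability,
    PSTH correlation matrices, trial correlations, spatial and
    simplex-position correlation profiles). A synthetic-circuit generator
    with controllable within-type morphological diversity makes the whole
    pipeline testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    igraph,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
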