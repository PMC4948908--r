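Package: vnboost
Title: Boosting Nonlinearity in Vestibular Nucleus Neuron Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of a conductance-based vestibular nucleus
    neuron model with calcium and calcium-activated potassium currents, and of
    its reduction to a generalized adaptive quadratic integrate-and-fire (QIF)
    model. Provides fixed-step and adaptive integrators, spike and burst
    detection with interspike-interval return maps, fixed-point and bifurcation
    analysis (saddle-node versus Hopf spiking onset), an analytic slow-gating
    theory for the steady-state firing rate and its gain across the boosting
    nonlinearity, and an iterative self-consistent algorithm for spike-waveform
    reset conditions.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    deSolve,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
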