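Package: rtcycle
Title: One-Dimensional Three-State Run-and-Tumble Dynamics with a Cell Cycle
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis of a one-dimensional three-state
    run-and-tumble model of bacterial motility coupled to a cell cycle:
    right-moving and left-moving swimmer populations exchange direction at a
    tumbling rate, settle into a sedentary proliferating state, and sedentary
    cells double into a pair of opposite movers.  The package provides the
    exact well-mixed population dynamics (eigenstructure, stationary states,
    matrix-exponential propagation, logistic growth), the Fourier-space
    solution of the free spatial model with intermediate scattering functions,
    displacement moments and their short- and long-time expansions, an
    event-driven stochastic particle simulator, linear stability analysis of
    the interacting model (dispersion relation, stability conditions,
    separatrix fits), a finite-difference Runge-Kutta solver for the full
    nonlinear reaction-advection-diffusion system on a periodic domain, and
    classification of the emerging static and traveling density waves into a
    non-equilibrium state diagram.  A parameter preset for Caulobacter
    crescentus is included.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    Matrix,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
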