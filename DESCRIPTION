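Package: abmctrl
Title: Optimal Control of Agent-Based Models via ODE Surrogate Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Derives ordinary-differential-equation surrogate models from
    trajectory ensembles of stochastic lattice agent-based models (ABMs),
    solves optimal control problems on the calibrated surrogates, and
    transfers the solutions back to the ABM for validation. Ships two
    reference ABMs (a sheep-wolves-grass predator-prey model and an
    elementary-step enzymatic pathway model), four surrogate families
    (mechanistic, generalized mass action, Taylor expansions at a steady
    state, and S-systems), least-squares trajectory calibration with
    optional L1 regularization, steady-state transfer and inflow
    optimization solvers, and a replicate-averaged grid-search oracle run
    directly on the ABM.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    deSolve,
    minpack.lm,
    lhs,
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    jsonlite,
    generics,
    ggplot2,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
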