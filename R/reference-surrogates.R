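#' Mechanistic surrogate of the sheep-wolves-grass model
#'
#' The model-reduced mass-action system with grass X, sheep Y and wolves Z:
#' \deqn{dX/dt = k_1 X - k_2 X^2 - k_3 X Y}
#' \deqn{dY/dt = k_4 X Y - k_5 Y - k_6 Y Z}
#' \deqn{dZ/dt = k_7 Y Z - k_8 Z}
#' i.e. logistic grass growth plus a Lotka-Volterra food chain. Each of the
#' eight mass-action terms is a separate process with its own rate constant.
#'
#' @param k named or unnamed vector of the eight rate constants.
#' @return A `mechanistic_surrogate` with labels `grass`, `sheep`, `wolves`.
#' @export
sheep_wolves_mechanistic <- function(k = c(k1 = 0.05, k2 = 2e-5, k3 = 2e-4,
                                           k4 = 1e-4, k5 = 0.02, k6 = 1e-3,
                                           k7 = 2e-4, k8 = 0.02)) {
  stopifnot(length(k) == 8, all(k > 0))
  labels <- c("grass", "sheep", "wolves")
  g <- function(...) c(...)
  processes <- list(
    process_term("power_law", alpha = k[[1]], g = g(1, 0, 0)), # grass growth
    process_term("power_law", alpha = k[[2]], g = g(2, 0, 0)), # grass crowding
    process_term("power_law", alpha = k[[3]], g = g(1, 1, 0)), # grazing
    process_term("power_law", alpha = k[[4]], g = g(1, 1, 0)), # sheep growth
    process_term("power_law", alpha = k[[5]], g = g(0, 1, 0)), # sheep death
    process_term("power_law", alpha = k[[6]], g = g(0, 1, 1)), # predation loss
    process_term("power_law", alpha = k[[7]], g = g(0, 1, 1)), # wolf growth
    process_term("power_law", alpha = k[[8]], g = g(0, 0, 1))  # wolf death
  )
  stoich <- rbind(
    grass  = c(1, -1, -1, 0, 0, 0, 0, 0),
    sheep  = c(0, 0, 0, 1, -1, -1, 0, 0),
    wolves = c(0, 0, 0, 0, 0, 0, 1, -1))
  mechanistic_model(labels, stoich, processes)
}

#' GMA surrogate of the sheep-wolves-grass model
#'
#' Seven power-law processes (net grass growth, grazing, sheep growth, sheep
#' death, predation loss, wolf growth, wolf death), each depending on all
#' three state variables, giving `7 * (1 + 3) = 28` free parameters. Kinetic
#' orders are initialized at their mass-action values (the net grass-growth
#' process collapses the logistic pair into a single power law).
#'
#' @param alpha initial rate constants (length 7).
#' @param orders initial `7 x 3` kinetic-order matrix.
#' @export
sheep_wolves_gma <- function(alpha = rep(0.02, 7), orders = NULL) {
  labels <- c("grass", "sheep", "wolves")
  stoich <- rbind(
    grass  = c(1, -1, 0, 0, 0, 0, 0),
    sheep  = c(0, 0, 1, -1, -1, 0, 0),
    wolves = c(0, 0, 0, 0, 0, 1, -1))
  if (is.null(orders)) {
    orders <- rbind(
      c(1, 0, 0),  # net grass growth
      c(1, 1, 0),  # grazing
      c(1, 1, 0),  # sheep growth
      c(0, 1, 0),  # sheep death
      c(0, 1, 1),  # predation loss
      c(0, 1, 1),  # wolf growth
      c(0, 0, 1))  # wolf death
  }
  gma_model(labels, stoich, alpha = alpha, orders = orders)
}

#' Convert a power-law mechanistic model to its exact GMA form
#'
#' Any mechanistic model whose processes are all power laws (mass action
#' included) has a GMA parameterization with an identical right-hand side
#' everywhere on the positive orthant; this performs that term-by-term
#' rewrite. Used as the algebraic identity oracle in the tests.
#'
#' @param model a `mechanistic_surrogate` with only `power_law` processes.
#' @export
as_gma <- function(model) {
  stopifnot(inherits(model, "mechanistic_surrogate"))
  kinds <- vapply(model$processes, `[[`, character(1), "kind")
  if (!all(kinds == "power_law")) {
    abort("only models with pure power-law processes have an exact GMA form")
  }
  alpha <- vapply(model$processes, `[[`, numeric(1), "alpha")
  orders <- do.call(rbind, lapply(model$processes, `[[`, "g"))
  gma_model(model$labels, model$stoich, alpha = alpha, orders = orders)
}

#' Mechanistic surrogate of the metabolic pathway
#'
#' The mean-field model of the elementary-step pathway: four irreversible
#' Michaelis-Menten reactions over free metabolite counts S, A, B, R, T,
#' with the two regulatory interactions as competitive inhibition factors
#' (T inhibits the B -> R branch, R inhibits the B -> T branch). Continuous
#' (chemostat) operation is expressed through an attached inflow control
#' term with first-order outflow on all metabolites.
#'
#' @param vmax,km Michaelis-Menten parameters of reactions 1-4.
#' @param ki inhibition constants of the two regulatory interactions
#'   (`c(T_on_3, R_on_4)`).
#' @param continuous attach the chemostat control term (inflow on S plus
#'   outflow on every metabolite)?
#' @param outflow first-order outflow rate per step (reference 0.0005).
#' @export
metabolic_mechanistic <- function(vmax = c(0.76, 0.76, 0.38, 0.38),
                                  km = c(2950, 2950, 1950, 1950),
                                  ki = c(4, 4),
                                  continuous = FALSE, outflow = 5e-4) {
  stopifnot(length(vmax) == 4, length(km) == 4, length(ki) == 2,
            all(c(vmax, km, ki) > 0))
  labels <- c("S", "A", "B", "R", "T")
  processes <- list(
    process_term("michaelis_menten", vmax = vmax[1], km = km[1], substrate = 1),
    process_term("michaelis_menten", vmax = vmax[2], km = km[2], substrate = 2),
    process_term("michaelis_menten", vmax = vmax[3], km = km[3], substrate = 3,
                 inhibitor = 5, ki = ki[1]),
    process_term("michaelis_menten", vmax = vmax[4], km = km[4], substrate = 3,
                 inhibitor = 4, ki = ki[2]))
  stoich <- rbind(
    S = c(-1, 0, 0, 0),
    A = c(1, -1, 0, 0),
    B = c(0, 1, -1, -1),
    R = c(0, 0, 1, 0),
    T = c(0, 0, 0, 1))
  model <- mechanistic_model(labels, stoich, processes)
  if (continuous) {
    model <- add_control(model, control_inflow("S", Q = 0, outflow = outflow))
  }
  model
}

#' Generic surrogate skeletons for a set of state labels
#'
#' Convenience constructors of untrained GMA (all-variable power laws over a
#' declared stoichiometry), S-system and Taylor skeletons for either
#' reference model, ready for [fit_parameters()].
#'
#' @param labels state-variable names.
#' @param x0 steady state (Taylor families).
#' @param family surrogate family.
#' @param stoich stoichiometric matrix (GMA).
#' @export
surrogate_skeleton <- function(family = c("ssystem", "linear", "quadratic"),
                               labels, x0 = NULL, stoich = NULL) {
  family <- match.arg(family)
  n <- length(labels)
  switch(family,
    ssystem = ssystem_model(labels,
                            alpha = rep(0.1, n), beta = rep(0.1, n),
                            g = matrix(0, n, n),
                            h = diag(n)),
    linear = {
      stopifnot(!is.null(x0))
      taylor_model(labels, x0, order = 1)
    },
    quadratic = {
      stopifnot(!is.null(x0))
      taylor_model(labels, x0, order = 2)
    })
}
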