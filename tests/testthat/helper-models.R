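# tiny fixtures shared across tests

tiny_sw <- function(...) {
  args <- utils::modifyList(
    list(width = 21, height = 21, initial_sheep = 30, initial_wolves = 12),
    list(...))
  do.call(sheep_wolves_params, args)
}

tiny_met <- function(...) {
  metabolic_params(width = 8, height = 8,
                   initial_counts = c(S = 60, E1 = 8, E2 = 8, E3 = 4, E4 = 4),
                   ...)
}

# a one-variable logistic resource model: dX/dt = k1 X - k2 X^2
logistic_surrogate <- function(k1 = 2, k2 = 1) {
  mechanistic_model("x", matrix(1, 1, 1),
                    list(process_term("logistic_growth", k1 = k1, k2 = k2,
                                      var = 1)))
}

# reference mechanistic parameter set used when an exactly known
# Lotka-Volterra system is needed
lv_k <- c(k1 = 0.05, k2 = 2e-5, k3 = 2e-4, k4 = 1e-4, k5 = 0.02,
          k6 = 1e-3, k7 = 2e-4, k8 = 0.02)

# integrate with the calibration path's solver settings (lsoda, capped)
fit_path_integrate <- function(model, x0, times, u = NULL) {
  abmctrl:::.integrate_matrix(model, x0, times, u = u, methods = "lsoda",
                              maxsteps = 100, rtol = 1e-5, atol = 1e-5)$values
}
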