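test_that("ensemble averaging computes pointwise mean and sample sd", {
  times <- 0:5
  t1 <- new_trajectory(times, matrix(0, 6, 1), "x", replicate = 1)
  t2 <- new_trajectory(times, matrix(2, 6, 1), "x", replicate = 2)
  ds <- average_ensemble(dplyr::bind_rows(t1, t2))
  m <- dataset_matrix(ds)
  expect_true(all(m$mean == 1))
  expect_true(all(abs(m$sd - sqrt(2)) < 1e-12))

  # identical replicates: mean equals the replicate, sd 0
  ds2 <- average_ensemble(dplyr::bind_rows(
    t1, dplyr::mutate(t1, replicate = 2L)))
  m2 <- dataset_matrix(ds2)
  expect_true(all(m2$mean == 0))
  expect_true(all(m2$sd == 0))
})

test_that("the mean of many noisy replicates concentrates as CLT predicts", {
  set.seed(20)
  times <- 0:20
  sigma <- 3
  reps <- purrr::map(1:100, function(r) {
    new_trajectory(times, matrix(50 + rnorm(21, sd = sigma), ncol = 1), "x",
                   replicate = r)
  }) |> purrr::list_rbind()
  m <- dataset_matrix(average_ensemble(reps))
  expect_true(all(abs(m$mean - 50) < 4 * sigma / sqrt(100)))
})

test_that("steady-state estimation averages the trajectory tail", {
  times <- 0:99
  vals <- cbind(c(seq(100, 10, length.out = 50), rep(10, 50)))
  ds <- average_ensemble(new_trajectory(times, vals, "x"))
  expect_equal(unname(estimate_steady_state(ds, 0.25)), 10)

  # a symmetric oscillation about c averages back to c
  osc <- cbind(20 + 5 * sin(2 * pi * times / 10))
  ds2 <- average_ensemble(new_trajectory(times, osc, "x"))
  expect_lt(abs(estimate_steady_state(ds2, 0.4) - 20), 0.5)

  short <- average_ensemble(new_trajectory(0:5, cbind(1:6), "x"))
  expect_error(estimate_steady_state(short, 0.2), "fewer than 2")
})

test_that("slope-based initialization recovers a known decay rate", {
  # dX/dt = -0.01 X in step units, sampled densely
  tt <- 0:200
  ds <- average_ensemble(new_trajectory(tt, cbind(5 * exp(-0.01 * tt)), "x"))
  m <- mechanistic_model("x", matrix(-1, 1, 1),
                         list(process_term("power_law", alpha = 1, g = 1)))
  guess <- initial_guess_slopes(ds, m)
  expect_lt(abs(guess[[1]] - 0.01) / 0.01, 0.05)
})

test_that("slope initialization floors rates on constant data and needs 3 points", {
  ds <- average_ensemble(new_trajectory(0:10, cbind(rep(7, 11)), "x"))
  m <- mechanistic_model("x", matrix(-1, 1, 1),
                         list(process_term("power_law", alpha = 1, g = 1)))
  expect_equal(unname(initial_guess_slopes(ds, m)), 1e-6)
  tiny <- average_ensemble(new_trajectory(0:1, cbind(c(1, 2)), "x"))
  expect_error(initial_guess_slopes(tiny, m), "3 time points")
})

test_that("fitting noise-free self-generated data is self-consistent", {
  truth <- as_gma(sheep_wolves_mechanistic(k = lv_k))
  times <- seq(0, 300, by = 5)
  # generate with the same solver settings the fit uses, so the only
  # deviation measured is the optimizer's
  sim <- fit_path_integrate(truth, c(1200, 110, 40), times)
  traj <- new_trajectory(times, sim, truth$labels)
  ds <- average_ensemble(traj, "I")
  fit <- fit_parameters(truth, list(ds), starts = 1)
  expect_lt(fit$residual, 1e-8)
  expect_true(fit$converged)
  # recovered trajectory is indistinguishable from the training data
  resim <- fit_path_integrate(fit$model, c(1200, 110, 40), times)
  rel <- abs(resim - sim) / pmax(sim, 1)
  expect_lt(max(rel), 1e-4)
})

test_that("the returned fit never exceeds the initial-guess residual", {
  truth <- as_gma(sheep_wolves_mechanistic(k = lv_k))
  times <- seq(0, 200, by = 5)
  sim <- integrate_surrogate(truth, c(1200, 110, 40), times)
  ds <- average_ensemble(new_trajectory(times, as.matrix(sim[, -1]),
                                        truth$labels), "I")
  start_model <- set_params(truth, surrogate_params(truth) * 1.3)
  fit <- fit_parameters(start_model, list(ds), starts = 1)
  d <- prepare_datasets(start_model, list(ds), 1)
  r0 <- sum(residual_fn_unpenalized(start_model, d,
                                    list(rep(1, 3)))^2)
  expect_lte(fit$residual, r0)
})

test_that("a dominant L1 weight drives kinetic orders to zero", {
  truth <- as_gma(sheep_wolves_mechanistic(k = lv_k))
  times <- seq(0, 200, by = 10)
  sim <- integrate_surrogate(truth, c(1200, 110, 40), times)
  ds <- average_ensemble(new_trajectory(times, as.matrix(sim[, -1]),
                                        truth$labels), "I")
  fit <- fit_parameters(truth, list(ds), lambda = 1e12, starts = 1,
                        maxiter = 200)
  expect_true(all(fit$zero_mask[order_indices(truth)]))
})

test_that("L1 regularization cannot improve the unpenalized residual", {
  truth <- as_gma(sheep_wolves_mechanistic(k = lv_k))
  times <- seq(0, 200, by = 10)
  sim <- integrate_surrogate(truth, c(1200, 110, 40), times)
  noisy <- as.matrix(sim[, -1]) * matrix(runif(length(times) * 3, 0.98, 1.02),
                                         ncol = 3)
  ds <- average_ensemble(new_trajectory(times, noisy, truth$labels), "I")
  f0 <- fit_parameters(truth, list(ds), lambda = 0, starts = 1)
  f1 <- fit_parameters(truth, list(ds), lambda = 100, starts = 1)
  expect_gte(f1$residual, f0$residual - 1e-8)
})

test_that("datasets with mismatched labels are rejected", {
  ds <- average_ensemble(new_trajectory(0:10, cbind(1:11), "mass"))
  truth <- sheep_wolves_gma()
  expect_error(fit_parameters(truth, list(ds)), "expects")
})

test_that("controlled datasets require a control term on the model", {
  ds <- average_ensemble(new_trajectory(0:10, matrix(1, 11, 3),
                                        c("grass", "sheep", "wolves")),
                         control = c(sheep = 0.02))
  expect_error(fit_parameters(sheep_wolves_gma(), list(ds)),
               "no control term")
})

test_that("quadratic fits reject candidates with extra in-domain roots", {
  # training data from a pure linear relaxation
  x0 <- c(50, 30)
  J <- matrix(c(-0.05, 0.01, 0.02, -0.08), 2, 2)
  lin <- taylor_model(c("a", "b"), x0, order = 1, J = J)
  times <- seq(0, 150, by = 2)
  sim <- integrate_surrogate(lin, c(80, 10), times)
  ds <- average_ensemble(new_trajectory(times, as.matrix(sim[, -1]),
                                        lin$labels), "I")
  quad <- taylor_model(c("a", "b"), x0, order = 2)
  fit <- fit_quadratic_with_root_constraint(quad, list(ds),
                                            lower_domain = c(0, 0),
                                            upper_domain = c(120, 120),
                                            starts = 2, seed = 1)
  expect_true(fit$admissible)
  expect_lt(fit$residual, 1)
  roots <- find_roots(fit$model, c(0, 0), c(120, 120), starts = 4)
  extra <- purrr::keep(roots, function(r) any(abs(r - x0) > 6))
  expect_equal(length(extra), 0)

  # the expansion point must lie inside the domain
  expect_error(
    fit_quadratic_with_root_constraint(quad, list(ds),
                                       lower_domain = c(60, 60),
                                       upper_domain = c(120, 120)),
    "inside the domain")
})
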