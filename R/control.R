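#' Define a steady-state transfer control problem
#'
#' Find constant proportional removal rates that move the system from its
#' baseline steady state `x0` to a new steady state specified as per-variable
#' multipliers of `x0` (untargeted variables are free), at minimal total
#' removal. The reference problem asks for 50% fewer wolves and 10% more
#' sheep via the control input `u = [0, -kappa2 Y, -kappa3 Z]'`.
#'
#' @param multipliers named multipliers for the targeted variables only
#'   (e.g. `c(sheep = 1.1, wolves = 0.5)`).
#' @param x0 named baseline steady state.
#' @param horizon steps over which total removal is accounted and the
#'   controlled system is relaxed to its steady state.
#' @param tol relative match tolerance per targeted variable.
#' @param kappa_upper upper bound of each removal rate during the solve;
#'   scalar or named per-variable (solutions should stay inside the control
#'   levels the surrogate was trained on, so that solving is interpolation).
#' @param control_vars variables whose removal rates are optimized; defaults
#'   to the targeted variables (the reference input matrix is
#'   `diag(0, 1, 1)`: removal acts on sheep and wolves only).
#' @export
transfer_problem <- function(multipliers, x0, horizon = 2000, tol = 0.01,
                             kappa_upper = 0.2,
                             control_vars = names(multipliers)) {
  stopifnot(all(multipliers > 0), !is.null(names(multipliers)),
            all(names(multipliers) %in% names(x0)), horizon >= 1)
  if (length(kappa_upper) == 1) {
    kappa_upper <- setNames(rep(kappa_upper, length(control_vars)),
                            control_vars)
  }
  structure(list(multipliers = multipliers, x0 = x0, horizon = horizon,
                 tol = tol, kappa_upper = kappa_upper[control_vars],
                 control_vars = control_vars),
            class = "transfer_problem")
}

#' Define an inflow optimization control problem
#'
#' Find the constant substrate inflow `Q_in` in `domain` minimizing the
#' cumulative substrate-to-product loss `sum_k S_k / (R_k + T_k)` over a
#' fixed horizon (reference: 50,000 steps, outflow 0.05% per step).
#'
#' @param domain inflow interval (within \[0, 1\]).
#' @param horizon number of time steps of the evaluation run.
#' @param outflow first-order outflow rate.
#' @param policy zero-denominator policy for the loss (see [loss_qin()]).
#' @export
inflow_problem <- function(domain = c(0, 1), horizon = 50000,
                           outflow = 5e-4, policy = c("skip", "strict")) {
  stopifnot(length(domain) == 2, domain[1] <= domain[2],
            domain[1] >= 0, domain[2] <= 1, horizon >= 1)
  structure(list(domain = domain, horizon = horizon, outflow = outflow,
                 policy = match.arg(policy)),
            class = "inflow_problem")
}

wide_traj <- function(traj) {
  if (all(c("variable", "value") %in% names(traj))) {
    labels <- traj_labels(traj)
    traj <- tidyr::pivot_wider(traj, id_cols = "time",
                               names_from = "variable",
                               values_from = "value")
    traj <- dplyr::arrange(traj, .data$time)
  }
  traj
}

#' Substrate-to-product loss of a trajectory
#'
#' The inflow-optimization objective: `sum_k S_k / (R_k + T_k)` over steps
#' `k >= 1`. On trajectories recorded with a stride, each sampled step is
#' weighted by the grid spacing (so the value approximates the per-step
#' sum). Steps with `R_k + T_k = 0` are handled by `policy`: `"skip"`
#' (default) omits them and reports their number in the `"skipped"`
#' attribute; `"strict"` raises an error.
#'
#' @param traj a trajectory containing variables `S`, `R` and `T` (tidy or
#'   wide).
#' @param policy zero-denominator policy.
#' @return The loss (numeric) with attribute `skipped`.
#' @export
loss_qin <- function(traj, policy = c("skip", "strict")) {
  policy <- match.arg(policy)
  w <- wide_traj(traj)
  missing <- setdiff(c("S", "R", "T"), names(w))
  if (length(missing) > 0) {
    abort(paste0("trajectory lacks variable(s): ", paste(missing, collapse = ", ")))
  }
  w <- w[w$time > min(w$time), ]
  dt <- diff(c(min(traj$time), w$time))
  den <- w$R + w$T
  zero <- den <= 0
  if (any(zero) && policy == "strict") {
    abort(sprintf("R + T = 0 at %d step(s); loss undefined under strict policy",
                  sum(zero)),
          class = "abmctrl_loss_undefined")
  }
  value <- sum((w$S[!zero] / den[!zero]) * dt[!zero])
  structure(value, skipped = sum(zero))
}

#' Total number of individuals removed by proportional control
#'
#' For removal rates `kappa` applied to a trajectory, returns
#' `sum_k sum_v kappa_v X_v(k)` over steps `k >= 1` (grid-spacing weighted
#' on strided trajectories), the expected removal count of the Bernoulli
#' control and the removal integral of the continuous surrogate.
#'
#' @param traj trajectory containing the targeted variables (tidy or wide).
#' @param kappa named non-negative removal rates.
#' @export
total_removed <- function(traj, kappa) {
  if (any(kappa < 0)) abort("removal rates must be >= 0")
  w <- wide_traj(traj)
  missing <- setdiff(names(kappa), names(w))
  if (length(missing) > 0) {
    abort(paste0("trajectory lacks variable(s): ", paste(missing, collapse = ", ")))
  }
  w0 <- w[w$time > min(w$time), ]
  dt <- diff(c(min(w$time), w0$time))
  sum(vapply(names(kappa), function(v) {
    sum(kappa[[v]] * w0[[v]] * dt)
  }, numeric(1)))
}

#' Steady state of a controlled surrogate
#'
#' Long-horizon integration from `x0` followed by root polishing of the
#' controlled right-hand side (controlled power-law systems rarely admit
#' closed-form steady states).
#'
#' @param model an `ode_surrogate` with control attached.
#' @param u named control parameter values.
#' @param x0 starting state.
#' @param horizon relaxation horizon in time steps.
#' @return Named steady-state vector.
#' @export
steady_state_controlled <- function(model, u, x0, horizon = 20000) {
  times <- seq(0, horizon, length.out = 201)
  sol <- .integrate_matrix(model, x0, times, u = u)
  xT <- sol$values[nrow(sol$values), ]
  # damped Newton polish (plain implementation: must be safely callable from
  # inside another optimizer, which Levenberg-Marquardt backends are not)
  f <- function(p) tryCatch(rhs(model, p, u),
                            error = function(e) rep(NA_real_, length(p)))
  x <- xT
  fx <- f(x)
  if (all(is.finite(fx))) {
    for (it in 1:20) {
      J <- num_jacobian(f, x)
      step <- tryCatch(solve(J, fx), error = function(e) NULL)
      if (is.null(step) || any(!is.finite(step))) break
      lambda <- 1
      improved <- FALSE
      for (k in 1:6) {
        xn <- pmax(x - lambda * step, 0)
        fn <- f(xn)
        if (all(is.finite(fn)) && max(abs(fn)) < max(abs(fx))) {
          x <- xn; fx <- fn; improved <- TRUE
          break
        }
        lambda <- lambda / 2
      }
      if (!improved || max(abs(fx)) < 1e-12 * max(1, max(abs(x)))) break
    }
  }
  out <- if (all(is.finite(fx)) && max(abs(fx)) <= max(abs(rhs(model, xT, u))))
    x else xT
  setNames(as.numeric(out), model$labels)
}

# damped Newton on a box with explicit finite-difference steps (robust when
# the residual comes out of an ODE solve, whose discretization jitter defeats
# machine-epsilon difference steps)
newton_box <- function(f, x, lower, upper, fd_step = 1e-4, maxit = 30) {
  clamp <- function(p) pmin(pmax(p, lower), upper)
  x <- clamp(x)
  fx <- f(x)
  if (any(!is.finite(fx))) return(NULL)
  for (it in seq_len(maxit)) {
    if (max(abs(fx)) < 1e-10) break
    J <- matrix(0, length(fx), length(x))
    for (j in seq_along(x)) {
      h <- fd_step
      xp <- x; xp[j] <- min(xp[j] + h, upper[j])
      hj <- xp[j] - x[j]
      if (hj == 0) { xp[j] <- x[j] - h; hj <- -h }
      J[, j] <- (f(xp) - fx) / hj
    }
    step <- tryCatch(solve(J, fx), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) break
    lambda <- 1; improved <- FALSE
    for (k in 1:8) {
      xn <- clamp(x - lambda * step)
      fn <- f(xn)
      if (all(is.finite(fn)) && max(abs(fn)) < max(abs(fx))) {
        x <- xn; fx <- fn; improved <- TRUE
        break
      }
      lambda <- lambda / 2
    }
    if (!improved) break
  }
  x
}

num_jacobian <- function(f, x, eps = 1e-6) {
  n <- length(x)
  f0 <- f(x)
  J <- matrix(0, length(f0), n)
  for (j in seq_len(n)) {
    h <- eps * max(1, abs(x[j]))
    xp <- x; xp[j] <- xp[j] + h
    J[, j] <- (f(xp) - f0) / h
  }
  J
}

#' Solve the steady-state transfer problem on a surrogate
#'
#' Root-finds the removal rates at which the controlled surrogate's steady
#' state matches the target (multipliers times the baseline steady state) on
#' the targeted variables, from multiple starts; among matching solutions
#' the one minimizing [total_removed()] over the horizon is returned. If no
#' candidate matches within tolerance the best candidate is returned with
#' `feasible = FALSE`.
#'
#' @param model a calibrated `ode_surrogate` with a removal control term.
#' @param problem a [transfer_problem()].
#' @param starts number of starting points for the root search.
#' @return A `control_solution` with elements `kappa`, `objective`
#'   (total removed), `feasible`, `achieved`, `mismatch`.
#' @export
solve_transfer_on_surrogate <- function(model, problem, starts = 4) {
  stopifnot(inherits(problem, "transfer_problem"),
            !is.null(model$control), model$control$type == "removal")
  targets <- names(problem$multipliers)
  knames <- problem$control_vars
  bad <- setdiff(knames, names(model$control$kappa))
  if (length(bad) > 0) {
    abort(paste0("model control term lacks removal on: ",
                 paste(bad, collapse = ", ")))
  }
  x0 <- problem$x0[model$labels]
  target_vals <- problem$multipliers * problem$x0[targets]
  if (any(target_vals < 0)) {
    abort("target steady state has a negative population")
  }

  fixed_zero <- setdiff(names(model$control$kappa), knames)
  resid <- function(kappa) {
    u <- c(setNames(kappa, knames), setNames(rep(0, length(fixed_zero)), fixed_zero))
    ss <- tryCatch(
      steady_state_controlled(model, u, x0, horizon = 10 * problem$horizon),
      error = function(e) rep(NA_real_, model$n) |> setNames(model$labels))
    r <- (ss[targets] - target_vals) / pmax(target_vals, 1e-9)
    r[!is.finite(r)] <- 1e4
    r
  }

  upper <- unname(problem$kappa_upper[knames])
  k0s <- list(rep(1e-6, length(knames)))
  if (starts > 1) {
    for (s in seq_len(starts - 1)) {
      k0s[[s + 1]] <- upper * (s / starts)
    }
  }
  cand <- list()
  for (k0 in k0s) {
    kappa <- newton_box(resid, k0, lower = rep(0, length(knames)),
                        upper = upper, fd_step = 1e-4)
    if (is.null(kappa)) next
    kappa <- setNames(kappa, knames)
    mism <- max(abs(resid(unname(kappa))))
    cand[[length(cand) + 1]] <- list(kappa = kappa, mismatch = mism)
  }
  if (length(cand) == 0) {
    abort("transfer solve failed: no start produced an integrable candidate",
          class = "abmctrl_integration_error")
  }
  score <- function(c1) {
    u <- c(c1$kappa, setNames(rep(0, length(fixed_zero)), fixed_zero))
    traj <- tryCatch(
      integrate_surrogate(model, x0,
                          seq(0, problem$horizon, length.out = 201), u = u),
      error = function(e) NULL)
    if (is.null(traj)) return(Inf)
    total_removed(traj, u)
  }
  matches <- purrr::keep(cand, function(c1) c1$mismatch <= problem$tol)
  pick_from <- if (length(matches) > 0) matches else cand
  objectives <- vapply(pick_from, score, numeric(1))
  best <- pick_from[[which.min(objectives)]]
  achieved <- steady_state_controlled(model, best$kappa, x0,
                                      horizon = 10 * problem$horizon)
  structure(list(
    type = "transfer",
    kappa = best$kappa,
    objective = min(objectives),
    feasible = length(matches) > 0,
    mismatch = best$mismatch,
    achieved = achieved,
    problem = problem
  ), class = "control_solution")
}

#' Solve the inflow optimization problem on a surrogate
#'
#' Scans the surrogate-predicted loss over a dense inflow grid and refines
#' the best interior point by local 1-D minimization. Inflow values where
#' the surrogate cannot be integrated are recorded, and the integrable
#' sub-domain is reported; if the loss has no interior minimum there, the
#' solution is flagged `no_interior_minimum` (surrogates are routinely
#' integrable on only part of the domain).
#'
#' @param model a calibrated surrogate with an inflow control term.
#' @param problem an [inflow_problem()].
#' @param x0 initial state of the evaluation run.
#' @param step grid step of the scan.
#' @param thin evaluate the loss on every `thin`-th step of the horizon.
#' @return A `control_solution` with elements `Q`, `objective`, `feasible`,
#'   `no_interior_minimum`, `integrable_domain` and the scan tibble `grid`.
#' @export
solve_inflow_on_surrogate <- function(model, problem, x0, step = 0.05,
                                      thin = 20) {
  stopifnot(inherits(problem, "inflow_problem"),
            !is.null(model$control), model$control$type == "inflow")
  dom <- problem$domain
  if (dom[1] == dom[2]) {
    return(structure(list(type = "inflow", Q = dom[1], objective = NA_real_,
                          feasible = TRUE, no_interior_minimum = FALSE,
                          integrable_domain = dom,
                          grid = tibble::tibble(Q = dom[1], loss = NA_real_,
                                                ok = TRUE)),
                     class = "control_solution"))
  }
  qs <- seq(dom[1], dom[2], by = step)
  if (tail(qs, 1) < dom[2]) qs <- c(qs, dom[2])
  times <- unique(c(0, seq(thin, problem$horizon, by = thin), problem$horizon))

  eval_loss <- function(q) {
    traj <- tryCatch(
      integrate_surrogate(model, x0, times, u = c(Q = q)),
      error = function(e) NULL)
    if (is.null(traj)) return(NA_real_)
    tryCatch(as.numeric(loss_qin(traj, policy = problem$policy)),
             error = function(e) Inf)
  }
  losses <- vapply(qs, eval_loss, numeric(1))
  ok <- is.finite(losses) | losses == Inf
  grid <- tibble::tibble(Q = qs, loss = losses, ok = !is.na(losses))
  if (!any(grid$ok)) {
    abort("surrogate integrable nowhere on the inflow domain",
          class = "abmctrl_integration_error")
  }
  okq <- qs[grid$ok]
  integrable <- c(min(okq), max(okq))
  finite_idx <- which(is.finite(losses))
  if (length(finite_idx) == 0) {
    return(structure(list(type = "inflow", Q = NA_real_, objective = Inf,
                          feasible = FALSE, no_interior_minimum = TRUE,
                          integrable_domain = integrable, grid = grid),
                     class = "control_solution"))
  }
  i_best <- finite_idx[which.min(losses[finite_idx])]
  interior <- i_best > 1 && i_best < length(qs) &&
    grid$ok[i_best - 1] && grid$ok[i_best + 1] &&
    losses[i_best] <= losses[i_best - 1] && losses[i_best] <= losses[i_best + 1] &&
    (losses[i_best] < losses[i_best - 1] || losses[i_best] < losses[i_best + 1])
  q_best <- qs[i_best]
  obj <- losses[i_best]
  if (interior) {
    refine <- tryCatch(
      optimize(function(q) {
        l <- eval_loss(q)
        if (is.na(l)) Inf else l
      }, lower = qs[i_best - 1], upper = qs[i_best + 1]),
      error = function(e) NULL)
    if (!is.null(refine) && is.finite(refine$objective) &&
        refine$objective <= obj) {
      q_best <- refine$minimum
      obj <- refine$objective
    }
  }
  structure(list(
    type = "inflow", Q = q_best, objective = obj,
    feasible = TRUE,
    no_interior_minimum = !interior,
    integrable_domain = integrable,
    grid = grid
  ), class = "control_solution")
}

#' @export
print.control_solution <- function(x, ...) {
  if (x$type == "transfer") {
    cat("<control solution: steady-state transfer>\n")
    cat("  kappa:", paste(names(x$kappa), signif(x$kappa, 4),
                          sep = " = ", collapse = ", "), "\n")
    cat(sprintf("  total removed: %.4g; feasible: %s (mismatch %.3g)\n",
                x$objective, x$feasible, x$mismatch))
  } else {
    cat("<control solution: inflow optimization>\n")
    cat(sprintf("  Q_in = %.4g; loss = %.6g; integrable on [%.3g, %.3g]%s\n",
                x$Q, x$objective, x$integrable_domain[1],
                x$integrable_domain[2],
                if (x$no_interior_minimum) "; no interior minimum" else ""))
  }
  invisible(x)
}

#' Discretize a surrogate control solution into an ABM schedule
#'
#' Constant removal rates become per-step Bernoulli removal probabilities on
#' the mapped subtypes; a constant inflow becomes a Bernoulli one-molecule
#' insertion per step (the ODE time unit equals one ABM step, so rates
#' transfer one-to-one). A rate above 1 per step cannot be a probability and
#' is an error; an all-zero solution produces an empty schedule.
#'
#' @param solution a `control_solution`.
#' @param start first ABM step at which the schedule applies.
#' @return A [control_schedule()].
#' @export
transfer_to_abm <- function(solution, start = 0L) {
  stopifnot(inherits(solution, "control_solution"))
  if (solution$type == "transfer") {
    kappa <- solution$kappa
    if (any(kappa > 1)) {
      abort("removal rate exceeds 1 per step and cannot be a probability")
    }
    control_schedule(removal = kappa[kappa > 0], start = start)
  } else {
    q <- solution$Q
    if (is.na(q)) abort("inflow solution is infeasible; nothing to transfer")
    if (q > 1) abort("inflow above 1 molecule per step is not representable")
    if (q == 0) control_schedule(start = start)
    else control_schedule(inflow = c(S = q), start = start)
  }
}

#' Replicate-averaged grid search on the ABM
#'
#' The validation oracle: for every control-parameter grid point, runs
#' seeded replicate simulations of the ABM under the transferred schedule,
#' evaluates the control objective on each run, and records the mean and
#' standard deviation per point. The best point attains the minimal mean;
#' ties break to the lexicographically smallest grid point. Replicate seeds
#' derive from `seed + 1e5 * point_index + replicate` and are recorded.
#'
#' @param model an `abm_model`.
#' @param grid tibble of control-parameter points (one column per parameter).
#' @param objective `function(traj, point)` returning the per-run objective,
#'   either a bare numeric or `list(value =, outcome =)` with a named
#'   outcome vector (enables [suboptimal_band()]).
#' @param schedule_fn `function(point)` mapping a grid row (named list) to a
#'   [control_schedule()].
#' @param replicates seeded replicates per point.
#' @param steps ABM steps per run.
#' @param seed root seed.
#' @param ... passed to [run_simulation()] (e.g. `stride`).
#' @return A `grid_search_result`: the grid with `mean`, `sd` and (when the
#'   objective reports outcomes) `outcome` summary columns, plus `best`.
#' @export
grid_search_abm <- function(model, grid, objective, schedule_fn,
                            replicates = 20, steps = 2000, seed = 1, ...) {
  stopifnot(nrow(grid) >= 1, replicates >= 1)
  rows <- purrr::map(seq_len(nrow(grid)), function(i) {
    point <- as.list(grid[i, , drop = FALSE])
    schedule <- schedule_fn(point)
    vals <- numeric(replicates)
    outs <- NULL
    for (r in seq_len(replicates)) {
      run_seed <- seed + 1e5 * i + r
      traj <- run_simulation(model, steps, seed = run_seed,
                             schedule = schedule, ...)
      o <- objective(traj, point)
      if (is.list(o)) {
        vals[r] <- o$value
        outs <- rbind(outs, o$outcome)
      } else {
        vals[r] <- o
      }
    }
    row <- tibble::tibble(point_index = i, mean = mean(vals),
                          sd = sd(vals))
    if (!is.null(outs)) {
      for (v in colnames(outs)) {
        row[[paste0(v, "_mean")]] <- mean(outs[, v])
        row[[paste0(v, "_sd")]] <- sd(outs[, v])
      }
    }
    row
  })
  res <- dplyr::bind_cols(grid, purrr::list_rbind(rows))
  finite_min <- suppressWarnings(min(res$mean[is.finite(res$mean)]))
  cand <- which(res$mean == finite_min)
  if (length(cand) > 1) {
    ord <- do.call(order, as.data.frame(res[cand, names(grid), drop = FALSE]))
    cand <- cand[ord[1]]
  }
  structure(list(
    result = res,
    best = if (is.finite(finite_min)) res[cand[1], ] else res[integer(0), ],
    grid_vars = names(grid),
    replicates = replicates, steps = steps, seed = seed
  ), class = "grid_search_result")
}

#' @export
print.grid_search_result <- function(x, ...) {
  cat(sprintf("<grid search> %d points x %d replicates (%d steps)\n",
              nrow(x$result), x$replicates, x$steps))
  if (nrow(x$best) > 0) {
    cat("  best: ")
    print(as.data.frame(x$best[, c(x$grid_vars, "mean", "sd")]), row.names = FALSE)
  } else {
    cat("  no finite grid point\n")
  }
  invisible(x)
}

#' Suboptimal band of a grid search
#'
#' All grid points whose mean outcome lies within one standard deviation of
#' the target, per outcome variable, boundary inclusive — the set of
#' control settings indistinguishable from the target at the ABM's intrinsic
#' noise level.
#'
#' @param result a `grid_search_result` whose objective reported outcomes.
#' @param target named target outcome vector.
#' @param std named std vector; defaults to each point's own outcome std.
#' @return The rows of the grid inside the band.
#' @export
suboptimal_band <- function(result, target, std = NULL) {
  stopifnot(inherits(result, "grid_search_result"))
  res <- result$result
  need <- paste0(names(target), "_mean")
  if (!all(need %in% names(res))) {
    abort("grid search objective did not report the targeted outcomes")
  }
  keep <- rep(TRUE, nrow(res))
  for (v in names(target)) {
    s <- if (is.null(std)) res[[paste0(v, "_sd")]] else rep(std[[v]], nrow(res))
    keep <- keep & abs(res[[paste0(v, "_mean")]] - target[[v]]) <= s
  }
  res[keep, , drop = FALSE]
}
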