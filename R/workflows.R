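#' Build the reference surrogate of a family for an ABM
#'
#' Constructs the surrogate skeleton matching the reference ABM (state
#' labels, stoichiometry, control term) for any of the five families:
#' `"mechanistic"`, `"gma"`, `"ssystem"`, `"linear"`, `"quadratic"`.
#' Taylor families take their expansion point from the steady state of the
#' first uncontrolled dataset.
#'
#' @param model an `sw_model` or `met_model`.
#' @param family surrogate family name.
#' @param datasets list of training datasets (used for the Taylor expansion
#'   point).
#' @export
reference_surrogate <- function(model, family, datasets = NULL) {
  if (inherits(model, "sw_model")) {
    ctrl <- control_removal(c(grass = 0, sheep = 0, wolves = 0))
    labels <- model$labels
    base <- switch(family,
      mechanistic = sheep_wolves_mechanistic(),
      gma = sheep_wolves_gma(),
      ssystem = surrogate_skeleton("ssystem", labels),
      linear = ,
      quadratic = {
        x0 <- unname(estimate_steady_state(first_uncontrolled(datasets)))
        surrogate_skeleton(family, labels, x0 = x0)
      },
      abort(paste0("unknown family: ", family)))
  } else {
    labels <- model$labels
    ctrl <- control_inflow("S", Q = 0, outflow = model$outflow)
    base <- switch(family,
      mechanistic = metabolic_mechanistic(),
      gma = {
        # one power-law process per reaction plus the declared stoichiometry
        stoich <- rbind(S = c(-1, 0, 0, 0), A = c(1, -1, 0, 0),
                        B = c(0, 1, -1, -1), R = c(0, 0, 1, 0),
                        T = c(0, 0, 0, 1))
        orders <- rbind(c(1, 0, 0, 0, 0), c(0, 1, 0, 0, 0),
                        c(0, 0, 1, 0, 0), c(0, 0, 1, 0, 0))
        gma_model(labels, stoich, alpha = rep(1e-3, 4), orders = orders)
      },
      ssystem = surrogate_skeleton("ssystem", labels),
      linear = ,
      quadratic = {
        x0 <- unname(estimate_steady_state(first_uncontrolled(datasets)))
        surrogate_skeleton(family, labels, x0 = x0)
      },
      abort(paste0("unknown family: ", family)))
  }
  add_control(base, ctrl)
}

first_uncontrolled <- function(datasets) {
  if (is.null(datasets)) abort("Taylor families need training datasets")
  idx <- which(vapply(datasets, function(d) length(d$control) == 0,
                      logical(1)))
  datasets[[if (length(idx) > 0) idx[1] else 1]]
}

#' Fit a reference surrogate family to training datasets
#'
#' Convenience wrapper: builds the [reference_surrogate()] and runs
#' [fit_parameters()] (or the root-constrained quadratic fit) with defaults
#' sized for the desk-scale reproductions.
#'
#' @inheritParams reference_surrogate
#' @param seed RNG seed for the multi-start design.
#' @param mech_fit optional previously fitted mechanistic surrogate; for the
#'   power-law families its local power-law view at the data's mean state is
#'   added as a warm start.
#' @param ... passed on to the fitting routine.
#' @export
fit_reference_surrogate <- function(model, family, datasets, seed = 1,
                                    mech_fit = NULL, ...) {
  surrogate <- reference_surrogate(model, family, datasets)
  defaults <- list(thin = if (family == "ssystem") 80 else 40,
                   maxiter = if (family == "ssystem") 15 else 40,
                   seed = seed,
                   starts = switch(family, mechanistic = 2, linear = 2,
                                   quadratic = 4, ssystem = 0, 1))
  dots <- utils::modifyList(defaults, list(...))
  if (family %in% c("gma", "ssystem")) {
    if (is.null(mech_fit)) {
      mech_fit <- fit_reference_surrogate(model, "mechanistic", datasets,
                                          seed = seed,
                                          thin = dots$thin,
                                          maxiter = dots$maxiter)
    }
    xbar <- pmax(colMeans(dataset_matrix(first_uncontrolled(datasets))$mean),
                 1e-6)
    warm <- if (family == "gma") {
      gma_from_mechanistic_local(mech_fit$model, xbar)
    } else {
      ssystem_from_mechanistic(mech_fit$model, xbar)
    }
    dots$extra_starts <- c(dots$extra_starts,
                           list(surrogate_params(warm)))
  }
  if (family == "linear") {
    # the linear expansion is fitted to the uncontrolled baseline only: its
    # validity region is too narrow to span several initializations
    datasets <- datasets[vapply(datasets, function(d) length(d$control) == 0,
                                logical(1))][1]
  }
  if (family %in% c("linear", "quadratic")) {
    # populations span an order of magnitude; unscaled residuals would let
    # the grass equation dominate the Taylor fits
    dots$scale_residuals <- dots$scale_residuals %||% TRUE
  }
  if (family == "quadratic") {
    # local expansions are fitted to the trajectories that live in their
    # validity region: the datasets sharing the expansion point's
    # initialization
    ref_init <- first_uncontrolled(datasets)$init_id
    same <- vapply(datasets, function(d) identical(d$init_id, ref_init),
                   logical(1))
    if (any(same)) datasets <- datasets[same]
  }
  if (family == "quadratic") {
    # the no-extra-roots constraint is enforced on the control problem's
    # region of interest: populations between 40% and 160% of the baseline
    x0 <- surrogate$x0
    do.call(fit_quadratic_with_root_constraint,
            c(list(model = surrogate, datasets = datasets,
                   lower_domain = 0.4 * x0,
                   upper_domain = pmax(1.6 * x0, 1)),
              dots))
  } else {
    do.call(fit_parameters,
            c(list(model = surrogate, datasets = datasets), dots))
  }
}

#' Reconstruct a fitted surrogate from its JSON serialization
#'
#' @param path path written by [write_fit()].
#' @param model the ABM configuration the fit belongs to.
#' @param datasets training datasets (needed for Taylor expansion points).
#' @export
read_fit <- function(path, model, datasets = NULL) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  family <- switch(obj$family, taylor = if (obj$order == 2) "quadratic"
                   else "linear", obj$family)
  surrogate <- reference_surrogate(model, family, datasets)
  if (!is.null(obj$x0)) surrogate$x0 <- as.numeric(obj$x0)
  set_params(surrogate, as.numeric(unlist(obj$params)))
}

#' Reference control targets of the sheep-wolves transfer problem
#'
#' @param x0 baseline steady state.
#' @export
sw_reference_problem <- function(x0) {
  # removal rates are capped at the training control levels (2% sheep,
  # 1.5% wolves) so the solved optimum stays an interpolation
  transfer_problem(c(sheep = 1.1, wolves = 0.5), x0, horizon = 2000,
                   tol = 0.02,
                   kappa_upper = c(sheep = 0.02, wolves = 0.015))
}

#' Objective of the transfer problem evaluated on an ABM run
#'
#' Returns a closure for [grid_search_abm()]: the achieved steady state is
#' the tail mean (final quarter) of sheep and wolves, and the objective is
#' the root-mean-square relative distance to the target.
#'
#' @param target named target vector (`sheep`, `wolves`).
#' @export
sw_transfer_objective <- function(target) {
  function(traj, point) {
    m <- trajectory_matrix(traj)
    tail_idx <- m$times >= max(m$times) * 0.75
    ach <- colMeans(m$values[tail_idx, c("sheep", "wolves"), drop = FALSE])
    list(value = sqrt(mean(((ach - target) / pmax(target, 1))^2)),
         outcome = c(sheep = unname(ach["sheep"]),
                     wolves = unname(ach["wolves"])))
  }
}

#' Objective of the inflow problem evaluated on an ABM run
#'
#' Under the `"strict"` policy a run whose product pool hits zero yields an
#' infinite loss, which removes that inflow from contention in the grid
#' search (the skip policy would instead reward starving the reactor).
#'
#' @param policy zero-denominator policy for [loss_qin()].
#' @export
met_loss_objective <- function(policy = "strict") {
  function(traj, point) {
    tryCatch(as.numeric(loss_qin(traj, policy = policy)),
             abmctrl_loss_undefined = function(e) Inf)
  }
}

#' Run the reference grid-search validation on an ABM
#'
#' Sheep-wolves: a removal-rate lattice is searched for the point whose
#' controlled steady state best matches the transfer target (control applied
#' from mid-run). Metabolic: inflows 0..1 are scored by the strict-policy
#' loss.
#'
#' @param model an `sw_model` or `met_model`.
#' @param seed root seed.
#' @param steps ABM steps per run.
#' @param replicates replicates per grid point.
#' @param grid optional custom grid tibble.
#' @param baseline optional precomputed baseline dataset (sheep-wolves).
#' @export
validate_reference_problem <- function(model, seed = 1, steps = NULL,
                                       replicates = 5, grid = NULL,
                                       baseline = NULL) {
  if (inherits(model, "sw_model")) {
    steps <- steps %||% 2000L
    if (is.null(baseline)) {
      baseline <- generate_datasets(model, labels = "I", seed = seed,
                                    steps = steps,
                                    replicates = replicates)$I
    }
    x0 <- estimate_steady_state(baseline)
    target <- c(sheep = unname(1.1 * x0["sheep"]),
                wolves = unname(0.5 * x0["wolves"]))
    grid <- grid %||% tidyr::expand_grid(
      kappa_sheep = seq(0, 0.03, by = 0.005),
      kappa_wolves = seq(0, 0.03, by = 0.005))
    out <- grid_search_abm(
      model, grid, sw_transfer_objective(target),
      function(point) control_schedule(
        removal = c(sheep = point$kappa_sheep, wolves = point$kappa_wolves),
        start = steps %/% 2),
      replicates = replicates, steps = steps, seed = seed)
    out$target <- target
    out$baseline <- x0
    # intrinsic noise: the populations' stochastic fluctuation about the
    # uncontrolled steady state, pooled over the baseline tail window
    # (between-replicate variance at each time plus the residual drift of
    # the ensemble mean)
    m <- dataset_matrix(baseline)
    tail_idx <- m$times >= max(m$times) * 0.75
    pooled <- function(v) {
      sqrt(mean(m$sd[tail_idx, v]^2) + stats::var(m$mean[tail_idx, v]))
    }
    out$noise <- c(sheep = pooled("sheep"), wolves = pooled("wolves"))
    out
  } else {
    steps <- steps %||% 10000L
    grid <- grid %||% tibble::tibble(Q = seq(0, 1, by = 0.1))
    model_c <- with_inflow(model, 0) # continuous-mode reference initialization
    out <- grid_search_abm(
      model_c, grid, met_loss_objective(),
      function(point) control_schedule(inflow = c(S = point$Q)),
      replicates = replicates, steps = steps, seed = seed, stride = 10L)
    out
  }
}

#' Scaled-down end-to-end reproduction driver
#'
#' Chains dataset generation, surrogate calibration, control solving on the
#' surrogate, transfer back to the ABM, and the grid-search validation at a
#' reduced problem size, and renders a plain-text comparison report.
#'
#' @param experiment `"sheep-wolves-transfer"` or `"metabolic-inflow"`.
#' @param scale factor in (0, 1] multiplying replicate counts and grid
#'   resolution relative to the desk-scale reference settings.
#' @param seed root seed.
#' @return List with `report` (character lines), the fits, the surrogate
#'   solutions and the `grid_search_result`.
#' @export
reproduce_experiment <- function(experiment = c("sheep-wolves-transfer",
                                                "metabolic-inflow"),
                                 scale = 0.1, seed = 1) {
  experiment <- match.arg(experiment)
  stopifnot(scale > 0, scale <= 1)
  report <- c(sprintf("experiment: %s (scale %.2f, seed %d)",
                      experiment, scale, seed))
  if (experiment == "sheep-wolves-transfer") {
    model <- sheep_wolves_params(scale = 5)
    steps <- 2000L
    reps <- max(2L, as.integer(round(20 * scale)))
    dss <- generate_datasets(model, seed = seed, steps = steps,
                             replicates = reps)
    x0 <- estimate_steady_state(dss$I)
    prob <- sw_reference_problem(x0)
    fams <- c("mechanistic", "gma")
    fits <- lapply(fams, function(f) {
      fit_reference_surrogate(model, f, dss, seed = seed)
    })
    names(fits) <- fams
    sols <- lapply(fits, function(f) {
      solve_transfer_on_surrogate(f$model, prob)
    })
    gs <- validate_reference_problem(
      model, seed = seed + 1, steps = steps, replicates = reps,
      grid = tidyr::expand_grid(kappa_sheep = seq(0, 0.02, by = 0.005),
                                kappa_wolves = seq(0, 0.02, by = 0.005)),
      baseline = dss$I)
    report <- c(report,
      sprintf("baseline steady state: %s",
              paste(names(x0), round(x0, 1), sep = "=", collapse = ", ")),
      sprintf("ABM grid-search best: kappa_sheep=%.4f kappa_wolves=%.4f (mean %.3f, sd %.3f)",
              gs$best$kappa_sheep, gs$best$kappa_wolves, gs$best$mean,
              gs$best$sd),
      vapply(fams, function(f) {
        s <- sols[[f]]
        sprintf("%s surrogate: kappa_sheep=%.4f kappa_wolves=%.4f (feasible %s)",
                f, s$kappa["sheep"], s$kappa["wolves"], s$feasible)
      }, character(1)))
    list(report = report, fits = fits, solutions = sols, grid_search = gs)
  } else {
    model <- metabolic_params()
    steps <- as.integer(max(2000, round(10000 * max(scale, 0.2))))
    reps <- max(2L, as.integer(round(10 * scale)))
    dss <- generate_datasets(model, labels = c("I", "II"), seed = seed,
                             steps = steps, stride = 20L)
    fit <- fit_reference_surrogate(model, "mechanistic", dss, seed = seed)
    prob <- inflow_problem(horizon = steps)
    x0_eval <- dataset_matrix(dss$II)$mean[1, ]
    sol <- solve_inflow_on_surrogate(fit$model, prob, x0_eval, step = 0.1)
    gs <- validate_reference_problem(model, seed = seed + 1, steps = steps,
                                     replicates = reps,
                                     grid = tibble::tibble(Q = seq(0, 1,
                                                                   by = 0.2)))
    best_q <- if (nrow(gs$best) > 0) gs$best$Q else NA_real_
    report <- c(report,
      sprintf("surrogate-predicted inflow: Q=%.3f (loss %.4g)%s",
              sol$Q, sol$objective,
              if (sol$no_interior_minimum) " [no interior minimum]" else ""),
      sprintf("ABM grid-search best inflow: Q=%s",
              ifelse(is.na(best_q), "none finite", format(best_q))),
      "per-point mean/sd of the strict-policy loss:",
      utils::capture.output(print(as.data.frame(
        gs$result[, c("Q", "mean", "sd")]), digits = 4)))
    list(report = report, fits = list(mechanistic = fit),
         solutions = list(mechanistic = sol), grid_search = gs)
  }
}

#' Solve the reference control problem for a serialized fit
#'
#' Rebuilds the fitted surrogate (see [read_fit()]) and solves the ABM's
#' reference control problem on it: the steady-state transfer for the
#' sheep-wolves model, the inflow optimization for the metabolic model.
#'
#' @param model an `sw_model` or `met_model`.
#' @param fit_json parsed fit JSON (list) or a `surrogate_fit`.
#' @param seed seed for the baseline dataset used to locate the steady state.
#' @param steps evaluation horizon.
#' @param replicates replicates of the baseline ensemble.
#' @export
solve_reference_problem <- function(model, fit_json, seed = 1, steps = NULL,
                                    replicates = 5) {
  if (inherits(model, "sw_model")) {
    steps <- steps %||% 2000L
    dss <- generate_datasets(model, labels = "I", seed = seed, steps = steps,
                             replicates = replicates)
    surrogate <- rebuild_surrogate(model, fit_json, dss)
    x0 <- estimate_steady_state(dss$I)
    solve_transfer_on_surrogate(surrogate, sw_reference_problem(x0))
  } else {
    steps <- steps %||% 10000L
    surrogate <- rebuild_surrogate(model, fit_json, NULL)
    cont <- metabolic_params(mode = "continuous")
    sm <- metabolic_state_map()
    x0 <- aggregate_counts(cont$initial_counts, sm)
    solve_inflow_on_surrogate(surrogate, inflow_problem(horizon = steps), x0)
  }
}

rebuild_surrogate <- function(model, fit_json, datasets) {
  if (inherits(fit_json, "surrogate_fit")) return(fit_json$model)
  family <- switch(fit_json$family,
                   taylor = if (identical(fit_json$order, 2)) "quadratic"
                            else "linear",
                   fit_json$family)
  surrogate <- reference_surrogate(model, family, datasets)
  if (!is.null(fit_json$x0)) surrogate$x0 <- as.numeric(fit_json$x0)
  set_params(surrogate, as.numeric(unlist(fit_json$params)))
}
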