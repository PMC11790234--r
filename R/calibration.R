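#' Average a replicate ensemble into a training dataset
#'
#' Stochastic ABM trajectories are averaged over replicates before surrogate
#' calibration: the dataset carries the pointwise mean and sample standard
#' deviation per variable per time, the control level the ensemble was run
#' under (as surrogate control-parameter values), and the replicate count.
#'
#' @param traj a tidy trajectory tibble (one or more replicates sharing
#'   times and variable labels).
#' @param label dataset label (e.g. `"I"`).
#' @param control named numeric vector of surrogate control values the runs
#'   used (e.g. `c(sheep = 0.02)` or `c(Q = 1)`); empty for no control.
#' @param init_id identifier of the initialization the ensemble started from.
#' @return An `abm_dataset` object with a tidy `summary` tibble
#'   (`time`, `variable`, `mean`, `sd`).
#' @export
average_ensemble <- function(traj, label = "I", control = numeric(),
                             init_id = NA_character_) {
  labels <- traj_labels(traj)
  per_rep <- dplyr::count(traj, .data$replicate)
  if (dplyr::n_distinct(per_rep$n) != 1) {
    abort("replicates do not share a common time grid / variable set")
  }
  summary <- traj |>
    dplyr::group_by(.data$time, .data$variable) |>
    dplyr::summarise(mean = mean(.data$value),
                     sd = if (dplyr::n() > 1) sd(.data$value) else 0,
                     .groups = "drop") |>
    dplyr::mutate(variable = factor(.data$variable, levels = labels)) |>
    dplyr::arrange(.data$time, .data$variable) |>
    dplyr::mutate(variable = as.character(.data$variable))
  structure(list(label = label, summary = summary, labels = labels,
                 control = control, init_id = init_id,
                 replicates = dplyr::n_distinct(traj$replicate)),
            class = "abm_dataset")
}

#' @export
print.abm_dataset <- function(x, ...) {
  cat(sprintf("<dataset %s> %d replicate(s), %d time points, states: %s\n",
              x$label, x$replicates, dplyr::n_distinct(x$summary$time),
              paste(x$labels, collapse = ", ")))
  if (length(x$control) > 0) {
    cat("  control:", paste(names(x$control), signif(x$control, 3),
                            sep = " = ", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Matrix view of a dataset
#'
#' @param ds an `abm_dataset`.
#' @return List with `times`, `mean` and `sd` (time-by-variable matrices).
#' @export
dataset_matrix <- function(ds) {
  stopifnot(inherits(ds, "abm_dataset"))
  wide_m <- tidyr::pivot_wider(ds$summary, id_cols = "time",
                               names_from = "variable", values_from = "mean")
  wide_s <- tidyr::pivot_wider(ds$summary, id_cols = "time",
                               names_from = "variable", values_from = "sd")
  list(times = wide_m$time,
       mean = as.matrix(wide_m[, ds$labels, drop = FALSE]),
       sd = as.matrix(wide_s[, ds$labels, drop = FALSE]))
}

#' Estimate the ABM steady state from a trajectory tail
#'
#' Averages the trailing window of the ensemble mean, variable by variable:
#' once trajectories have converged to their noisy plateau, the window mean
#' estimates the steady state the Taylor surrogates expand around.
#'
#' @param ds an `abm_dataset`.
#' @param tail_fraction fraction of the trajectory (from the end) to
#'   average; the window must contain at least 2 time points.
#' @return Named steady-state vector.
#' @export
estimate_steady_state <- function(ds, tail_fraction = 0.25) {
  stopifnot(tail_fraction > 0, tail_fraction <= 1)
  m <- dataset_matrix(ds)
  nt <- length(m$times)
  w <- floor(nt * tail_fraction)
  if (w < 2) abort("steady-state window has fewer than 2 time points")
  idx <- (nt - w + 1):nt
  setNames(colMeans(m$mean[idx, , drop = FALSE]), ds$labels)
}

finite_diff_slopes <- function(times, values) {
  nt <- length(times)
  if (nt < 3) abort("slope estimation needs at least 3 time points")
  idx <- 2:(nt - 1)
  dt <- times[idx + 1] - times[idx - 1]
  slopes <- (values[idx + 1, , drop = FALSE] - values[idx - 1, , drop = FALSE]) / dt
  list(x = values[idx, , drop = FALSE], slopes = slopes)
}

#' Slope-based initial parameter guess
#'
#' The time-course slope method: central-difference derivatives of the
#' dataset mean are regressed, one scalar rate at a time, onto the model's
#' process terms evaluated at the observed states (kinetic orders and
#' saturation constants held at the model's current values). Rates that must
#' be positive are floored at a small epsilon. This gives a feasible,
#' order-of-magnitude-correct start for the least-squares fit.
#'
#' @param ds an `abm_dataset` (at least 3 time points).
#' @param model the surrogate to initialize.
#' @param eps positivity floor for rate constants.
#' @return A packed parameter vector (see [surrogate_params()]).
#' @export
initial_guess_slopes <- function(ds, model, eps = 1e-6) {
  m <- dataset_matrix(ds)
  fd <- finite_diff_slopes(m$times, m$mean)
  X <- fd$x
  n <- model$n
  y <- as.numeric(fd$slopes) # stacked column-major: all times of var 1, ...

  if (inherits(model, "taylor_surrogate")) {
    d <- sweep(X, 2, model$x0)
    J <- matrix(0, n, n)
    for (i in seq_len(n)) {
      J[i, ] <- coef(lm(fd$slopes[, i] ~ 0 + d))
    }
    J[!is.finite(J)] <- 0
    out <- surrogate_params(model)
    out[seq_len(n^2)] <- as.numeric(t(J))
    out[-seq_len(n^2)] <- 0
    return(out)
  }

  if (inherits(model, "ssystem_surrogate")) {
    # regress each equation's slopes on (influx at unit rate, -efflux at unit
    # rate) with the current kinetic orders
    for (i in seq_len(n)) {
      gin <- apply(sweep_pow_rows(X, model$g[i, ]), 1, prod)
      gout <- apply(sweep_pow_rows(X, model$h[i, ]), 1, prod)
      cf <- tryCatch(coef(lm(fd$slopes[, i] ~ 0 + cbind(gin, -gout))),
                     error = function(e) c(NA, NA))
      model$alpha[i] <- max(cf[1], eps, na.rm = TRUE)
      model$beta[i] <- max(cf[2], eps, na.rm = TRUE)
    }
    return(surrogate_params(model))
  }

  # GMA / mechanistic: one design column per scalar rate parameter
  cols <- list()
  if (inherits(model, "gma_surrogate")) {
    for (j in seq_len(model$m)) {
      fj <- apply(sweep_pow_rows(X, model$orders[j, ]), 1, prod)
      cols[[j]] <- as.numeric(outer(fj, model$stoich[, j]))
    }
  } else {
    for (j in seq_along(model$processes)) {
      term <- model$processes[[j]]
      unit <- switch(term$kind,
        power_law = list(apply(sweep_pow_rows(X, term$g), 1, prod)),
        michaelis_menten = {
          r <- X[, term$substrate] / (term$km + X[, term$substrate])
          if (!is.null(term$inhibitor) && !is.na(term$inhibitor)) {
            r <- r * term$ki / (term$ki + X[, term$inhibitor])
          }
          list(r)
        },
        logistic_growth = list(X[, term$var], -X[, term$var]^2))
      for (u in unit) {
        cols[[length(cols) + 1]] <- as.numeric(outer(u, model$stoich[, j]))
      }
    }
  }
  D <- do.call(cbind, cols)
  cf <- tryCatch(coef(lm(y ~ 0 + D)), error = function(e) rep(NA, ncol(D)))
  cf[!is.finite(cf)] <- eps
  rates <- pmax(cf, eps)

  p <- surrogate_params(model)
  if (inherits(model, "gma_surrogate")) {
    mat <- matrix(p, nrow = model$m, byrow = TRUE)
    mat[, 1] <- rates
    return(setNames(as.numeric(t(mat)), names(p)))
  }
  # mechanistic: rates map onto the linear parameters in pack order
  pos <- 0; ci <- 0
  for (j in seq_along(model$processes)) {
    term <- model$processes[[j]]
    k <- switch(term$kind,
      power_law = { p[pos + 1] <- rates[ci + 1]; ci <- ci + 1; 1 },
      michaelis_menten = {
        p[pos + 1] <- rates[ci + 1]; ci <- ci + 1
        npar <- if (!is.null(term$inhibitor) && !is.na(term$inhibitor)) 3 else 2
        npar
      },
      logistic_growth = {
        p[pos + 1:2] <- rates[ci + 1:2]; ci <- ci + 2; 2
      })
    pos <- pos + k
  }
  p
}

sweep_pow_rows <- function(X, g) {
  # X: time-by-variable matrix, g: kinetic orders; rows x^g (0^0 = 1)
  out <- X
  for (k in seq_along(g)) out[, k] <- X[, k]^g[k]
  out
}

default_bounds <- function(model) {
  p <- surrogate_params(model)
  lower <- rep(-Inf, length(p))
  upper <- rep(Inf, length(p))
  if (inherits(model, c("gma_surrogate", "ssystem_surrogate"))) {
    rate_idx <- grep("^(alpha|beta)", names(p))
    lower[rate_idx] <- 1e-9
    upper[rate_idx] <- 1e9
    ord <- order_indices(model)
    lower[ord] <- -4
    upper[ord] <- 4
  } else if (inherits(model, "mechanistic_surrogate")) {
    lower[] <- 1e-9
    upper[] <- 1e6
  }
  list(lower = lower, upper = upper)
}

#' Fit surrogate parameters to ABM training datasets
#'
#' Simultaneous multi-dataset least squares: the surrogate is integrated
#' from each dataset's initial mean state under that dataset's control
#' level, residuals against the dataset means are concatenated over all
#' datasets, and the packed parameter vector is optimized by bounded
#' Levenberg-Marquardt from multiple starts (the slope-based guess plus
#' Latin-hypercube perturbations). An optional L1 penalty
#' `lambda * sum(|kinetic orders|)` sparsifies power-law families, which
#' performs variable selection; rate constants are never penalized.
#'
#' @param model an `ode_surrogate` (with a control term attached if any
#'   dataset was generated under control).
#' @param datasets list of [average_ensemble()] datasets.
#' @param lambda L1 weight on kinetic orders (>= 0).
#' @param starts number of multi-starts (>= 1).
#' @param seed RNG seed for the start design (fit is deterministic given it).
#' @param thin keep every `thin`-th time point of each dataset for the
#'   residuals (1 = all).
#' @param scale_residuals if `TRUE`, residuals of each variable are divided
#'   by that variable's maximum mean (for badly scaled systems); the
#'   reference objective is unweighted raw counts.
#' @param lower,upper parameter bounds; defaults depend on the family (rate
#'   constants in (1e-9, 1e9], kinetic orders in \[-4, 4\], Taylor entries
#'   unbounded).
#' @param maxiter Levenberg-Marquardt iteration cap per start.
#' @param zero_tol absolute threshold below which a kinetic order is
#'   reported as zero in the fit's sparsity mask.
#' @param solver integration settings used inside the objective
#'   (`maxsteps`, `rtol`, `atol`); the defaults fail fast on pathological
#'   parameter proposals.
#' @param extra_starts list of additional packed start vectors (e.g. warm
#'   starts derived from another family), tried alongside the generated
#'   design.
#' @return A `surrogate_fit` object: the calibrated model plus residual
#'   bookkeeping (`residual` is the unpenalized sum of squares).
#' @export
fit_parameters <- function(model, datasets, lambda = 0, starts = 8, seed = 1,
                           thin = 1, scale_residuals = FALSE,
                           lower = NULL, upper = NULL, maxiter = 100,
                           zero_tol = 1e-4, extra_starts = list(),
                           solver = list(maxsteps = 100, rtol = 1e-5,
                                         atol = 1e-5)) {
  stopifnot(length(datasets) >= 1, lambda >= 0, starts >= 0)
  datasets <- prepare_datasets(model, datasets, thin)
  bounds <- default_bounds(model)
  lower <- lower %||% bounds$lower
  upper <- upper %||% bounds$upper

  ord_idx <- if (inherits(model, c("gma_surrogate", "ssystem_surrogate"))) {
    order_indices(model)
  } else {
    integer()
  }
  scales <- if (scale_residuals) {
    lapply(datasets, function(d) pmax(apply(d$mean, 2, max), 1e-9))
  } else {
    lapply(datasets, function(d) rep(1, ncol(d$mean)))
  }
  n_res <- sum(vapply(datasets, function(d) length(d$mean), integer(1)))

  residual_fn <- function(p) {
    m <- set_params(model, p)
    res <- tryCatch({
      unlist(lapply(seq_along(datasets), function(i) {
        d <- datasets[[i]]
        sim <- .integrate_matrix(m, d$x0, d$times, u = d$control,
                                 methods = "lsoda",
                                 maxsteps = solver$maxsteps,
                                 rtol = solver$rtol, atol = solver$atol)$values
        as.numeric(sweep(sim - d$mean, 2, scales[[i]], "/"))
      }))
    }, error = function(e) rep(1e4, n_res))
    if (length(res) != n_res || any(!is.finite(res))) res <- rep(1e4, n_res)
    if (lambda > 0 && length(ord_idx) > 0) {
      res <- c(res, sqrt(lambda * abs(p[ord_idx])))
    }
    res
  }

  start_list <- if (starts >= 1) {
    make_starts(model, datasets, starts, seed, lower, upper)
  } else {
    list()
  }
  start_list <- c(start_list, lapply(extra_starts, function(p) {
    pmin(pmax(as.numeric(p), lower + 1e-12), upper - 1e-12)
  }))
  if (length(start_list) == 0) abort("no starting points to fit from")
  best <- NULL
  for (p0 in start_list) {
    fit <- tryCatch(
      suppressWarnings(
        minpack.lm::nls.lm(par = p0, fn = residual_fn,
                           lower = lower, upper = upper,
                           control = minpack.lm::nls.lm.control(
                             maxiter = maxiter, maxfev = 100 * maxiter,
                             ptol = 1e-9, ftol = 1e-9))),
      error = function(e) NULL)
    if (is.null(fit)) next
    obj <- fit$deviance
    if (is.null(best) || obj < best$obj) {
      best <- list(fit = fit, obj = obj, start = p0)
    }
  }
  if (is.null(best)) {
    abort("no multi-start produced an integrable fit",
          class = "abmctrl_fit_error")
  }
  p_hat <- coef(best$fit)
  fitted_model <- set_params(model, p_hat)
  unpen <- sum(residual_fn_unpenalized(fitted_model, datasets, scales,
                                       solver)^2)
  zero_mask <- setNames(rep(FALSE, length(p_hat)),
                        names(surrogate_params(model)))
  if (length(ord_idx) > 0) zero_mask[ord_idx] <- abs(p_hat[ord_idx]) < zero_tol
  structure(list(
    model = fitted_model,
    params = setNames(p_hat, names(surrogate_params(model))),
    residual = unpen,
    penalized = best$obj,
    converged = best$fit$info %in% 1:4,
    lambda = lambda,
    zero_mask = zero_mask,
    datasets = vapply(datasets, `[[`, character(1), "label"),
    seed = seed,
    starts = length(start_list)
  ), class = "surrogate_fit")
}

residual_fn_unpenalized <- function(model, datasets, scales,
                                    solver = list(maxsteps = 100,
                                                  rtol = 1e-5, atol = 1e-5)) {
  tryCatch({
    unlist(lapply(seq_along(datasets), function(i) {
      d <- datasets[[i]]
      sim <- .integrate_matrix(model, d$x0, d$times, u = d$control,
                               methods = "lsoda",
                               maxsteps = solver$maxsteps,
                               rtol = solver$rtol, atol = solver$atol)$values
      as.numeric(sweep(sim - d$mean, 2, scales[[i]], "/"))
    }))
  }, error = function(e) Inf)
}

prepare_datasets <- function(model, datasets, thin) {
  lapply(datasets, function(ds) {
    stopifnot(inherits(ds, "abm_dataset"))
    if (!identical(ds$labels, model$labels)) {
      abort(sprintf("dataset '%s' has variables [%s] but the model expects [%s]",
                    ds$label, paste(ds$labels, collapse = ", "),
                    paste(model$labels, collapse = ", ")))
    }
    if (length(ds$control) > 0 && is.null(model$control)) {
      abort(sprintf("dataset '%s' was generated under control but the model has no control term",
                    ds$label))
    }
    m <- dataset_matrix(ds)
    keep <- unique(c(seq(1, length(m$times), by = thin), length(m$times)))
    list(label = ds$label, times = m$times[keep],
         mean = m$mean[keep, , drop = FALSE],
         x0 = m$mean[keep[1], ],
         control = if (length(ds$control) > 0) ds$control else NULL)
  })
}

make_starts <- function(model, datasets, starts, seed, lower, upper) {
  set.seed(seed)
  clamp <- function(p) pmin(pmax(unname(p), lower + 1e-12), upper - 1e-12)
  p0 <- tryCatch(initial_guess_slopes_prepared(model, datasets),
                 error = function(e) surrogate_params(model))
  p0 <- clamp(p0)
  # the model's own current parameters are always a candidate start (the
  # caller's initial guess, and the self-consistency anchor)
  out <- list(clamp(surrogate_params(model)), p0)
  if (starts > 1) {
    k <- length(p0)
    lat <- lhs::randomLHS(starts - 1, k)
    for (i in seq_len(starts - 1)) {
      pi <- p0
      jitter <- lat[i, ]
      finite_box <- is.finite(lower) & is.finite(upper)
      pos_box <- finite_box & lower > 0
      ord_box <- finite_box & !pos_box
      # positive rates: log-uniform between 1e-2x and 1e2x the slope guess
      pi[pos_box] <- pmin(pmax(
        p0[pos_box] * 10^(4 * jitter[pos_box] - 2),
        lower[pos_box]), upper[pos_box])
      # kinetic orders: additive jitter of +-0.75 around the guess
      pi[ord_box] <- pmin(pmax(
        p0[ord_box] + 1.5 * (jitter[ord_box] - 0.5),
        lower[ord_box]), upper[ord_box])
      # unbounded (Taylor) entries: multiplicative jitter around the guess
      pi[!finite_box] <- p0[!finite_box] * (0.25 + 1.5 * jitter[!finite_box])
      out[[length(out) + 1]] <- pi
    }
  }
  out
}

initial_guess_slopes_prepared <- function(model, datasets) {
  # slope guess from the first uncontrolled dataset (or the first overall)
  d <- datasets[[which.max(vapply(datasets, function(x) is.null(x$control),
                                  logical(1)))]]
  ds <- structure(list(
    label = d$label,
    summary = tibble::tibble(
      time = rep(d$times, each = ncol(d$mean)),
      variable = rep(colnames(d$mean), length(d$times)),
      mean = as.numeric(t(d$mean)), sd = 0),
    labels = colnames(d$mean), control = numeric(), init_id = NA,
    replicates = 1L), class = "abm_dataset")
  initial_guess_slopes(ds, model)
}

#' Fit a quadratic Taylor surrogate with a no-extra-roots constraint
#'
#' Quadratic expansions can acquire spurious steady states that derail
#' control optimization. This fit runs the usual multi-start least squares
#' but rejects any candidate whose right-hand side has a root other than the
#' expansion point `x0` inside the stated domain box (checked with
#' [find_roots()]); the best admissible candidate is returned.
#'
#' @inheritParams fit_parameters
#' @param lower_domain,upper_domain the control problem's region of
#'   interest; `x0` must lie inside it.
#' @param root_tol a root differing from `x0` by more than this (absolute,
#'   any coordinate) counts as an extra steady state.
#' @param root_starts lattice resolution per dimension for the root search.
#' @return A `surrogate_fit` whose model has no extra in-domain roots.
#' @export
fit_quadratic_with_root_constraint <- function(model, datasets,
                                               lower_domain, upper_domain,
                                               root_tol = NULL,
                                               root_starts = 4, ...) {
  stopifnot(inherits(model, "taylor_surrogate"), model$order == 2)
  if (any(model$x0 < lower_domain) || any(model$x0 > upper_domain)) {
    abort("the expansion point x0 must lie inside the domain box")
  }
  root_tol <- root_tol %||% (0.05 * max(upper_domain - lower_domain))
  dots <- list(...)
  starts <- dots$starts %||% 8
  seed <- dots$seed %||% 1
  dots$starts <- NULL; dots$seed <- NULL

  candidates <- list()
  for (s in seq_len(starts)) {
    fit <- tryCatch(
      do.call(fit_parameters,
              c(list(model = model, datasets = datasets, starts = 1,
                     seed = seed + s - 1), dots)),
      error = function(e) NULL)
    if (!is.null(fit)) candidates[[length(candidates) + 1]] <- fit
  }
  if (length(candidates) == 0) {
    abort("no multi-start produced an integrable fit",
          class = "abmctrl_fit_error")
  }
  ord <- order(vapply(candidates, `[[`, numeric(1), "penalized"))
  for (i in ord) {
    fit <- candidates[[i]]
    roots <- find_roots(fit$model, lower_domain, upper_domain,
                        starts = root_starts)
    extra <- purrr::keep(roots, function(r) {
      any(abs(r - model$x0) > root_tol)
    })
    if (length(extra) == 0) {
      fit$admissible <- TRUE
      return(fit)
    }
  }
  abort("every candidate fit has an extra steady state inside the domain",
        class = "abmctrl_constrained_fit_error")
}
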