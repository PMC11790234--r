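#' Evaluate a power-law process rate
#'
#' The canonical process form of biochemical systems theory:
#' `alpha * prod(x^g)`, with rate constant `alpha > 0` and real-valued
#' kinetic orders `g` (positive = activation, negative = inhibition, zero =
#' no effect). `0^0` is defined as 1; a zero state raised to a negative
#' kinetic order is a domain error (the rate would be infinite), not a value
#' to clamp.
#'
#' @param alpha positive rate constant.
#' @param g numeric vector of kinetic orders.
#' @param x state vector, same length as `g`, non-negative.
#' @return The non-negative, finite rate.
#' @export
eval_power_law <- function(alpha, g, x) {
  stopifnot(length(g) == length(x), alpha > 0)
  if (any(x == 0 & g < 0)) {
    abort("power law undefined: zero state with negative kinetic order",
          class = "abmctrl_domain_error")
  }
  alpha * prod(x^g)
}

new_surrogate <- function(family, labels, ..., class) {
  structure(c(list(family = family, labels = labels, n = length(labels)),
              list(...)),
            class = c(class, "ode_surrogate"))
}

#' Generalized mass action (GMA) surrogate model
#'
#' An ODE system `dX/dt = M F(X)` whose `m` process rates are power laws
#' `F_j = alpha_j * prod_k X_k^{g_jk}` in all `n` state variables, with the
#' signed stoichiometric matrix `M` declaring which processes raise or lower
#' each state. Free parameters: one rate constant plus `n` kinetic orders per
#' process, `m * (1 + n)` in total.
#'
#' @param labels character vector of state-variable names (length `n`).
#' @param stoich `n x m` stoichiometric matrix with entries in `{-1, 0, 1}`.
#' @param alpha positive rate constants (length `m`).
#' @param orders `m x n` matrix of kinetic orders.
#' @return A `gma_surrogate` object.
#' @export
gma_model <- function(labels, stoich,
                      alpha = rep(1, ncol(stoich)),
                      orders = matrix(0, ncol(stoich), length(labels))) {
  stoich <- as.matrix(stoich)
  orders <- as.matrix(orders)
  stopifnot(nrow(stoich) == length(labels),
            nrow(orders) == ncol(stoich), ncol(orders) == length(labels),
            length(alpha) == ncol(stoich))
  if (!all(stoich %in% c(-1, 0, 1))) {
    abort("stoichiometric entries must be -1, 0 or 1")
  }
  if (any(alpha <= 0)) abort("rate constants must be > 0")
  new_surrogate("gma", labels, stoich = stoich, alpha = alpha,
                orders = orders, m = ncol(stoich), class = "gma_surrogate")
}

#' S-system surrogate model
#'
#' The canonical form in which every state equation is the difference of an
#' aggregate influx and an aggregate efflux power law:
#' `dX_i/dt = alpha_i prod_j X_j^{g_ij} - beta_i prod_j X_j^{h_ij}`.
#' Free parameters: `2 (n + n^2)`.
#'
#' @param labels state-variable names.
#' @param alpha,beta positive rate constants (length `n`).
#' @param g,h `n x n` kinetic-order matrices (influx, efflux).
#' @export
ssystem_model <- function(labels,
                          alpha = rep(1, length(labels)),
                          beta = rep(1, length(labels)),
                          g = matrix(0, length(labels), length(labels)),
                          h = matrix(0, length(labels), length(labels))) {
  n <- length(labels)
  g <- as.matrix(g); h <- as.matrix(h)
  stopifnot(length(alpha) == n, length(beta) == n,
            all(dim(g) == n), all(dim(h) == n))
  if (any(alpha <= 0) || any(beta <= 0)) abort("rate constants must be > 0")
  new_surrogate("ssystem", labels, alpha = alpha, beta = beta, g = g, h = h,
                class = "ssystem_surrogate")
}

#' Taylor-expansion surrogate at a steady state
#'
#' A local approximation around the ABM's (estimated) steady state `x0`:
#' order 1 is `dX/dt = J (X - x0)` with the Jacobian entries treated as free
#' parameters; order 2 adds, per coordinate `i`, the quadratic form
#' `0.5 (X - x0)' H_i (X - x0)` with symmetric Hessians. Free parameters:
#' `n^2` (order 1) or `(3 n^2 + n^3) / 2` (order 2).
#'
#' @param labels state-variable names.
#' @param x0 steady-state expansion point (length `n`).
#' @param order 1 (linear) or 2 (quadratic).
#' @param J `n x n` Jacobian matrix.
#' @param H list of `n` symmetric `n x n` Hessian matrices (order 2 only).
#' @export
taylor_model <- function(labels, x0, order = 1,
                         J = matrix(0, length(labels), length(labels)),
                         H = NULL) {
  n <- length(labels)
  stopifnot(length(x0) == n, order %in% c(1, 2), all(dim(as.matrix(J)) == n))
  if (order == 2) {
    if (is.null(H)) H <- replicate(n, matrix(0, n, n), simplify = FALSE)
    stopifnot(length(H) == n)
    for (Hi in H) {
      if (!isTRUE(all.equal(Hi, t(Hi), tolerance = 1e-8))) {
        abort("Hessian matrices must be symmetric")
      }
    }
  } else {
    H <- NULL
  }
  new_surrogate("taylor", labels, x0 = as.numeric(x0), order = order,
                J = as.matrix(J), H = H, class = "taylor_surrogate")
}

#' Process term of a mechanistic surrogate
#'
#' @param type `"power_law"` (`alpha * prod(x^g)`, mass action being the
#'   integer-order special case), `"michaelis_menten"`
#'   (`vmax * S / (km + S)`, optionally multiplied by a competitive
#'   inhibition factor `ki / (ki + I)`), or `"logistic_growth"`
#'   (`k1 * X - k2 * X^2`, a net growth term).
#' @param ... kind-specific parameters: `alpha`, `g` (power_law); `vmax`,
#'   `km`, `substrate`, and optionally `inhibitor`, `ki` (michaelis_menten);
#'   `k1`, `k2`, `var` (logistic_growth). Indices refer to state positions.
#' @export
process_term <- function(type = c("power_law", "michaelis_menten",
                                  "logistic_growth"), ...) {
  kind <- match.arg(type)
  args <- list(...)
  need <- switch(kind,
    power_law = c("alpha", "g"),
    michaelis_menten = c("vmax", "km", "substrate"),
    logistic_growth = c("k1", "k2", "var"))
  missing <- setdiff(need, names(args))
  if (length(missing) > 0) {
    abort(paste0(kind, " term needs parameter(s): ",
                 paste(missing, collapse = ", ")))
  }
  structure(c(list(kind = kind), args), class = "process_term")
}

#' Mechanistic surrogate model
#'
#' An ODE system `dX/dt = M F(X)` whose process rates carry declared
#' functional forms (mass-action power laws, Michaelis-Menten rates with
#' optional competitive inhibition, logistic growth) rather than generic
#' power laws.
#'
#' @param labels state-variable names.
#' @param stoich `n x m` stoichiometric matrix in `{-1, 0, 1}`.
#' @param processes list of `m` [process_term()] objects.
#' @export
mechanistic_model <- function(labels, stoich, processes) {
  stoich <- as.matrix(stoich)
  stopifnot(nrow(stoich) == length(labels), ncol(stoich) == length(processes))
  if (!all(stoich %in% c(-1, 0, 1))) {
    abort("stoichiometric entries must be -1, 0 or 1")
  }
  stopifnot(all(vapply(processes, inherits, logical(1), "process_term")))
  new_surrogate("mechanistic", labels, stoich = stoich, processes = processes,
                m = ncol(stoich), class = "mechanistic_surrogate")
}

process_rate <- function(term, x) {
  switch(term$kind,
    power_law = eval_power_law(term$alpha, term$g, x),
    michaelis_menten = {
      s <- x[term$substrate]
      r <- term$vmax * s / (term$km + s)
      if (!is.null(term$inhibitor) && !is.na(term$inhibitor)) {
        r <- r * term$ki / (term$ki + x[term$inhibitor])
      }
      r
    },
    logistic_growth = term$k1 * x[term$var] - term$k2 * x[term$var]^2)
}

#' Right-hand side of a surrogate model
#'
#' Evaluates the derivative vector of any surrogate family at state `x`,
#' including an attached control term (see [add_control()]) when control
#' parameter values `u` are supplied.
#'
#' @param model an `ode_surrogate`.
#' @param x state vector in the model's admissible domain.
#' @param u named control parameter values (e.g. `c(sheep = 0.01)` removal
#'   rates, or `c(Q = 0.5)` inflow); defaults to no control.
#' @return Numeric derivative vector of length `n`.
#' @export
rhs <- function(model, x, u = NULL) {
  UseMethod("rhs")
}

apply_control_rhs <- function(model, x, dx, u) {
  ctrl <- model$control
  if (is.null(ctrl) || is.null(u)) return(dx)
  if (ctrl$type == "removal") {
    for (v in names(ctrl$kappa)) {
      k <- if (v %in% names(u)) u[[v]] else ctrl$kappa[[v]]
      if (k < 0) abort("removal rates must be >= 0")
      i <- match(v, model$labels)
      dx[i] <- dx[i] - k * x[i]
    }
  } else {
    q <- if ("Q" %in% names(u)) u[["Q"]] else ctrl$Q
    i <- match(ctrl$variable, model$labels)
    dx[i] <- dx[i] + q
    if (!is.null(ctrl$outflow) && ctrl$outflow > 0) {
      mets <- match(ctrl$outflow_vars %||% model$labels, model$labels)
      dx[mets] <- dx[mets] - ctrl$outflow * x[mets]
    }
  }
  dx
}

#' @export
rhs.gma_surrogate <- function(model, x, u = NULL) {
  f <- vapply(seq_len(model$m), function(j) {
    eval_power_law(model$alpha[j], model$orders[j, ], x)
  }, numeric(1))
  dx <- as.numeric(model$stoich %*% f)
  apply_control_rhs(model, x, dx, u)
}

#' @export
rhs.ssystem_surrogate <- function(model, x, u = NULL) {
  if (any(vapply(seq_len(model$n), function(i) {
    any(x == 0 & (model$g[i, ] < 0 | model$h[i, ] < 0))
  }, logical(1)))) {
    abort("power law undefined: zero state with negative kinetic order",
          class = "abmctrl_domain_error")
  }
  influx <- model$alpha * apply(sweep_pow(x, model$g), 1, prod)
  efflux <- model$beta * apply(sweep_pow(x, model$h), 1, prod)
  apply_control_rhs(model, x, influx - efflux, u)
}

sweep_pow <- function(x, expo) {
  # rows of `expo` are per-equation kinetic orders; returns x^expo rowwise
  matrix(rep(x, each = nrow(expo)), nrow(expo), length(x))^expo
}

#' @export
rhs.taylor_surrogate <- function(model, x, u = NULL) {
  d <- x - model$x0
  dx <- as.numeric(model$J %*% d)
  if (model$order == 2) {
    dx <- dx + 0.5 * vapply(model$H, function(Hi) {
      as.numeric(t(d) %*% Hi %*% d)
    }, numeric(1))
  }
  apply_control_rhs(model, x, dx, u)
}

#' @export
rhs.mechanistic_surrogate <- function(model, x, u = NULL) {
  f <- vapply(model$processes, process_rate, numeric(1), x = x)
  dx <- as.numeric(model$stoich %*% f)
  apply_control_rhs(model, x, dx, u)
}

#' Number of free parameters of a surrogate family
#'
#' Closed-form parameter counts: `n^2` for the linear (first-order Taylor)
#' approximation, `(3 n^2 + n^3) / 2` for the quadratic, `2 (n + n^2)` for
#' the S-system, and `m (1 + n)` for a GMA model with `m` processes.
#'
#' @param family `"linear"`, `"quadratic"`, `"ssystem"` or `"gma"`.
#' @param n number of state variables (>= 1).
#' @param m number of processes (GMA only).
#' @return Integer parameter count.
#' @export
count_parameters <- function(family, n, m = NULL) {
  stopifnot(n >= 1)
  switch(family,
    linear = n^2,
    quadratic = (3 * n^2 + n^3) / 2,
    ssystem = 2 * (n + n^2),
    gma = {
      if (is.null(m) || m < 1) abort("GMA count needs the process count `m`")
      m * (1 + n)
    },
    abort(paste0("unknown surrogate family: ", family)))
}

#' Pack / unpack surrogate parameters
#'
#' Every surrogate family exposes its free parameters as a single numeric
#' vector in a fixed order, so optimizers can treat all families uniformly;
#' `set_params()` is the exact inverse of `surrogate_params()`.
#'
#' @param model an `ode_surrogate`.
#' @return For `surrogate_params()`, a named numeric vector.
#' @export
surrogate_params <- function(model) {
  UseMethod("surrogate_params")
}

#' @export
surrogate_params.gma_surrogate <- function(model) {
  out <- as.numeric(t(cbind(model$alpha, model$orders)))
  names(out) <- as.vector(vapply(seq_len(model$m), function(j) {
    c(paste0("alpha", j), paste0("g", j, seq_len(model$n)))
  }, character(1 + model$n)))
  out
}

#' @export
surrogate_params.ssystem_surrogate <- function(model) {
  n <- model$n
  out <- c(model$alpha, model$beta, as.numeric(t(model$g)), as.numeric(t(model$h)))
  names(out) <- c(paste0("alpha", 1:n), paste0("beta", 1:n),
                  paste0("g", rep(1:n, each = n), rep(1:n, n)),
                  paste0("h", rep(1:n, each = n), rep(1:n, n)))
  out
}

#' @export
surrogate_params.taylor_surrogate <- function(model) {
  n <- model$n
  out <- as.numeric(t(model$J))
  names(out) <- paste0("J", rep(1:n, each = n), rep(1:n, n))
  if (model$order == 2) {
    idx <- which(lower.tri(diag(n), diag = TRUE), arr.ind = TRUE)
    hv <- unlist(lapply(seq_len(n), function(i) model$H[[i]][idx]))
    names(hv) <- unlist(lapply(seq_len(n), function(i) {
      paste0("H", i, "_", idx[, 1], idx[, 2])
    }))
    out <- c(out, hv)
  }
  out
}

#' @export
surrogate_params.mechanistic_surrogate <- function(model) {
  unlist(lapply(seq_along(model$processes), function(j) {
    term <- model$processes[[j]]
    p <- switch(term$kind,
      power_law = c(alpha = term$alpha),
      michaelis_menten = {
        v <- c(vmax = term$vmax, km = term$km)
        if (!is.null(term$inhibitor) && !is.na(term$inhibitor)) {
          v <- c(v, ki = term$ki)
        }
        v
      },
      logistic_growth = c(k1 = term$k1, k2 = term$k2))
    setNames(p, paste0("p", j, "_", names(p)))
  }))
}

#' @param p numeric parameter vector as produced by [surrogate_params()].
#' @rdname surrogate_params
#' @export
set_params <- function(model, p) {
  UseMethod("set_params")
}

#' @export
set_params.gma_surrogate <- function(model, p) {
  stopifnot(length(p) == model$m * (1 + model$n))
  mat <- matrix(p, nrow = model$m, byrow = TRUE)
  model$alpha <- mat[, 1]
  model$orders <- mat[, -1, drop = FALSE]
  model
}

#' @export
set_params.ssystem_surrogate <- function(model, p) {
  n <- model$n
  stopifnot(length(p) == 2 * (n + n^2))
  model$alpha <- p[1:n]
  model$beta <- p[(n + 1):(2 * n)]
  model$g <- matrix(p[2 * n + 1:(n^2)], n, n, byrow = TRUE)
  model$h <- matrix(p[2 * n + n^2 + 1:(n^2)], n, n, byrow = TRUE)
  model
}

#' @export
set_params.taylor_surrogate <- function(model, p) {
  n <- model$n
  expected <- if (model$order == 1) n^2 else (3 * n^2 + n^3) / 2
  stopifnot(length(p) == expected)
  model$J <- matrix(p[1:n^2], n, n, byrow = TRUE)
  if (model$order == 2) {
    k <- n * (n + 1) / 2
    idx <- which(lower.tri(diag(n), diag = TRUE))
    model$H <- lapply(seq_len(n), function(i) {
      Hi <- matrix(0, n, n)
      Hi[idx] <- p[n^2 + (i - 1) * k + 1:k]
      Hi[upper.tri(Hi)] <- t(Hi)[upper.tri(Hi)]
      Hi
    })
  }
  model
}

#' @export
set_params.mechanistic_surrogate <- function(model, p) {
  pos <- 0
  for (j in seq_along(model$processes)) {
    term <- model$processes[[j]]
    k <- switch(term$kind,
      power_law = 1,
      michaelis_menten = if (!is.null(term$inhibitor) &&
                             !is.na(term$inhibitor)) 3 else 2,
      logistic_growth = 2)
    vals <- p[pos + seq_len(k)]
    model$processes[[j]] <- switch(term$kind,
      power_law = { term$alpha <- vals[1]; term },
      michaelis_menten = {
        term$vmax <- vals[1]; term$km <- vals[2]
        if (k == 3) term$ki <- vals[3]
        term
      },
      logistic_growth = { term$k1 <- vals[1]; term$k2 <- vals[2]; term })
    pos <- pos + k
  }
  stopifnot(pos == length(p))
  model
}

#' Indices of kinetic-order parameters in the packed vector
#'
#' Used by the L1 penalty, which applies to kinetic orders only (sparsifying
#' orders performs variable selection; rate constants stay unpenalized).
#' @param model an `ode_surrogate`.
#' @return Integer indices into [surrogate_params()].
#' @export
order_indices <- function(model) {
  p <- surrogate_params(model)
  grep("^[gh]", names(p))
}

#' Attach a linear control term to a surrogate
#'
#' Appends `B u` to the model right-hand side. Two parameterizations cover
#' the reference control problems: proportional removal
#' (`u_i = -kappa_i X_i` on the targeted variables) and constant inflow
#' (`+Q` on one variable, with an optional first-order outflow on all
#' variables to mirror chemostat operation). With all control parameters at
#' zero the controlled right-hand side equals the uncontrolled one exactly.
#'
#' @param model an `ode_surrogate`.
#' @param term a [control_removal()] or [control_inflow()] term.
#' @export
add_control <- function(model, term) {
  stopifnot(inherits(model, "ode_surrogate"), inherits(term, "surrogate_control"))
  vars <- if (term$type == "removal") names(term$kappa) else term$variable
  bad <- setdiff(vars, model$labels)
  if (length(bad) > 0) {
    abort(paste0("control targets unknown state(s): ", paste(bad, collapse = ", ")))
  }
  model$control <- term
  model
}

#' @param kappa named non-negative default removal rates per targeted state.
#' @rdname add_control
#' @export
control_removal <- function(kappa) {
  if (any(kappa < 0)) abort("removal rates must be >= 0")
  structure(list(type = "removal", kappa = kappa), class = "surrogate_control")
}

#' @param variable state receiving the inflow.
#' @param Q default inflow rate (>= 0).
#' @param outflow first-order outflow rate applied to `outflow_vars`
#'   (0 disables).
#' @param outflow_vars states subject to outflow; defaults to all.
#' @rdname add_control
#' @export
control_inflow <- function(variable, Q = 0, outflow = 0, outflow_vars = NULL) {
  if (Q < 0 || outflow < 0) abort("inflow and outflow rates must be >= 0")
  structure(list(type = "inflow", variable = variable, Q = Q,
                 outflow = outflow, outflow_vars = outflow_vars),
            class = "surrogate_control")
}

#' Integrate a surrogate model
#'
#' Solves the surrogate ODE on `times`, first with a non-stiff Runge-Kutta
#' method and, if that fails or stalls, with a stiff-capable fallback
#' (`lsoda`). If no method reaches the end of the grid an error of class
#' `"abmctrl_integration_error"` is raised carrying the last reachable time
#' (`t_reached`), so callers can report the integrable sub-interval.
#'
#' @param model an `ode_surrogate`.
#' @param x0 initial state.
#' @param times increasing numeric time grid.
#' @param u named control parameter values (see [rhs()]).
#' @param methods integration methods to try in order.
#' @return A wide tibble: column `time` plus one column per state variable.
#' @export
integrate_surrogate <- function(model, x0, times, u = NULL,
                                methods = c("ode45", "lsoda")) {
  stopifnot(!is.unsorted(times, strictly = TRUE))
  out <- .integrate_matrix(model, x0, times, u, methods)
  tibble::as_tibble(as.data.frame(out$values)) |>
    setNames(model$labels) |>
    dplyr::mutate(time = out$times, .before = 1)
}

build_rhs_spec <- function(model, u = NULL) {
  n <- model$n
  spec <- list(n = n, ctrl = 0L)
  if (inherits(model, "gma_surrogate")) {
    spec$family <- 1L
    spec$m <- model$m
    spec$alpha <- model$alpha
    spec$g <- as.numeric(t(model$orders))
    spec$stoich <- as.numeric(t(model$stoich))
  } else if (inherits(model, "ssystem_surrogate")) {
    spec$family <- 2L
    spec$alpha <- model$alpha
    spec$beta <- model$beta
    spec$g <- as.numeric(t(model$g))
    spec$h <- as.numeric(t(model$h))
  } else if (inherits(model, "taylor_surrogate")) {
    spec$family <- 3L
    spec$order <- model$order
    spec$x0 <- model$x0
    spec$J <- as.numeric(t(model$J))
    if (model$order == 2) {
      spec$H <- unlist(lapply(model$H, function(Hi) as.numeric(t(Hi))))
    }
  } else if (inherits(model, "mechanistic_surrogate")) {
    spec$family <- 4L
    spec$m <- model$m
    spec$stoich <- as.numeric(t(model$stoich))
    kinds <- vapply(model$processes, `[[`, character(1), "kind")
    spec$pkind <- match(kinds, c("power_law", "michaelis_menten",
                                 "logistic_growth")) - 1L
    get_or <- function(term, field, default) {
      v <- term[[field]]
      if (is.null(v) || is.na(v)) default else v
    }
    spec$psub <- vapply(model$processes, get_or, numeric(1), "substrate", 1) - 1L
    spec$pinh <- as.integer(vapply(model$processes, get_or, numeric(1),
                                   "inhibitor", 0) - 1L)
    spec$pvar <- vapply(model$processes, get_or, numeric(1), "var", 1) - 1L
    spec$pv1 <- vapply(model$processes, function(tm) {
      switch(tm$kind, power_law = tm$alpha, michaelis_menten = tm$vmax,
             logistic_growth = tm$k1)
    }, numeric(1))
    spec$pv2 <- vapply(model$processes, function(tm) {
      switch(tm$kind, power_law = 0, michaelis_menten = tm$km,
             logistic_growth = tm$k2)
    }, numeric(1))
    spec$pv3 <- vapply(model$processes, function(tm) {
      if (tm$kind == "michaelis_menten" && !is.null(tm$inhibitor) &&
          !is.na(tm$inhibitor)) tm$ki else 0
    }, numeric(1))
    spec$pg <- as.numeric(t(do.call(rbind, lapply(model$processes, function(tm) {
      if (tm$kind == "power_law") tm$g else numeric(n)
    }))))
  } else {
    abort("unknown surrogate class")
  }
  ctrl <- model$control
  if (!is.null(ctrl)) {
    if (ctrl$type == "removal") {
      kappa <- setNames(numeric(n), model$labels)
      kappa[names(ctrl$kappa)] <- ctrl$kappa
      if (!is.null(u)) {
        shared <- intersect(names(u), model$labels)
        kappa[shared] <- u[shared]
      }
      if (any(kappa != 0)) {
        spec$ctrl <- 1L
        spec$kappa <- unname(kappa)
      }
    } else {
      q <- if (!is.null(u) && "Q" %in% names(u)) u[["Q"]] else ctrl$Q
      spec$ctrl <- 2L
      spec$qvar <- match(ctrl$variable, model$labels) - 1L
      spec$Q <- q
      spec$outflow <- ctrl$outflow %||% 0
      vars <- ctrl$outflow_vars %||% model$labels
      spec$outmask <- as.integer(model$labels %in% vars)
    }
  }
  spec
}

compiled_rhs <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ptr <- .rhs_func_ptr()
      class(ptr) <- "NativeSymbol"
      f <- function() NULL
      body(f) <- call("{", ptr)
      class(f) <- "CFunc"
      cache <<- f
    }
    cache
  }
})

.integrate_matrix <- function(model, x0, times, u = NULL,
                              methods = c("ode45", "lsoda"),
                              maxsteps = 5000, rtol = 1e-8, atol = 1e-8) {
  .stage_rhs_config(build_rhs_spec(model, u))
  t_reached <- times[1]
  for (method in methods) {
    # capture.output: the Fortran cores print step-size complaints directly
    utils::capture.output(
      sol <- tryCatch(
        suppressWarnings(deSolve::ode(y = as.numeric(x0), times = times,
                                      func = compiled_rhs(),
                                      initfunc = NULL,
                                      maxsteps = maxsteps, rtol = rtol,
                                      atol = atol,
                                      parms = NULL, method = method)),
        error = function(e) NULL))
    if (!is.null(sol)) {
      vals <- unname(as.matrix(sol)[, -1, drop = FALSE])
      ok <- stats::complete.cases(vals) & apply(is.finite(vals), 1, all)
      if (nrow(vals) == length(times) && all(ok)) {
        return(list(times = times, values = vals, method = method))
      }
      last <- if (any(ok)) sol[max(which(ok)), 1] else times[1]
      t_reached <- max(t_reached, last)
    }
  }
  abort(
    sprintf("integration failed; reachable sub-interval [%g, %g]",
            times[1], t_reached),
    class = "abmctrl_integration_error",
    t_reached = t_reached, t_start = times[1])
}

#' Find all roots of a surrogate right-hand side in a box
#'
#' Multi-start damped least-squares root search from a regular lattice of
#' starting points, deduplicated at an absolute per-coordinate tolerance and
#' returned in lexicographic order. Used both to locate controlled steady
#' states and to enforce the no-extra-roots constraint of the quadratic fit.
#'
#' @param model an `ode_surrogate`.
#' @param lower,upper box bounds (length `n`).
#' @param u named control parameter values.
#' @param starts lattice points per dimension.
#' @param tol dedup tolerance (absolute, per coordinate).
#' @return A list of root vectors (possibly empty).
#' @export
find_roots <- function(model, lower, upper, u = NULL, starts = 5, tol = 1e-6) {
  n <- model$n
  stopifnot(length(lower) == n, length(upper) == n, all(upper >= lower),
            all(is.finite(lower)), all(is.finite(upper)))
  grids <- lapply(seq_len(n), function(i) {
    seq(lower[i], upper[i], length.out = starts)
  })
  starts_mat <- as.matrix(expand.grid(grids))
  scale <- pmax(abs(upper - lower), 1)
  roots <- list()
  for (k in seq_len(nrow(starts_mat))) {
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = starts_mat[k, ],
        fn = function(p) tryCatch(rhs(model, p, u),
                                  error = function(e) rep(1e6, n)),
        lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 200, maxfev = 5000)),
      error = function(e) NULL)
    if (is.null(fit)) next
    root <- unname(coef(fit))
    resid <- tryCatch(rhs(model, root, u), error = function(e) rep(Inf, n))
    if (max(abs(resid)) < 1e-8 * max(1, max(abs(root)))) {
      dup <- any(vapply(roots, function(r) all(abs(r - root) <= tol),
                        logical(1)))
      if (!dup) roots <- c(roots, list(root))
    }
  }
  if (length(roots) > 1) {
    ord <- do.call(order, as.data.frame(do.call(rbind, roots)))
    roots <- roots[ord]
  }
  roots
}

#' @export
print.ode_surrogate <- function(x, ...) {
  cat(sprintf("<%s surrogate> %d state(s): %s\n", x$family, x$n,
              paste(x$labels, collapse = ", ")))
  if (!is.null(x$control)) {
    cat(sprintf("  control: %s\n", x$control$type))
  }
  invisible(x)
}
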