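#' Local power-law views of mechanistic process terms
#'
#' Any positive-valued rate law can be approximated near an operating point
#' `xbar` by the power law whose value and logarithmic derivatives match
#' there (the canonical approximation of biochemical systems theory). A
#' Michaelis-Menten rate yields kinetic order `Km / (Km + S)` in its
#' substrate and `-I / (Ki + I)` in a competitive inhibitor; a logistic
#' growth term splits into its two signed mass-action components.
#'
#' @param term a [process_term()].
#' @param xbar positive operating point.
#' @return List of components, each `list(coef, g)` with a signed
#'   coefficient and a kinetic-order vector.
#' @keywords internal
power_law_view <- function(term, xbar) {
  n <- length(xbar)
  switch(term$kind,
    power_law = list(list(coef = term$alpha, g = term$g)),
    michaelis_menten = {
      s <- xbar[term$substrate]
      g <- numeric(n)
      g[term$substrate] <- term$km / (term$km + s)
      v <- term$vmax * s / (term$km + s)
      if (!is.null(term$inhibitor) && !is.na(term$inhibitor)) {
        i <- xbar[term$inhibitor]
        g[term$inhibitor] <- -i / (term$ki + i)
        v <- v * term$ki / (term$ki + i)
      }
      list(list(coef = v / prod(xbar^g), g = g))
    },
    logistic_growth = {
      g1 <- numeric(n); g1[term$var] <- 1
      g2 <- numeric(n); g2[term$var] <- 2
      list(list(coef = term$k1, g = g1), list(coef = -term$k2, g = g2))
    })
}

collapse_power_laws <- function(components, xbar, eps = 1e-9) {
  # aggregate signed power-law components into one power law matching the
  # sum's value and log-derivatives at xbar; requires a positive sum
  vals <- vapply(components, function(cm) cm$coef * prod(xbar^cm$g),
                 numeric(1))
  f <- sum(vals)
  if (!is.finite(f) || f <= 0) {
    return(list(alpha = eps, g = numeric(length(xbar))))
  }
  w <- vals / f
  g <- Reduce(`+`, Map(function(cm, wt) wt * cm$g, components, w))
  list(alpha = f / prod(xbar^g), g = g)
}

#' S-system warm start from a fitted mechanistic model
#'
#' Collapses, per state equation, the aggregate influx and efflux of a
#' mechanistic model into single power laws at the operating point `xbar`,
#' yielding a principled S-system parameterization to start the fit from.
#'
#' @param model a `mechanistic_surrogate`.
#' @param xbar positive operating point (e.g. the time-mean of the training
#'   data).
#' @return An `ssystem_surrogate`.
#' @export
ssystem_from_mechanistic <- function(model, xbar) {
  stopifnot(inherits(model, "mechanistic_surrogate"), all(xbar > 0))
  n <- model$n
  alpha <- beta <- rep(1e-9, n)
  g <- h <- matrix(0, n, n)
  for (i in seq_len(n)) {
    influx <- list(); efflux <- list()
    for (j in seq_len(model$m)) {
      sgn <- model$stoich[i, j]
      if (sgn == 0) next
      for (cm in power_law_view(model$processes[[j]], xbar)) {
        cm$coef <- cm$coef * sgn
        if (cm$coef >= 0) influx <- c(influx, list(cm))
        else efflux <- c(efflux, list(list(coef = -cm$coef, g = cm$g)))
      }
    }
    if (length(influx) > 0) {
      cl <- collapse_power_laws(influx, xbar)
      alpha[i] <- max(cl$alpha, 1e-9); g[i, ] <- cl$g
    }
    if (length(efflux) > 0) {
      cl <- collapse_power_laws(efflux, xbar)
      beta[i] <- max(cl$alpha, 1e-9); h[i, ] <- cl$g
    }
  }
  ssystem_model(model$labels, alpha = alpha, beta = beta, g = g, h = h)
}

#' GMA warm starts for the reference pathways
#'
#' Rewrites a fitted mechanistic model into the reference GMA process list
#' by taking the local power-law view of each process at `xbar`
#' (sheep-wolves: the logistic pair collapses into the single net
#' grass-growth power law; metabolic: each Michaelis-Menten rate becomes a
#' saturating-order power law).
#'
#' @inheritParams ssystem_from_mechanistic
#' @return A `gma_surrogate` with the reference structure.
#' @export
gma_from_mechanistic_local <- function(model, xbar) {
  stopifnot(inherits(model, "mechanistic_surrogate"), all(xbar > 0))
  kinds <- vapply(model$processes, `[[`, character(1), "kind")
  if (identical(model$labels, c("grass", "sheep", "wolves")) &&
      model$m == 8) {
    # processes 1 and 2 (growth, crowding) collapse into net growth
    comp <- list(
      list(coef = model$processes[[1]]$alpha, g = model$processes[[1]]$g),
      list(coef = -model$processes[[2]]$alpha, g = model$processes[[2]]$g))
    net <- collapse_power_laws(comp, xbar)
    alpha <- c(max(net$alpha, 1e-9),
               vapply(model$processes[3:8], `[[`, numeric(1), "alpha"))
    orders <- rbind(net$g,
                    do.call(rbind, lapply(model$processes[3:8], `[[`, "g")))
    out <- sheep_wolves_gma(alpha = alpha, orders = orders)
    return(out)
  }
  # otherwise processes map one-to-one
  views <- lapply(model$processes, function(tm) {
    collapse_power_laws(power_law_view(tm, xbar), xbar)
  })
  gma_model(model$labels, model$stoich,
            alpha = pmax(vapply(views, `[[`, numeric(1), "alpha"), 1e-9),
            orders = do.call(rbind, lapply(views, `[[`, "g")))
}
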