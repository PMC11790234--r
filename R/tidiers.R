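#' Tidy a surrogate fit
#'
#' @param x a `surrogate_fit`.
#' @param ... unused.
#' @return One row per parameter: `term`, `estimate`, `penalized` flag (was
#'   the L1 penalty applied to this parameter) and `zero` (sparsity mask).
#' @export
tidy.surrogate_fit <- function(x, ...) {
  pen <- rep(FALSE, length(x$params))
  if (inherits(x$model, c("gma_surrogate", "ssystem_surrogate"))) {
    pen[order_indices(x$model)] <- x$lambda > 0
  }
  tibble::tibble(
    term = names(x$params),
    estimate = unname(x$params),
    penalized = pen,
    zero = unname(x$zero_mask)
  )
}

#' @export
glance.surrogate_fit <- function(x, ...) {
  tibble::tibble(
    family = x$model$family,
    n_params = length(x$params),
    residual = x$residual,
    lambda = x$lambda,
    n_zero = sum(x$zero_mask),
    converged = x$converged,
    datasets = paste(x$datasets, collapse = ",")
  )
}

#' @export
tidy.grid_search_result <- function(x, ...) {
  x$result
}

#' @export
glance.grid_search_result <- function(x, ...) {
  out <- tibble::tibble(
    n_points = nrow(x$result),
    replicates = x$replicates,
    steps = x$steps,
    n_infeasible = sum(!is.finite(x$result$mean))
  )
  if (nrow(x$best) > 0) {
    for (v in x$grid_vars) out[[paste0("best_", v)]] <- x$best[[v]]
    out$best_mean <- x$best$mean
  }
  out
}

#' @export
tidy.control_solution <- function(x, ...) {
  if (x$type == "transfer") {
    tibble::tibble(term = names(x$kappa), estimate = unname(x$kappa))
  } else {
    tibble::tibble(term = "Q", estimate = x$Q)
  }
}

#' @export
glance.control_solution <- function(x, ...) {
  tibble::tibble(
    type = x$type,
    objective = x$objective,
    feasible = x$feasible,
    no_interior_minimum = x$no_interior_minimum %||% NA
  )
}

#' @export
tidy.abm_dataset <- function(x, ...) {
  x$summary
}
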