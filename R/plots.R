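#' Plot a trajectory ensemble
#'
#' One panel per state variable, thin lines per replicate.
#'
#' @param object a tidy trajectory tibble (as returned by the simulators).
#' @param ... unused.
#' @export
plot_trajectory <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$value,
                                       group = .data$replicate)) +
    ggplot2::geom_line(alpha = 0.4, linewidth = 0.3) +
    ggplot2::facet_wrap(~variable, scales = "free_y") +
    ggplot2::labs(x = "time step", y = "count")
}

#' @export
autoplot.abm_dataset <- function(object, ...) {
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(x = .data$time, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~variable, scales = "free_y") +
    ggplot2::labs(title = paste("dataset", object$label),
                  x = "time step", y = "count (mean ± sd)")
}

#' @export
autoplot.surrogate_fit <- function(object, datasets, thin = 1, ...) {
  stopifnot(!missing(datasets))
  prepared <- prepare_datasets(object$model, datasets, thin)
  sims <- purrr::map(prepared, function(d) {
    sim <- integrate_surrogate(object$model, d$x0, d$times, u = d$control)
    tidyr::pivot_longer(sim, -"time", names_to = "variable",
                        values_to = "value") |>
      dplyr::mutate(dataset = d$label)
  }) |> purrr::list_rbind()
  data <- purrr::map(datasets, function(ds) {
    dplyr::mutate(ds$summary, dataset = ds$label)
  }) |> purrr::list_rbind()
  ggplot2::ggplot(sims, ggplot2::aes(x = .data$time)) +
    ggplot2::geom_point(data = data,
                        ggplot2::aes(y = .data$mean, colour = .data$dataset),
                        size = 0.4, alpha = 0.5) +
    ggplot2::geom_line(ggplot2::aes(y = .data$value, colour = .data$dataset)) +
    ggplot2::facet_wrap(~variable, scales = "free_y") +
    ggplot2::labs(y = "count", x = "time step",
                  title = paste(object$model$family, "surrogate fit"))
}

#' @export
autoplot.grid_search_result <- function(object, ...) {
  res <- object$result
  vars <- object$grid_vars
  if (length(vars) == 1) {
    ggplot2::ggplot(res, ggplot2::aes(x = .data[[vars]], y = .data$mean)) +
      ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           alpha = 0.25) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::geom_point(data = object$best, colour = "red", size = 3,
                          shape = 15) +
      ggplot2::labs(y = "objective (mean ± sd)")
  } else {
    ggplot2::ggplot(res, ggplot2::aes(x = .data[[vars[1]]],
                                      y = .data[[vars[2]]],
                                      fill = .data$mean)) +
      ggplot2::geom_tile() +
      ggplot2::geom_point(data = object$best, colour = "red", shape = 4,
                          size = 3, stroke = 1.5) +
      ggplot2::scale_fill_viridis_c()
  }
}
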