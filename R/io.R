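#' Read and write tidy trajectory CSV files
#'
#' Trajectory ensembles are exchanged as tidy CSV with the mandatory header
#' `time,replicate,variable,value`, UTF-8, in deterministic row order
#' (time-major, then declared variable order). Values round-trip losslessly
#' (written with full precision).
#'
#' @param traj a tidy trajectory tibble.
#' @param path file path.
#' @return `write_trajectory()` returns `path` invisibly;
#'   `read_trajectory()` returns the trajectory tibble.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(all(c("time", "replicate", "variable", "value") %in% names(traj)))
  labels <- traj_labels(traj)
  out <- traj |>
    dplyr::mutate(variable = factor(.data$variable, levels = labels)) |>
    dplyr::arrange(.data$replicate, .data$time, .data$variable) |>
    dplyr::mutate(variable = as.character(.data$variable))
  readr::write_csv(out[, c("time", "replicate", "variable", "value")], path)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  traj <- readr::read_csv(path, show_col_types = FALSE,
                          col_types = readr::cols(
                            time = readr::col_integer(),
                            replicate = readr::col_integer(),
                            variable = readr::col_character(),
                            value = readr::col_double()))
  missing <- setdiff(c("time", "replicate", "variable", "value"), names(traj))
  if (length(missing) > 0) {
    abort(paste0("trajectory file lacks column(s): ",
                 paste(missing, collapse = ", ")))
  }
  bad <- which(!is.finite(traj$value))
  if (length(bad) > 0) {
    abort(sprintf("non-numeric or non-finite value at data row %d", bad[1]))
  }
  tibble::as_tibble(traj)
}

#' Serialize a surrogate fit to JSON
#'
#' @param fit a `surrogate_fit`.
#' @param path file path.
#' @export
write_fit <- function(fit, path) {
  stopifnot(inherits(fit, "surrogate_fit"))
  obj <- list(
    family = fit$model$family,
    order = fit$model$order,
    x0 = fit$model$x0,
    labels = fit$model$labels,
    lambda = fit$lambda,
    params = as.list(fit$params),
    residual = fit$residual,
    converged = fit$converged,
    zero_mask = as.list(fit$zero_mask),
    datasets = fit$datasets,
    seed = fit$seed
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
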