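#' Tidy trajectory tibbles
#'
#' All simulators in abmctrl return trajectories in a single tidy format: a
#' tibble with columns `time` (integer step), `replicate` (integer id),
#' `variable` (state-variable label) and `value` (count). Rows are ordered
#' time-major, then by the declared variable order. The same format is the
#' input currency of the calibration and control modules.
#'
#' @param times integer vector of time steps (length T).
#' @param values numeric matrix, T x n, one column per state variable.
#' @param labels character vector of n state-variable labels.
#' @param replicate integer replicate id.
#' @return A tibble with columns `time`, `replicate`, `variable`, `value`.
#' @export
new_trajectory <- function(times, values, labels, replicate = 1L) {
  values <- as.matrix(values)
  stopifnot(length(times) == nrow(values), length(labels) == ncol(values))
  if (any(values < 0, na.rm = TRUE)) {
    abort("trajectory values must be non-negative counts")
  }
  tibble::tibble(
    time = rep(as.integer(times), each = ncol(values)),
    replicate = as.integer(replicate),
    variable = factor(rep(labels, length(times)), levels = labels),
    value = as.numeric(t(values))
  ) |>
    dplyr::mutate(variable = as.character(.data$variable))
}

traj_labels <- function(traj) {
  # declared variable order = order of first appearance (time-major layout)
  unique(traj$variable)
}

#' Reshape a tidy trajectory to a time-by-variable matrix
#'
#' @param traj a tidy trajectory tibble (single replicate, or pass
#'   `replicate` to select one).
#' @param replicate optional replicate id to extract.
#' @return A list with `times` (integer vector) and `values`
#'   (matrix, time by variable, with variable labels as column names).
#' @export
trajectory_matrix <- function(traj, replicate = NULL) {
  if (!is.null(replicate)) {
    traj <- dplyr::filter(traj, .data$replicate == !!replicate)
  }
  if (dplyr::n_distinct(traj$replicate) > 1) {
    abort("trajectory has several replicates; select one or average first")
  }
  labels <- traj_labels(traj)
  wide <- tidyr::pivot_wider(traj, id_cols = "time",
                             names_from = "variable", values_from = "value")
  wide <- dplyr::arrange(wide, .data$time)
  list(times = wide$time, values = as.matrix(wide[, labels, drop = FALSE]))
}

#' Remove agents independently with a fixed probability
#'
#' The control primitive used to thin a population: each individual survives
#' with probability `1 - fraction`, independently. The number removed is
#' binomially distributed.
#'
#' @param n population size (non-negative integer).
#' @param fraction per-individual removal probability in \[0, 1\].
#' @return A list with `survivors` and `removed` counts.
#' @export
apply_removal <- function(n, fraction) {
  stopifnot(is.numeric(n), length(n) == 1, is.finite(n), n >= 0)
  if (!is.numeric(fraction) || length(fraction) != 1 ||
      is.na(fraction) || fraction < 0 || fraction > 1) {
    abort("`fraction` must be a single value in [0, 1]")
  }
  removed <- rbinom(1L, size = as.integer(n), prob = fraction)
  list(survivors = as.integer(n) - removed, removed = removed)
}

#' Map agent subtypes onto surrogate state variables
#'
#' A state map declares, for every agent subtype an ABM can contain, either
#' the ODE state variable it is aggregated into or that it is deliberately
#' left out of the surrogate (e.g. enzymes and complexes when only free
#' metabolites are modelled).
#'
#' @param states ordered character vector of state-variable labels.
#' @param map named character vector: names are agent subtypes, values the
#'   state each subtype contributes to. Defaults to the identity map on
#'   `states`.
#' @param unmapped character vector of subtypes that are declared but not
#'   aggregated into any state.
#' @export
state_map <- function(states, map = setNames(states, states), unmapped = character()) {
  stopifnot(length(states) >= 1, !anyDuplicated(states))
  if (!all(map %in% states)) {
    abort("every mapped subtype must map onto a declared state")
  }
  if (any(names(map) %in% unmapped)) {
    abort("a subtype cannot be both mapped and unmapped")
  }
  structure(list(states = states, map = map, unmapped = unmapped),
            class = "state_map")
}

#' Aggregate per-subtype agent counts into state-variable counts
#'
#' @param counts named integer vector of agent counts per subtype.
#' @param sm a [state_map()].
#' @return Named integer vector over `sm$states`; the sum over states equals
#'   the number of agents of mapped subtypes.
#' @export
aggregate_counts <- function(counts, sm) {
  stopifnot(inherits(sm, "state_map"), !is.null(names(counts)))
  known <- c(names(sm$map), sm$unmapped)
  unknown <- setdiff(names(counts), known)
  if (length(unknown) > 0) {
    abort(paste0("unknown agent subtype(s): ", paste(unknown, collapse = ", ")))
  }
  out <- setNames(numeric(length(sm$states)), sm$states)
  mapped <- intersect(names(counts), names(sm$map))
  for (s in mapped) {
    out[sm$map[[s]]] <- out[sm$map[[s]]] + counts[[s]]
  }
  out
}

#' Declare a per-step control schedule for an ABM run
#'
#' @param removal named numeric vector of per-step removal fractions per
#'   subtype (independent Bernoulli per agent), each in \[0, 1\].
#' @param inflow named numeric vector of expected molecules inserted per step
#'   (values in \[0, 1\] are realised as Bernoulli one-molecule insertions).
#' @param start first time step (>= 0) at which the schedule applies.
#' @export
control_schedule <- function(removal = numeric(), inflow = numeric(), start = 0L) {
  if (length(removal) && (any(removal < 0) || any(removal > 1))) {
    abort("removal fractions must lie in [0, 1]")
  }
  if (length(inflow) && any(inflow < 0)) {
    abort("inflow rates must be >= 0")
  }
  stopifnot(start >= 0)
  structure(list(removal = removal, inflow = inflow, start = as.integer(start)),
            class = "control_schedule")
}

is_empty_schedule <- function(schedule) {
  all(c(schedule$removal, schedule$inflow) == 0) ||
    (length(schedule$removal) + length(schedule$inflow)) == 0
}
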