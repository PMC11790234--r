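#' Sheep-wolves-grass model parameters
#'
#' A lattice predator-prey model with an energy budget: sheep and wolves move
#' at random on a toroidal grid, paying `move_cost` energy per step; a sheep
#' on fully grown grass may graze (gaining `sheep_gain` and starting that
#' cell's regrowth countdown), a wolf sharing a cell with a sheep may eat it
#' (gaining `wolf_gain`); each animal reproduces with its per-step
#' probability, splitting its energy evenly with the offspring; animals whose
#' energy is depleted die. The reference configuration is a 255 x 255 world
#' with 2,500 sheep, 1,250 wolves and 50% initial grass cover; rule constants
#' follow the classic wolf-sheep-predation defaults (sheep gain 4, wolf gain
#' 20, reproduction 4% / 5%, grass regrowth 30 steps).
#'
#' @param scale linear down-scaling factor: the world side is divided by
#'   `scale` and the initial populations by `scale^2`, preserving densities.
#'   `scale = 5` gives the 51 x 51 / 100 sheep / 50 wolves desk configuration.
#' @param width,height grid dimensions in cells.
#' @param initial_sheep,initial_wolves,initial_grass initial populations and
#'   the fraction of cells starting fully grown.
#' @param sheep_gain,wolf_gain energy gained per feeding event.
#' @param sheep_reproduce,wolf_reproduce per-step reproduction probabilities.
#' @param grass_regrowth steps an eaten cell needs to regrow.
#' @param move_cost energy paid per movement step.
#' @param grazing_prob,predation_prob probability that a feeding opportunity
#'   is taken (1 in the reference rules).
#' @return An object of class `sw_model`.
#' @export
sheep_wolves_params <- function(scale = 1,
                                width = NULL, height = NULL,
                                initial_sheep = NULL, initial_wolves = NULL,
                                initial_grass = 0.5,
                                sheep_gain = 4, wolf_gain = 20,
                                sheep_reproduce = 0.04, wolf_reproduce = 0.05,
                                grass_regrowth = 30, move_cost = 1,
                                grazing_prob = 1, predation_prob = 1) {
  stopifnot(scale >= 1)
  width <- width %||% as.integer(round(255 / scale))
  height <- height %||% as.integer(round(255 / scale))
  initial_sheep <- initial_sheep %||% as.integer(round(2500 / scale^2))
  initial_wolves <- initial_wolves %||% as.integer(round(1250 / scale^2))
  probs <- c(initial_grass, sheep_reproduce, wolf_reproduce,
             grazing_prob, predation_prob)
  if (any(probs < 0 | probs > 1)) abort("probabilities must lie in [0, 1]")
  if (sheep_gain <= 0 || wolf_gain <= 0 || grass_regrowth <= 0 || move_cost <= 0) {
    abort("gains, regrowth time and move cost must be > 0")
  }
  structure(list(
    width = as.integer(width), height = as.integer(height),
    initial_sheep = as.integer(initial_sheep),
    initial_wolves = as.integer(initial_wolves),
    initial_grass = initial_grass,
    sheep_gain = sheep_gain, wolf_gain = wolf_gain,
    sheep_reproduce = sheep_reproduce, wolf_reproduce = wolf_reproduce,
    grass_regrowth = as.integer(grass_regrowth), move_cost = move_cost,
    grazing_prob = grazing_prob, predation_prob = predation_prob,
    labels = c("grass", "sheep", "wolves")
  ), class = c("sw_model", "abm_model"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run an ABM simulation
#'
#' Runs one seeded simulation of a reference ABM and records the aggregated
#' state-variable counts at every step (or every `stride` steps for the
#' metabolic model). Identical `(seed, model, schedule)` triples reproduce
#' runs bit-exactly.
#'
#' @param model an `sw_model` or `met_model` object.
#' @param steps number of time steps (>= 0).
#' @param seed integer RNG seed for this run.
#' @param schedule a [control_schedule()].
#' @param ... passed to methods (`stride`, `raw` for the metabolic model).
#' @return A tidy trajectory tibble (see [new_trajectory()]); when control is
#'   active the numbers removed per step are attached as attribute
#'   `"removed"`.
#' @export
run_simulation <- function(model, steps, seed, schedule = control_schedule(), ...) {
  UseMethod("run_simulation")
}

#' @export
run_simulation.sw_model <- function(model, steps, seed,
                                    schedule = control_schedule(), ...) {
  stopifnot(inherits(schedule, "control_schedule"))
  if (steps < 0) abort("`steps` must be non-negative")
  bad <- setdiff(names(schedule$removal), model$labels)
  if (length(bad) > 0) {
    abort(paste0("schedule names unknown subtypes: ", paste(bad, collapse = ", ")))
  }
  if (length(schedule$inflow) > 0) {
    abort("the sheep-wolves model has no inflow control")
  }
  ctrl <- list(
    start = schedule$start,
    grass = unname(schedule$removal["grass"] %|NA|% 0),
    sheep = unname(schedule$removal["sheep"] %|NA|% 0),
    wolves = unname(schedule$removal["wolves"] %|NA|% 0)
  )
  set.seed(seed)
  out <- .sw_simulate(model, as.integer(steps), ctrl)
  traj <- new_trajectory(0:steps, out$counts, model$labels)
  colnames(out$removed) <- model$labels
  attr(traj, "removed") <- out$removed
  attr(traj, "seed") <- seed
  traj
}

`%|NA|%` <- function(a, b) if (length(a) == 0 || is.na(a)) b else a

#' Simulate a replicate ensemble of an ABM
#'
#' Convenience wrapper around [run_simulation()]: replicate `r` of an
#' ensemble rooted at `seed` uses seed `seed + r`.
#'
#' @inheritParams run_simulation
#' @param replicates number of independent replicates.
#' @param ... passed to [run_simulation()] methods.
#' @return A tidy trajectory tibble with one `replicate` id per run.
#' @export
simulate_ensemble <- function(model, steps, seed, replicates = 1,
                              schedule = control_schedule(), ...) {
  purrr::map(seq_len(replicates), function(r) {
    traj <- run_simulation(model, steps, seed + r, schedule = schedule, ...)
    traj$replicate <- as.integer(r)
    traj
  }) |>
    purrr::list_rbind()
}
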