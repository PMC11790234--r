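#' Training-dataset recipes for the reference ABMs
#'
#' Five datasets per model. Sheep-wolves: I and II are uncontrolled
#' ensembles from two different initializations; III, IV and V start from
#' initialization I and apply control from the midpoint of the run (2% of
#' grass, 2% of sheep, or 1.5% of wolves removed per step, respectively).
#' Metabolic: I is a single batch run; II a single continuous run (inflow 1
#' molecule/step, outflow 0.05%/step); III and IV are replicate-averaged
#' versions of I and II; V is a replicate-averaged continuous run with
#' inflow 0.2. Reference replicate counts are 100 for averaged datasets and
#' 1 for single runs.
#'
#' @param model_name `"sheep_wolves"` or `"metabolic"`.
#' @return A tibble of recipes (label, init, control, replicates).
#' @export
dataset_recipes <- function(model_name = c("sheep_wolves", "metabolic")) {
  model_name <- match.arg(model_name)
  if (model_name == "sheep_wolves") {
    tibble::tibble(
      label = c("I", "II", "III", "IV", "V"),
      init = c("A", "B", "A", "A", "A"),
      control_var = c(NA, NA, "grass", "sheep", "wolves"),
      control_value = c(0, 0, 0.02, 0.02, 0.015),
      replicates = c(100L, 100L, 100L, 100L, 100L)
    )
  } else {
    tibble::tibble(
      label = c("I", "II", "III", "IV", "V"),
      mode = c("batch", "continuous", "batch", "continuous", "continuous"),
      inflow = c(0, 1, 0, 1, 0.2),
      replicates = c(1L, 1L, 100L, 100L, 100L)
    )
  }
}

#' Generate the reference training datasets
#'
#' Simulates the requested dataset recipes (see [dataset_recipes()]) and
#' averages each ensemble into an [average_ensemble()] dataset. Replicate
#' `r` of a dataset uses seed `seed + r`, with disjoint seed blocks per
#' dataset.
#'
#' @param model an `sw_model` or `met_model` configuration (desk- or
#'   full-scale); initialization II of the sheep-wolves model uses 1.5x the
#'   sheep and 0.6x the wolves of the model's configured initialization.
#' @param labels recipe labels to generate (subset of `"I"`..`"V"`).
#' @param seed root seed.
#' @param steps steps per run.
#' @param replicates optional override of the recipes' replicate counts
#'   (for desk-scale work).
#' @param control_start first step of control application for the
#'   controlled sheep-wolves datasets; defaults to `steps / 2`.
#' @param stride recording stride (metabolic model).
#' @return Named list of `abm_dataset` objects.
#' @export
generate_datasets <- function(model, labels = c("I", "II", "III", "IV", "V"),
                              seed = 1, steps = 2000, replicates = NULL,
                              control_start = NULL, stride = 1L) {
  UseMethod("generate_datasets")
}

#' @export
generate_datasets.sw_model <- function(model,
                                       labels = c("I", "II", "III", "IV", "V"),
                                       seed = 1, steps = 2000,
                                       replicates = NULL,
                                       control_start = NULL, stride = 1L) {
  recipes <- dataset_recipes("sheep_wolves")
  check_labels(labels, recipes$label)
  control_start <- control_start %||% (steps %/% 2)
  out <- list()
  for (lab in labels) {
    r <- recipes[recipes$label == lab, ]
    reps <- replicates %||% r$replicates
    m <- model
    if (r$init == "B") {
      m$initial_sheep <- as.integer(round(1.5 * model$initial_sheep))
      m$initial_wolves <- as.integer(round(0.6 * model$initial_wolves))
    }
    schedule <- if (is.na(r$control_var)) {
      control_schedule()
    } else {
      control_schedule(removal = setNames(r$control_value, r$control_var),
                       start = control_start)
    }
    block_seed <- seed + 1000 * match(lab, recipes$label)
    traj <- simulate_ensemble(m, steps, seed = block_seed, replicates = reps,
                              schedule = schedule)
    ctrl <- if (is.na(r$control_var)) numeric()
            else setNames(r$control_value, r$control_var)
    out[[lab]] <- average_ensemble(traj, label = lab, control = ctrl,
                                   init_id = r$init)
  }
  out
}

#' @export
generate_datasets.met_model <- function(model,
                                        labels = c("I", "II", "III", "IV", "V"),
                                        seed = 1, steps = 10000,
                                        replicates = NULL,
                                        control_start = NULL, stride = 20L) {
  recipes <- dataset_recipes("metabolic")
  check_labels(labels, recipes$label)
  out <- list()
  for (lab in labels) {
    r <- recipes[recipes$label == lab, ]
    reps <- replicates %||% r$replicates
    m <- if (r$mode == "continuous") with_inflow(model, r$inflow) else model
    block_seed <- seed + 1000 * match(lab, recipes$label)
    traj <- simulate_ensemble(m, steps, seed = block_seed, replicates = reps,
                              schedule = control_schedule(), stride = stride)
    ctrl <- if (r$mode == "continuous") c(Q = r$inflow) else numeric()
    out[[lab]] <- average_ensemble(traj, label = lab, control = ctrl,
                                   init_id = r$mode)
  }
  out
}

check_labels <- function(labels, known) {
  bad <- setdiff(labels, known)
  if (length(bad) > 0) {
    abort(paste0("unknown dataset label(s): ", paste(bad, collapse = ", ")))
  }
}
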