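#' Species table of the elementary-step metabolic pathway ABM
#'
#' The pathway converts substrate S through intermediates A and B into the
#' two branch products R and T: S -> A (enzyme E1), A -> B (E2), B -> R (E3)
#' and B -> T (E4), all irreversible at the catalytic step. Two regulatory
#' interactions couple the branches in mixed-inhibition form: product T binds
#' the sibling branch enzyme E3 (free or substrate-loaded, giving the
#' inactive complexes E3T and E3BT) and product R binds E4 similarly (E4R,
#' E4BR). Together with the four enzyme-substrate and four enzyme-product
#' complexes this yields the 12 enzyme-containing complexes of the reference
#' pathway. The interaction tables are data, not code, so alternative
#' topologies can be declared.
#'
#' @return A tibble with one row per species: `species`, `type`
#'   (`"metabolite"`, `"enzyme"` or `"complex"`), `enzyme` (the enzyme a
#'   complex contains, `NA` otherwise) and `n_bound` (number of metabolite
#'   moieties bound in the species).
#' @export
metabolic_species <- function() {
  tibble::tribble(
    ~species, ~type,        ~enzyme, ~n_bound,
    "S",      "metabolite", NA,      1,
    "A",      "metabolite", NA,      1,
    "B",      "metabolite", NA,      1,
    "R",      "metabolite", NA,      1,
    "T",      "metabolite", NA,      1,
    "E1",     "enzyme",     "E1",    0,
    "E2",     "enzyme",     "E2",    0,
    "E3",     "enzyme",     "E3",    0,
    "E4",     "enzyme",     "E4",    0,
    "E1S",    "complex",    "E1",    1,
    "E1A",    "complex",    "E1",    1,
    "E2A",    "complex",    "E2",    1,
    "E2B",    "complex",    "E2",    1,
    "E3B",    "complex",    "E3",    1,
    "E3R",    "complex",    "E3",    1,
    "E3T",    "complex",    "E3",    1,
    "E3BT",   "complex",    "E3",    2,
    "E4B",    "complex",    "E4",    1,
    "E4T",    "complex",    "E4",    1,
    "E4R",    "complex",    "E4",    1,
    "E4BR",   "complex",    "E4",    2
  )
}

#' Metabolic pathway model parameters
#'
#' Builds the elementary-step pathway ABM (see [metabolic_species()] for the
#' topology). Metabolites take `metabolite_speed` movement substeps per
#' enzyme/complex step, and binding is attempted whenever a metabolite lands
#' on a cell occupied by a binding-competent partner. In `"continuous"` mode
#' the vessel behaves like a constant-volume stirred tank: substrate S flows
#' in at `inflow` expected molecules per step (Bernoulli insertion) and every
#' free metabolite leaves with probability `outflow` per step; enzymes and
#' complexes never leave.
#'
#' Default lattice size, molecule counts and event probabilities are the
#' package's desk-scale reference configuration, chosen via the mechanistic
#' mean-field model so that the continuous-mode pathway shows the
#' characteristic interior optimum of the inflow control problem (see the
#' methods vignette).
#'
#' @param width,height grid dimensions in cells.
#' @param initial_counts named integer vector of initial molecule counts; any
#'   species omitted starts at 0.
#' @param bind_prob probability that S or A binds its cognate free enzyme
#'   (E1, E2) on contact.
#' @param branch_bind_prob probability that B binds a branch enzyme (E3, E4)
#'   on contact.
#' @param product_bind_prob probability that a product rebinds its producing
#'   enzyme on contact.
#' @param unbind_prob per-step dissociation probability of an
#'   enzyme-substrate complex.
#' @param product_release_prob per-step release probability of a bound
#'   product.
#' @param cat_prob named numeric vector of per-step catalysis probabilities
#'   for enzymes E1-E4.
#' @param reg_bind_prob,reg_release_prob contact-binding and per-step release
#'   probabilities of the two regulatory (inhibitory) interactions.
#' @param metabolite_speed movement substeps per step for metabolites
#'   (10 in the reference configuration).
#' @param mode `"batch"` (closed vessel) or `"continuous"` (chemostat-like).
#' @param inflow expected molecules of S inserted per step in continuous
#'   mode, in \[0, 1\].
#' @param outflow per-step exit probability of each free metabolite in
#'   continuous mode (reference value 0.0005, i.e. 0.05% per step).
#' @return An object of class `met_model`.
#' @export
metabolic_params <- function(width = 16, height = 16,
                             initial_counts = NULL,
                             bind_prob = 6e-4,
                             branch_bind_prob = 9e-4,
                             product_bind_prob = 1e-3,
                             unbind_prob = 0.05,
                             product_release_prob = 0.05,
                             cat_prob = c(E1 = 0.019, E2 = 0.019,
                                          E3 = 0.019, E4 = 0.019),
                             reg_bind_prob = 0.1,
                             reg_release_prob = 0.016,
                             metabolite_speed = 10,
                             mode = c("batch", "continuous"),
                             inflow = 1, outflow = 5e-4) {
  mode <- match.arg(mode)
  default_init <- is.null(initial_counts)
  if (default_init) {
    initial_counts <- if (mode == "batch") {
      c(S = 400, E1 = 40, E2 = 40, E3 = 20, E4 = 20)
    } else {
      # continuous-mode reference initialization: vessel pre-loaded near its
      # operating state so product pools (the loss denominators) are occupied
      c(S = 400, R = 6, T = 6, E1 = 40, E2 = 40,
        E3 = 6, E4 = 6, E3T = 14, E4R = 14)
    }
  }
  sp <- metabolic_species()
  probs <- c(bind_prob, branch_bind_prob, product_bind_prob, unbind_prob, product_release_prob,
             cat_prob, reg_bind_prob, reg_release_prob, outflow)
  if (any(probs < 0 | probs > 1)) abort("probabilities must lie in [0, 1]")
  if (inflow < 0 || inflow > 1) {
    abort("inflow must lie in [0, 1] molecules per step (Bernoulli insertion)")
  }
  code <- setNames(seq_len(nrow(sp)) - 1L, sp$species)
  init <- setNames(integer(nrow(sp)), sp$species)
  bad <- setdiff(names(initial_counts), sp$species)
  if (length(bad) > 0) {
    abort(paste0("unknown species in initial_counts: ", paste(bad, collapse = ", ")))
  }
  init[names(initial_counts)] <- as.integer(initial_counts)

  bind <- tibble::tribble(
    ~met, ~partner, ~complex, ~prob,
    "S", "E1", "E1S", bind_prob,
    "A", "E1", "E1A", product_bind_prob,
    "A", "E2", "E2A", bind_prob,
    "B", "E2", "E2B", product_bind_prob,
    "B", "E3", "E3B", branch_bind_prob,
    "R", "E3", "E3R", product_bind_prob,
    "B", "E4", "E4B", branch_bind_prob,
    "T", "E4", "E4T", product_bind_prob,
    "T", "E3", "E3T", reg_bind_prob,
    "T", "E3B", "E3BT", reg_bind_prob,
    "R", "E4", "E4R", reg_bind_prob,
    "R", "E4B", "E4BR", reg_bind_prob
  )
  dis <- tibble::tribble(
    ~complex, ~met, ~partner, ~prob,
    "E1S", "S", "E1", unbind_prob,
    "E1A", "A", "E1", product_release_prob,
    "E2A", "A", "E2", unbind_prob,
    "E2B", "B", "E2", product_release_prob,
    "E3B", "B", "E3", unbind_prob,
    "E3R", "R", "E3", product_release_prob,
    "E4B", "B", "E4", unbind_prob,
    "E4T", "T", "E4", product_release_prob,
    "E3T", "T", "E3", reg_release_prob,
    "E3BT", "T", "E3B", reg_release_prob,
    "E4R", "R", "E4", reg_release_prob,
    "E4BR", "R", "E4B", reg_release_prob
  )
  cat_tab <- tibble::tribble(
    ~from, ~to, ~prob,
    "E1S", "E1A", unname(cat_prob["E1"]),
    "E2A", "E2B", unname(cat_prob["E2"]),
    "E3B", "E3R", unname(cat_prob["E3"]),
    "E4B", "E4T", unname(cat_prob["E4"])
  )

  structure(list(
    width = as.integer(width), height = as.integer(height),
    species = sp, code = code,
    initial_counts = init,
    is_metabolite = sp$type == "metabolite",
    metabolite_speed = as.integer(metabolite_speed),
    bind_table = cbind(code[bind$met], code[bind$partner], code[bind$complex]),
    bind_prob = bind$prob,
    dis_table = cbind(code[dis$complex], code[dis$met], code[dis$partner]),
    dis_prob = dis$prob,
    cat_table = cbind(code[cat_tab$from], code[cat_tab$to]),
    cat_prob = cat_tab$prob,
    mode = mode, inflow = inflow, outflow = outflow,
    default_init = default_init,
    labels = sp$species[sp$type == "metabolite"]
  ), class = c("met_model", "abm_model"))
}

#' Switch a metabolic model to continuous mode with a given inflow
#'
#' @param model a `met_model`.
#' @param inflow expected molecules of S per step, in \[0, 1\].
#' @param outflow per-step exit probability of free metabolites.
#' @export
with_inflow <- function(model, inflow, outflow = model$outflow) {
  stopifnot(inherits(model, "met_model"))
  if (inflow < 0 || inflow > 1) abort("inflow must lie in [0, 1]")
  if (model$mode == "batch" && isTRUE(model$default_init)) {
    # switching modes switches to the continuous-mode reference initialization
    cont <- metabolic_params(mode = "continuous")
    model$initial_counts <- cont$initial_counts
  }
  model$mode <- "continuous"
  model$inflow <- inflow
  model$outflow <- outflow
  model
}

#' @param stride record every `stride`-th step (plus the initial state).
#' @param raw if `TRUE`, return counts of all 21 species instead of the five
#'   free-metabolite state variables.
#' @rdname run_simulation
#' @export
run_simulation.met_model <- function(model, steps, seed,
                                     schedule = control_schedule(),
                                     stride = 1L, raw = FALSE, ...) {
  stopifnot(inherits(schedule, "control_schedule"))
  if (steps < 0) abort("`steps` must be non-negative")
  if (length(schedule$removal) > 0) {
    abort("the metabolic model supports inflow control only")
  }
  inflow <- model$inflow
  if (length(schedule$inflow) > 0) {
    bad <- setdiff(names(schedule$inflow), "S")
    if (length(bad) > 0) {
      abort(paste0("only substrate S can be inflow-controlled, got: ",
                   paste(bad, collapse = ", ")))
    }
    inflow <- unname(schedule$inflow["S"])
  }
  ctrl <- list(
    continuous = model$mode == "continuous" || length(schedule$inflow) > 0,
    inflow = inflow,
    inflow_code = unname(model$code["S"]),
    outflow = model$outflow,
    start = schedule$start
  )
  set.seed(seed)
  out <- .met_simulate(model, as.integer(steps), ctrl, as.integer(stride))
  colnames(out$counts) <- names(model$code)
  if (raw) {
    traj <- new_trajectory(out$times, out$counts, names(model$code))
  } else {
    sm <- metabolic_state_map()
    traj <- new_trajectory(out$times, out$counts[, sm$states, drop = FALSE],
                           sm$states)
  }
  attr(traj, "seed") <- seed
  traj
}

#' State map of the metabolic surrogate
#'
#' The five ODE state variables are the free metabolite counts; enzymes and
#' complexes are deliberately unmapped (the mean-field surrogate absorbs them
#' into its rate laws).
#' @export
metabolic_state_map <- function() {
  sp <- metabolic_species()
  mets <- sp$species[sp$type == "metabolite"]
  state_map(states = mets, map = setNames(mets, mets),
            unmapped = sp$species[sp$type != "metabolite"])
}

#' Conserved totals of a raw metabolic trajectory
#'
#' For each enzyme, free + complexed copies are constant over any run; in
#' batch mode the total number of metabolite moieties (free + bound inside
#' complexes) is also constant. Used as conservation oracles in the tests.
#'
#' @param traj a raw (21-species) metabolic trajectory tibble.
#' @return A tibble per time point with one column per enzyme total and
#'   `metabolite_total`.
#' @export
metabolic_conserved <- function(traj) {
  sp <- metabolic_species()
  m <- trajectory_matrix(traj)
  vals <- m$values
  out <- tibble::tibble(time = m$times)
  for (e in c("E1", "E2", "E3", "E4")) {
    cols <- sp$species[!is.na(sp$enzyme) & sp$enzyme == e]
    out[[e]] <- rowSums(vals[, cols, drop = FALSE])
  }
  out$metabolite_total <- as.numeric(vals %*% sp$n_bound)
  out
}
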