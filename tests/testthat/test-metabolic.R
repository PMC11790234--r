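test_that("the declared pathway has 5 metabolites, 4 enzymes, 12 complexes", {
  sp <- metabolic_species()
  expect_equal(sum(sp$type == "metabolite"), 5)
  expect_equal(sum(sp$type == "enzyme"), 4)
  expect_equal(sum(sp$type == "complex"), 12)
})

test_that("a substrate binds a co-located enzyme when the probability is 1", {
  p <- metabolic_params(width = 1, height = 1,
                        initial_counts = c(S = 1, E1 = 1),
                        bind_prob = 1, unbind_prob = 0, cat_prob = c(E1 = 0,
                        E2 = 0, E3 = 0, E4 = 0))
  m <- trajectory_matrix(run_simulation(p, 1, seed = 1, raw = TRUE))
  expect_equal(unname(m$values[2, "E1S"]), 1)
  expect_equal(unname(m$values[2, "S"]), 0)
  expect_equal(unname(m$values[2, "E1"]), 0)
})

test_that("a complex with dissociation probability 1 splits into its parts", {
  p <- metabolic_params(width = 3, height = 3,
                        initial_counts = c(E1S = 1),
                        bind_prob = 0, unbind_prob = 1,
                        cat_prob = c(E1 = 0, E2 = 0, E3 = 0, E4 = 0))
  m <- trajectory_matrix(run_simulation(p, 1, seed = 2, raw = TRUE))
  expect_equal(unname(m$values[2, "E1S"]), 0)
  expect_equal(unname(m$values[2, "S"]), 1)
  expect_equal(unname(m$values[2, "E1"]), 1)
})

test_that("catalysis converts the substrate complex to the product complex", {
  p <- metabolic_params(width = 3, height = 3,
                        initial_counts = c(E1S = 1),
                        bind_prob = 0, unbind_prob = 0,
                        product_release_prob = 0,
                        cat_prob = c(E1 = 1, E2 = 0, E3 = 0, E4 = 0))
  m <- trajectory_matrix(run_simulation(p, 1, seed = 3, raw = TRUE))
  expect_equal(unname(m$values[2, "E1A"]), 1)
  expect_equal(unname(m$values[2, "E1S"]), 0)
})

test_that("an inflow of one molecule per step adds exactly one per step", {
  p <- metabolic_params(width = 5, height = 5,
                        initial_counts = c(S = 0),
                        bind_prob = 0, mode = "continuous",
                        inflow = 1, outflow = 0)
  m <- trajectory_matrix(run_simulation(p, 100, seed = 4, stride = 100))
  expect_equal(unname(m$values[2, "S"]), 100)
})

test_that("enzyme totals and batch mass balance are conserved exactly", {
  p <- tiny_met()
  traj <- run_simulation(p, 10000, seed = 5, raw = TRUE, stride = 100)
  cons <- metabolic_conserved(traj)
  for (e in c("E1", "E2", "E3", "E4")) {
    expect_equal(length(unique(cons[[e]])), 1)
  }
  expect_equal(length(unique(cons$metabolite_total)), 1)
})

test_that("batch runs deplete substrate monotonically in expectation", {
  p <- tiny_met()
  runs <- lapply(1:5, function(r) {
    trajectory_matrix(run_simulation(p, 4000, seed = 10 + r,
                                     stride = 400))$values[, "S"]
  })
  s_mean <- Reduce(`+`, runs) / length(runs)
  expect_true(all(diff(s_mean) <= 0))
})

test_that("only metabolites are subject to outflow", {
  p <- metabolic_params(width = 4, height = 4,
                        initial_counts = c(S = 50, E1 = 10),
                        bind_prob = 0, mode = "continuous",
                        inflow = 0, outflow = 0.05)
  m <- trajectory_matrix(run_simulation(p, 200, seed = 6, stride = 200,
                                        raw = TRUE))
  expect_equal(unname(m$values[2, "E1"]), 10)
  expect_lt(unname(m$values[2, "S"]), 10) # ~50 * 0.95^200
})

test_that("inflow control rejects rates outside [0, 1]", {
  expect_error(metabolic_params(inflow = 1.5), "\\[0, 1\\]")
  expect_error(with_inflow(metabolic_params(), 1.2), "\\[0, 1\\]")
})

test_that("metabolic dataset recipes follow the declared settings", {
  r <- dataset_recipes("metabolic")
  expect_equal(r$replicates, c(1L, 1L, 100L, 100L, 100L))
  expect_equal(r$inflow, c(0, 1, 0, 1, 0.2))
  p <- tiny_met()
  dss <- generate_datasets(p, labels = "II", seed = 1, steps = 200,
                           stride = 20)
  expect_equal(dss$II$replicates, 1)
  expect_equal(dss$II$control, c(Q = 1))
})
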