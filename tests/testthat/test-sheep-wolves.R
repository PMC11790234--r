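test_that("an animal whose energy is depleted is removed", {
  # a lone sheep with no grass and unit move cost must starve: initial energy
  # is at most 2 * gain, so it is gone after at most that many steps
  p <- sheep_wolves_params(width = 5, height = 5, initial_sheep = 1,
                           initial_wolves = 0, initial_grass = 0,
                           sheep_gain = 1, grass_regrowth = 10000,
                           sheep_reproduce = 0, wolf_reproduce = 0)
  m <- trajectory_matrix(run_simulation(p, 5, seed = 1))
  expect_equal(unname(m$values[6, "sheep"]), 0)
})

test_that("a wolf sharing a cell with a sheep eats it", {
  # 1 x 1 world: predator and prey are always co-located
  p <- sheep_wolves_params(width = 1, height = 1, initial_sheep = 1,
                           initial_wolves = 1, initial_grass = 0,
                           grass_regrowth = 10000,
                           sheep_reproduce = 0, wolf_reproduce = 0,
                           predation_prob = 1, move_cost = 0.01)
  m <- trajectory_matrix(run_simulation(p, 1, seed = 2))
  expect_equal(unname(m$values[2, "sheep"]), 0)
  expect_equal(unname(m$values[2, "wolves"]), 1)
})

test_that("reproduction splits the parent's energy with the offspring", {
  p <- sheep_wolves_params(width = 9, height = 9, initial_sheep = 1,
                           initial_wolves = 0, initial_grass = 0,
                           grass_regrowth = 10000,
                           sheep_reproduce = 1, move_cost = 0.01)
  m <- trajectory_matrix(run_simulation(p, 1, seed = 3))
  expect_equal(unname(m$values[2, "sheep"]), 2)
  # energy halves each generation while the move cost bites, so with
  # certainty of reproduction the lineage collapses within a few steps
  m2 <- trajectory_matrix(run_simulation(p, 40, seed = 3))
  expect_equal(unname(m2$values[41, "sheep"]), 0)
})

test_that("grazed grass regrows after the configured number of steps", {
  # one sheep on a fully grown 1 x 1 world: the cell is grazed at step 1 and
  # must be grown again exactly after `grass_regrowth` further steps
  p <- sheep_wolves_params(width = 1, height = 1, initial_sheep = 1,
                           initial_wolves = 0, initial_grass = 1,
                           grass_regrowth = 5, sheep_reproduce = 0,
                           move_cost = 0.01, sheep_gain = 100)
  m <- trajectory_matrix(run_simulation(p, 6, seed = 4))
  expect_equal(unname(m$values[, "grass"]), c(1, 0, 0, 0, 0, 1, 0))
})

test_that("control removal is reported per step", {
  p <- tiny_sw(initial_sheep = 300)
  sch <- control_schedule(removal = c(sheep = 0.1), start = 5)
  traj <- run_simulation(p, 10, seed = 5, schedule = sch)
  rem <- attr(traj, "removed")
  expect_equal(sum(rem[1:4, "sheep"]), 0)
  expect_gt(sum(rem[5:10, "sheep"]), 0)
})

test_that("the reference dataset recipes have the declared structure", {
  r <- dataset_recipes("sheep_wolves")
  expect_equal(r$label, c("I", "II", "III", "IV", "V"))
  expect_equal(r$control_value[3:5], c(0.02, 0.02, 0.015))
  expect_equal(r$control_var[3:5], c("grass", "sheep", "wolves"))
  expect_true(all(r$replicates == 100))
})

test_that("generate_datasets builds controlled and uncontrolled ensembles", {
  p <- tiny_sw()
  dss <- generate_datasets(p, labels = c("I", "V"), seed = 1, steps = 60,
                           replicates = 3, control_start = 30)
  expect_named(dss, c("I", "V"))
  expect_equal(dss$I$replicates, 3)
  expect_equal(dss$V$control, c(wolves = 0.015))
  expect_equal(dss$I$control, numeric())
  expect_error(generate_datasets(p, labels = "VI", seed = 1), "unknown dataset")
})
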