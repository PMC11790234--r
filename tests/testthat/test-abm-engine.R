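test_that("apply_removal handles the degenerate fractions exactly", {
  set.seed(1)
  expect_equal(apply_removal(100, 0)$survivors, 100)
  expect_equal(apply_removal(50, 1)$survivors, 0)
  expect_equal(apply_removal(50, 1)$removed, 50)
  expect_error(apply_removal(10, 1.2), "fraction")
  expect_error(apply_removal(10, -0.1), "fraction")
})

test_that("removal is binomial: mean over replicates matches the law", {
  set.seed(42)
  surv <- vapply(1:200, function(i) apply_removal(10000, 0.02)$survivors,
                 numeric(1))
  se <- sqrt(10000 * 0.02 * 0.98) / sqrt(200)
  expect_lt(abs(mean(surv) - 9800), 4 * se)
})

test_that("simulations are deterministic and honour steps = 0", {
  p <- tiny_sw()
  t0 <- run_simulation(p, 0, seed = 7)
  expect_equal(unique(t0$time), 0L)
  expect_equal(sum(t0$value[t0$variable == "sheep"]), 30)
  t1 <- run_simulation(p, 50, seed = 7)
  t2 <- run_simulation(p, 50, seed = 7)
  expect_identical(t1, t2)
  t3 <- run_simulation(p, 50, seed = 8)
  expect_false(identical(t1$value, t3$value))
  expect_error(run_simulation(p, -1, seed = 1), "non-negative")
})

test_that("counts stay non-negative and populations shrink without births", {
  p <- tiny_sw(sheep_reproduce = 0, wolf_reproduce = 0)
  m <- trajectory_matrix(run_simulation(p, 200, seed = 3))
  expect_true(all(m$values >= 0))
  animals <- m$values[, "sheep"] + m$values[, "wolves"]
  expect_true(all(diff(animals) <= 0))
})

test_that("aggregate_counts sums mapped subtypes and rejects unknown ones", {
  sm <- state_map(c("grass", "sheep", "wolves"))
  expect_equal(unname(aggregate_counts(c(grass = 0, sheep = 0, wolves = 0), sm)),
               c(0, 0, 0))
  expect_equal(aggregate_counts(c(grass = 12, sheep = 3, wolves = 2), sm),
               c(grass = 12, sheep = 3, wolves = 2))
  expect_error(aggregate_counts(c(sheep = 1, goats = 2), sm), "goats")

  # lumping: two subtypes onto one state preserves the mapped-agent total
  sm2 <- state_map("animals", map = c(sheep = "animals", wolves = "animals"),
                   unmapped = "grass")
  out <- aggregate_counts(c(sheep = 3, wolves = 2, grass = 99), sm2)
  expect_equal(unname(out), 5)
})

test_that("control schedules validate their rates", {
  expect_error(control_schedule(removal = c(sheep = 1.5)), "\\[0, 1\\]")
  expect_error(control_schedule(inflow = c(S = -1)), ">= 0")
  s <- control_schedule(removal = c(sheep = 0.02), start = 10)
  expect_equal(s$start, 10L)
})

test_that("scheduled removal converges to the scheduled fraction", {
  p <- tiny_sw(width = 31, height = 31, initial_sheep = 400, initial_wolves = 0,
               sheep_reproduce = 0, move_cost = 1e-6, initial_grass = 0)
  frac <- 0.05
  sch <- control_schedule(removal = c(sheep = frac), start = 1)
  # one step: expected survivors 400 * (1 - frac), binomial variance
  surv <- vapply(1:200, function(r) {
    m <- trajectory_matrix(run_simulation(p, 1, seed = 100 + r, schedule = sch))
    m$values[2, "sheep"]
  }, numeric(1))
  expected <- 400 * (1 - frac)
  se <- sqrt(400 * frac * (1 - frac) / 200)
  expect_lt(abs(mean(surv) - expected), 4 * se)
})
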