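test_that("power-law rates follow the canonical form", {
  expect_equal(eval_power_law(1, c(0, 0, 0), c(3, 9, 2)), 1)
  expect_equal(eval_power_law(2, c(1, 2), c(3, 2)), 24)
  expect_equal(eval_power_law(1, c(0), c(0)), 1) # 0^0 = 1
  expect_error(eval_power_law(1, c(-1), c(0)), class = "abmctrl_domain_error")
})

test_that("Taylor models vanish at the expansion point", {
  x0 <- c(10, 20, 30)
  t1 <- taylor_model(letters[1:3], x0, order = 1,
                     J = matrix(rnorm(9), 3, 3))
  expect_equal(rhs(t1, x0), rep(0, 3))
  H <- replicate(3, {
    A <- matrix(rnorm(9), 3, 3); A + t(A)
  }, simplify = FALSE)
  t2 <- taylor_model(letters[1:3], x0, order = 2, J = matrix(rnorm(9), 3, 3),
                     H = H)
  expect_equal(rhs(t2, x0), rep(0, 3))
})

test_that("a symmetric S-system cancels identically", {
  g <- matrix(runif(9, -1, 1), 3, 3)
  m <- ssystem_model(letters[1:3], alpha = c(1, 2, 3), beta = c(1, 2, 3),
                     g = g, h = g)
  for (i in 1:10) {
    x <- runif(3, 0.1, 10)
    expect_equal(rhs(m, x), rep(0, 3))
  }
})

test_that("the GMA rewrite of a mass-action model is algebraically exact", {
  mech <- sheep_wolves_mechanistic(k = lv_k)
  g <- as_gma(mech)
  set.seed(11)
  for (i in 1:100) {
    x <- runif(3, 1e-2, 1e4)
    a <- rhs(mech, x)
    b <- rhs(g, x)
    expect_lt(max(abs(a - b) / pmax(abs(a), 1e-12)), 1e-10)
  }
})

test_that("a quadratic Taylor with zero Hessians equals the linear one", {
  x0 <- c(5, 7)
  J <- matrix(c(-1, 2, 0.5, -3), 2, 2)
  t1 <- taylor_model(c("a", "b"), x0, order = 1, J = J)
  t2 <- taylor_model(c("a", "b"), x0, order = 2, J = J)
  set.seed(12)
  for (i in 1:20) {
    x <- runif(2, 0, 20)
    expect_equal(rhs(t1, x), rhs(t2, x))
  }
})

test_that("parameter counts match the closed-form expressions", {
  for (n in 1:10) {
    expect_equal(count_parameters("linear", n), n^2)
    expect_equal(count_parameters("quadratic", n), (3 * n^2 + n^3) / 2)
    expect_equal(count_parameters("ssystem", n), 2 * (n + n^2))
    expect_equal(count_parameters("gma", n, m = 7), 7 * (1 + n))
  }
  expect_equal(count_parameters("gma", 3, 7), 28)
  expect_error(count_parameters("spline", 3), "unknown")
  expect_error(count_parameters("gma", 3), "process count")
})

test_that("packing and unpacking parameters is a bijection for all families", {
  set.seed(13)
  models <- list(
    sheep_wolves_gma(),
    ssystem_model(letters[1:3]),
    taylor_model(letters[1:3], c(1, 2, 3), order = 1),
    taylor_model(letters[1:3], c(1, 2, 3), order = 2),
    sheep_wolves_mechanistic(),
    metabolic_mechanistic()
  )
  for (m in models) {
    p <- surrogate_params(m)
    p2 <- p * runif(length(p), 0.5, 1.5) + 1e-6
    m2 <- set_params(m, p2)
    expect_equal(unname(surrogate_params(m2)), unname(p2))
    # a round trip through the compiled right-hand side agrees with R's
    x <- runif(m$n, 1, 50)
    if (inherits(m2, "taylor_surrogate")) {
      # Hessians must stay symmetric after unpacking
      if (m2$order == 2) {
        for (Hi in m2$H) expect_equal(Hi, t(Hi))
      }
    }
    expect_true(all(is.finite(rhs(m2, x))))
  }
})

test_that("expected parameter-vector lengths match count_parameters", {
  expect_length(surrogate_params(sheep_wolves_gma()), 28)
  expect_length(surrogate_params(ssystem_model(letters[1:3])), 24)
  expect_length(surrogate_params(taylor_model(letters[1:3], 1:3, order = 2)),
                27)
  expect_length(surrogate_params(taylor_model(letters[1:3], 1:3, order = 1)),
                9)
})

test_that("control terms add linearly and vanish at zero parameters", {
  mech <- add_control(sheep_wolves_mechanistic(k = lv_k),
                      control_removal(c(sheep = 0, wolves = 0)))
  x <- c(800, 100, 20)
  expect_equal(rhs(mech, x, u = c(sheep = 0, wolves = 0)),
               rhs(sheep_wolves_mechanistic(k = lv_k), x))
  # kappa2 = 0.01 on 100 sheep lowers the sheep derivative by exactly 1
  base <- rhs(mech, x, u = c(sheep = 0, wolves = 0))
  ctrl <- rhs(mech, x, u = c(sheep = 0.01, wolves = 0))
  expect_equal(base[2] - ctrl[2], 1)
  expect_equal(base[c(1, 3)], ctrl[c(1, 3)])
})

test_that("inflow control feeds only the substrate coordinate", {
  met <- metabolic_mechanistic(continuous = TRUE, outflow = 0)
  x <- c(10, 5, 3, 2, 2)
  d0 <- rhs(met, x, u = c(Q = 0))
  d1 <- rhs(met, x, u = c(Q = 0.7))
  expect_equal(d1 - d0, c(0.7, 0, 0, 0, 0))
})

test_that("dimension mismatches in control terms are caught", {
  expect_error(add_control(sheep_wolves_mechanistic(),
                           control_removal(c(lynx = 0.1))), "unknown state")
})

test_that("a zero right-hand side integrates to a constant trajectory", {
  m <- taylor_model(c("a", "b"), c(1, 2), order = 1, J = matrix(0, 2, 2))
  tr <- integrate_surrogate(m, c(5, 6), 0:10)
  expect_true(all(tr$a == 5))
  expect_true(all(tr$b == 6))
})

test_that("linear decay integrates to the closed-form exponential", {
  m <- taylor_model("x", 0, order = 1, J = matrix(-1, 1, 1))
  tr <- integrate_surrogate(m, 5, seq(0, 6, by = 0.25))
  expect_lt(max(abs(tr$x - 5 * exp(-tr$time)) / (5 * exp(-tr$time))), 1e-6)
})

test_that("a stiff system falls back or raises a structured error", {
  # two uncoupled power-law relaxations with a 1e6 rate-scale ratio plus a
  # finite-time blow-up term: the non-stiff attempt cannot finish
  m <- ssystem_model(c("fast", "slow"),
                     alpha = c(1e6, 1e-9), beta = c(1e6, 1e-9),
                     g = matrix(0, 2, 2),
                     h = rbind(c(1, 0), c(-3, 0)))
  out <- tryCatch(
    integrate_surrogate(m, c(1e-4, 1), seq(0, 50, by = 0.5)),
    abmctrl_integration_error = function(e) e)
  if (inherits(out, "abmctrl_integration_error")) {
    expect_true(is.numeric(out$t_reached))
    expect_gte(out$t_reached, 0)
  } else {
    expect_true(all(is.finite(as.matrix(out[-1]))))
  }
})

test_that("integration failure reports the reachable sub-interval", {
  # dx/dt = x^2 from x(0) = 1 blows up at t = 1
  m <- gma_model("x", matrix(1, 1, 1), alpha = 1, orders = matrix(2, 1, 1))
  err <- tryCatch(integrate_surrogate(m, 1, seq(0, 5, by = 0.05)),
                  abmctrl_integration_error = function(e) e)
  expect_s3_class(err, "abmctrl_integration_error")
  expect_lt(err$t_reached, 1.05)
  expect_gt(err$t_reached, 0.5)
})

test_that("find_roots recovers known root sets", {
  # logistic: roots at 0 and k1/k2
  m <- logistic_surrogate(k1 = 2, k2 = 1)
  roots <- find_roots(m, 0, 10)
  expect_equal(length(roots), 2)
  expect_equal(roots[[1]], 0, tolerance = 1e-6)
  expect_equal(roots[[2]], 2, tolerance = 1e-6)

  # nonsingular linear Taylor: only x0
  t1 <- taylor_model(c("a", "b"), c(3, 4), order = 1,
                     J = matrix(c(-1, 0.2, 0.1, -2), 2, 2))
  roots <- find_roots(t1, c(0, 0), c(10, 10))
  expect_equal(length(roots), 1)
  expect_equal(roots[[1]], c(3, 4), tolerance = 1e-5)

  # crafted quadratic with a second root inside the box:
  # dx/dt = (x - 1)(x - 3) = x^2 - 4x + 3 -> J = -2 at x0 = 1 (f'(1) = -2),
  # H = 2: f(x) = -2 (x - 1) + (x - 1)^2 has roots 1 and 3
  t2 <- taylor_model("x", 1, order = 2, J = matrix(-2, 1, 1),
                     H = list(matrix(2, 1, 1)))
  roots <- find_roots(t2, 0, 10)
  expect_equal(length(roots), 2)
  expect_equal(roots[[1]], 1, tolerance = 1e-5)
  expect_equal(roots[[2]], 3, tolerance = 1e-5)
})

test_that("Michaelis-Menten terms half-saturate at Km", {
  tm <- process_term("michaelis_menten", vmax = 10, km = 3, substrate = 1)
  m <- mechanistic_model("s", matrix(-1, 1, 1), list(tm))
  expect_equal(rhs(m, 3), -5)
})
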