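linear_decay <- function(t, u) -u

test_that("linear Caputo decay matches the Mittag-Leffler solution", {
  # D^0.5 u = -u, u(0) = 1: u(1) = E_0.5(-1) = e * erfc(1)
  tr <- caputo_integrate(linear_decay, 1, 0.5,
                         solver_settings(h = 1 / 2048, t_end = 1,
                                         clamp = FALSE))
  expect_equal(tail(tr$states[, 1], 1), 0.427584, tolerance = 2e-4)
  # constant forcing: u(t) = t^theta / Gamma(theta + 1)
  tr2 <- caputo_integrate(function(t, u) 1, 0, 0.5,
                          solver_settings(h = 1 / 2048, t_end = 1,
                                          clamp = FALSE))
  expect_equal(tail(tr2$states[, 1], 1), 1 / gamma(1.5), tolerance = 1e-4)
  # classical limit
  tr3 <- caputo_integrate(linear_decay, 1, 1,
                          solver_settings(h = 1e-3, t_end = 1, clamp = FALSE))
  expect_equal(tail(tr3$states[, 1], 1), exp(-1), tolerance = 1e-6)
})

test_that("empirical convergence order reaches one across orders", {
  for (th in c(0.5, 0.78, 0.9)) {
    err <- vapply(c(1 / 512, 1 / 1024), function(h) {
      tr <- caputo_integrate(linear_decay, 1, th,
                             solver_settings(h = h, t_end = 1, clamp = FALSE))
      abs(tail(tr$states[, 1], 1) - mittag_leffler(th, -1))
    }, numeric(1))
    expect_gte(log2(err[1] / err[2]), 1.0)
  }
})

test_that("Mittag-Leffler series matches closed forms", {
  expect_equal(mittag_leffler(1, -1), exp(-1), tolerance = 1e-12)
  expect_equal(mittag_leffler(1, 2), exp(2), tolerance = 1e-12)
  if (requireNamespace("pracma", quietly = TRUE))
    expect_equal(mittag_leffler(0.5, -1), exp(1) * pracma::erfc(1),
                 tolerance = 1e-10)
  expect_equal(mittag_leffler(0.5, -1), 0.427584, tolerance = 1e-6)
  for (th in c(0.3, 0.6, 1))
    expect_equal(mittag_leffler(th, 0, beta = 2), 1, tolerance = 1e-15)
  # two-parameter case: E_{1,2}(z) = (e^z - 1)/z
  expect_equal(mittag_leffler(1, 1.5, beta = 2), (exp(1.5) - 1) / 1.5,
               tolerance = 1e-12)
  expect_error(mittag_leffler(0.5, 100), "z")
  expect_error(mittag_leffler(1.5, 1), "theta")
})

test_that("trajectories keep the grid contract and initial condition", {
  tr <- simulate_trajectory(pA, 0.78,
                            settings = solver_settings(h = 0.02, t_end = 20))
  expect_equal(tr$states[1, ], c(u1 = 0.3, u2 = 0.3))
  expect_lt(max(abs(diff(tr$t) - 0.02)), 1e-12)
  expect_true(all(tr$states >= 0))
  expect_identical(tr$clamped_count, 0L)
  expect_error(caputo_integrate(linear_decay, 1, 0.78,
                                solver_settings(h = 10, t_end = 1)),
               "grid")
})

test_that("a trajectory started at the coexistence equilibrium stays there", {
  eq <- interior_equilibrium(pA)
  for (th in c(0.5, 1)) {
    tr <- simulate_trajectory(pA, th, u0 = c(eq$u1, eq$u2),
                              settings = solver_settings(h = 0.1,
                                                         t_end = 100))
    expect_lt(max(abs(sweep(tr$states, 2, c(eq$u1, eq$u2)))), 1e-6)
  }
})

test_that("oscillation statistics recover a constructed signal", {
  t <- seq(0, 200, by = 0.05)
  fake <- list(t = t,
               states = cbind(0.4 + 0.3 * sin(2 * pi * t / 17),
                              0.2 + 0.1 * cos(2 * pi * t / 17)))
  st <- oscillation_stats(fake, tail_fraction = 0.5)
  expect_equal(unname(st$amplitude[1]), 0.3, tolerance = 0.02 * 0.3)
  expect_equal(unname(st$amplitude[2]), 0.1, tolerance = 0.02 * 0.1)
  expect_equal(st$period, 17, tolerance = 0.02 * 17)
  expect_identical(st$label, "oscillatory")

  eq <- interior_equilibrium(pA)
  flat <- list(t = t, states = cbind(rep(eq$u1, length(t)),
                                     rep(eq$u2, length(t))))
  stf <- oscillation_stats(flat)
  expect_identical(stf$label, "damped/steady")
  expect_equal(max(stf$amplitude), 0)
  expect_error(oscillation_stats(list(t = 1:5, states = cbind(1:5, 1:5))),
               "short")
})

test_that("crossing the critical order switches damped decay to oscillation", {
  p <- generate_scenarios(1, "hopf_capable", seed = 77,
                          ranges = scenario_ranges())[[1]]
  th0 <- attr(p, "certificate")$theta0
  eq <- interior_equilibrium(p)
  u0 <- c(eq$u1 * 1.05, eq$u2 * 1.05)
  s <- solver_settings(h = 0.05, t_end = 400)
  below <- oscillation_stats(simulate_trajectory(p, max(th0 - 0.05, 0.01),
                                                 u0, s))
  above <- oscillation_stats(simulate_trajectory(p, min(th0 + 0.05, 1),
                                                 u0, s))
  expect_gt(max(above$amplitude), 10 * max(below$amplitude))
})
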