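test_that("boundary equilibria solve the prey nullcline quadratic", {
  bnd <- boundary_equilibria(pA)
  expect_length(bnd, 1L)
  expect_equal(bnd[[1]]$u1, (0.7 + sqrt(0.89)) / 2, tolerance = 1e-12)
  expect_equal(bnd[[1]]$u2, 0)
  expect_lt(max(abs(pp_rhs(pA, c(bnd[[1]]$u1, 0)))), 1e-9)
  # the rejected second quadratic root is negative
  expect_lt((0.7 - sqrt(0.89)) / 2, 0)
})

test_that("vanishing harvest leaves the carrying capacity as boundary root", {
  p <- model_params(gamma1 = 1, gamma2 = 1, gamma3 = 0.2, gamma4 = 0.25,
                    kappa = 1.7, sigma = 0.25, rho1 = 1e-12, rho2 = 1,
                    rho3 = 0.3, rho4 = 1)
  roots <- vapply(boundary_equilibria(p), function(e) e$u1, numeric(1))
  expect_true(any(abs(roots - 1.7) < 1e-9))
})

test_that("kappa = 1 boundary roots match the printed closed forms", {
  set.seed(41)
  for (i in 1:25) {
    p <- model_params(gamma1 = runif(1, 0.5, 1.5), gamma2 = runif(1, 0.5, 1.5),
                      gamma3 = runif(1, 0.05, 0.5), gamma4 = runif(1, 0.1, 0.5),
                      kappa = 1, sigma = runif(1, 0.2, 0.9),
                      rho1 = runif(1, 0.01, 0.3), rho2 = runif(1, 0.5, 1.5),
                      rho3 = runif(1, 0.1, 0.5), rho4 = runif(1, 0.5, 1.5))
    printed <- boundary_roots_printed(p)
    printed <- sort(printed[printed > 0])
    found <- sort(vapply(boundary_equilibria(p), function(e) e$u1, numeric(1)))
    expect_equal(found, printed, tolerance = 1e-12)
  }
})

test_that("interior equilibrium matches the worked examples to 4 decimals", {
  eqA <- interior_equilibrium(pA)
  expect_identical(round(c(eqA$u1, eqA$u2), 4), c(0.4096, 0.1580))
  expect_equal(eqA$u1, 0.8^4, tolerance = 1e-14)
  eqB <- interior_equilibrium(fixture_params("exampleB"))
  expect_identical(round(c(eqB$u1, eqB$u2), 4), c(0.4168, 0.1465))
  expect_equal(eqB$u1, 0.8^(1 / 0.255), tolerance = 1e-14)
  # the face-value harvesting constants yield a different predator level,
  # documenting the source inconsistency
  eqL <- interior_equilibrium(fixture_params("exampleB-literal"))
  expect_identical(round(eqL$u2, 4), 0.1534)
})

test_that("balanced gain puts the interior prey level at one", {
  p <- model_params(gamma1 = 1, gamma2 = 0.8, gamma3 = 0.2, gamma4 = 0.25,
                    kappa = 3, sigma = 0.37, rho1 = 0.05, rho2 = 1,
                    rho3 = 0.3, rho4 = 1)
  p$gamma3 <- p$gamma2 * p$gamma4  # gamma3 = gain => u1* = 1 for any sigma
  expect_equal(interior_equilibrium(p)$u1, 1, tolerance = 1e-14)
})

test_that("closed-form interior prey level agrees with a bracketing solve", {
  sets <- c(generate_scenarios(60, "stable_focus", seed = 101),
            generate_scenarios(40, "hopf_capable", seed = 102))
  for (p in sets) {
    eq <- interior_equilibrium(p)
    expect_equal(eq$u1, interior_u1_bracketed(p), tolerance = 1e-10)
    expect_lt(max(abs(pp_rhs(p, c(eq$u1, eq$u2)))), 1e-9)
  }
})

test_that("existence report classifies branch and filters admissible roots", {
  ex <- existence_report(pA)
  expect_true(ex$has_zero)
  expect_true(ex$has_interior)
  expect_equal(ex$discriminant, 0.89, tolerance = 1e-12)
  expect_equal(ex$saturation_ratio, 0.3, tolerance = 1e-12)
  expect_match(ex$branch, "two boundary roots")
  expect_identical(ex$boundary_count, 1L)

  # heavy harvest: negative discriminant, no boundary equilibria
  ph <- model_params(gamma1 = 0.5, gamma2 = 1, gamma3 = 0.2, gamma4 = 0.25,
                     kappa = 1, sigma = 0.25, rho1 = 0.4, rho2 = 1,
                     rho3 = 0.3, rho4 = 1)
  exh <- existence_report(ph)
  expect_lt(exh$discriminant, 0)
  expect_identical(exh$boundary_count, 0L)
  expect_length(boundary_equilibria(ph), 0L)

  # constructed tangency: discriminant exactly zero, double root
  s <- 0.3
  rho1 <- ((1 - s)^2 / 4 + s) * 1 * 1 * 1  # gamma1 = rho4 = kappa = rho2 = 1
  pt <- model_params(gamma1 = 1, gamma2 = 1, gamma3 = 0.2, gamma4 = 0.25,
                     kappa = 1, sigma = 0.25, rho1 = rho1, rho2 = 1,
                     rho3 = s, rho4 = 1)
  ext <- existence_report(pt)
  expect_equal(ext$discriminant, 0, tolerance = 1e-14)
  expect_match(ext$branch, "double")
  expect_identical(ext$boundary_count, 1L)
  expect_equal(boundary_equilibria(pt)[[1]]$u1, (1 - s) / 2, tolerance = 1e-9)
})

test_that("all_equilibria starts at extinction and annihilates the field", {
  eqs <- all_equilibria(pA)
  expect_identical(eqs[[1]]$klass, "zero")
  for (eq in eqs) {
    expect_true(eq$admissible)
    expect_lt(max(abs(pp_rhs(pA, c(eq$u1, eq$u2)))), 1e-9)
  }
  expect_setequal(vapply(eqs, function(e) e$klass, character(1)),
                  c("zero", "boundary", "interior"))
})
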