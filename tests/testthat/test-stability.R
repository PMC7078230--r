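test_that("Jacobian matches the explicit limit matrix at extinction", {
  J <- pp_jacobian(pA, c(0, 0))
  expect_equal(J$a11, 1 - 0.2 / 0.3, tolerance = 1e-14)
  expect_equal(J$a12, 0)
  expect_equal(J$a21, 0)
  expect_equal(J$a22, -0.2)
  expect_error(pp_jacobian(pA, c(0, 0.5)), "singular")
})

test_that("Jacobian at the coexistence equilibrium has the proved structure", {
  eq <- interior_equilibrium(pA)
  J <- pp_jacobian(pA, c(eq$u1, eq$u2))
  expect_equal(J$a22, 0, tolerance = 1e-14)
  expect_equal(J$alpha, -0.015497, tolerance = 1e-4)
  expect_equal(J$beta, 0.015428, tolerance = 1e-4)
  # determinant identity beta = sigma * gamma2^2 * gamma4 * u1^(2s-1) * u2
  expect_equal(J$beta,
               pA$sigma * pA$gamma2^2 * pA$gamma4 *
                 eq$u1^(2 * pA$sigma - 1) * eq$u2,
               tolerance = 1e-12)
})

test_that("Matignon classification handles the canonical cases", {
  for (th in c(0.3, 0.8, 1))
    expect_identical(matignon_classify(jacobian_eval(-1, 0, 0, -1), th)$label,
                     "asymptotically_stable")
  # pure rotation: |arg| = pi/2 strictly above theta*pi/2 for theta < 1
  expect_identical(matignon_classify(jacobian_eval(0, 1, -1, 0), 0.9)$label,
                   "asymptotically_stable")
  expect_identical(matignon_classify(jacobian_eval(1, 0, 0, -1), 0.5)$label,
                   "saddle")
  expect_identical(matignon_classify(jacobian_eval(1, 0, 0, 2), 0.5)$label,
                   "unstable")
  # zero eigenvalue and on-threshold pair are inconclusive
  expect_identical(matignon_classify(jacobian_eval(1, 0, 0, 0), 0.5)$label,
                   "inconclusive")
  expect_identical(matignon_classify(jacobian_eval(0, 1, -1, 0), 1)$label,
                   "inconclusive")
})

test_that("extinction-state classification follows the harvest-growth balance", {
  expect_identical(classify_zero_eq(pA, 0.78)$label, "saddle")
  over <- model_params(gamma1 = 1, gamma2 = 1, gamma3 = 0.2, gamma4 = 0.25,
                       kappa = 1, sigma = 0.25, rho1 = 1, rho2 = 1,
                       rho3 = 0.5, rho4 = 1)
  expect_identical(classify_zero_eq(over, 0.78)$label, "asymptotically_stable")
  marginal <- model_params(gamma1 = 2, gamma2 = 1, gamma3 = 0.2,
                           gamma4 = 0.25, kappa = 1, sigma = 0.25,
                           rho1 = 1, rho2 = 1, rho3 = 0.5, rho4 = 1)
  expect_identical(classify_zero_eq(marginal, 0.78)$label, "inconclusive")
  # wrapper equals the Matignon path on the same Jacobian
  expect_identical(classify_zero_eq(pA, 0.5)$label,
                   matignon_classify(pp_jacobian(pA, c(0, 0)), 0.5)$label)
})

test_that("boundary-state classification equals Matignon on the triangular Jacobian", {
  bnd <- boundary_equilibria(pA)[[1]]
  rep <- classify_boundary_eq(pA, bnd, 0.78)
  # predator invasion rate at this root is positive, prey direction stable
  lam2 <- -pA$gamma3 + pA$gamma2 * pA$gamma4 * bnd$u1^pA$sigma
  expect_gt(lam2, 0)
  expect_identical(rep$label, "saddle")
  expect_identical(rep$label,
                   matignon_classify(pp_jacobian(pA, c(bnd$u1, 0)),
                                     0.78)$label)
  expect_error(classify_boundary_eq(pA, interior_equilibrium(pA), 0.78),
               "boundary")
})

test_that("coexistence classification agrees with Matignon across regimes", {
  expect_identical(classify_interior_eq(pA, 0.78)$label,
                   "asymptotically_stable")
  hopfset <- generate_scenarios(5, "hopf_capable", seed = 7)
  for (p in hopfset) {
    th0 <- attr(p, "certificate")$theta0
    expect_identical(classify_interior_eq(p, th0 - 0.01)$label,
                     "asymptotically_stable")
    expect_identical(classify_interior_eq(p, th0 + 0.01)$label, "unstable")
  }
  for (p in generate_scenarios(5, "stable_node", seed = 8))
    expect_identical(classify_interior_eq(p, 0.9)$label,
                     "asymptotically_stable")
  expect_error(classify_interior_eq(
    generate_scenarios(1, "no_interior", seed = 9)[[1]], 0.5),
    "interior")
})

test_that("trace/determinant case analysis matches eigenvalue arguments", {
  set.seed(123)
  mismatches <- 0L
  for (i in 1:300) {
    J <- random_jacobian()
    th <- runif(1, 0.05, 0.99)
    lab_thm <- fracprey:::interior_case_label(J$alpha, J$beta, th)$label
    lab_mat <- matignon_classify(J, th)$label
    if (lab_thm != "inconclusive" && lab_mat != "inconclusive" &&
        lab_thm != lab_mat)
      mismatches <- mismatches + 1L
  }
  expect_identical(mismatches, 0L)
})

test_that("the coexistence equilibrium is never a saddle", {
  sets <- c(generate_scenarios(30, "stable_focus", seed = 31),
            generate_scenarios(30, "hopf_capable", seed = 32),
            generate_scenarios(30, "stable_node", seed = 33))
  for (p in sets) {
    cert <- attr(p, "certificate")
    expect_gt(cert$beta, 0)
    for (th in c(0.3, 0.7, 0.95))
      expect_false(classify_interior_eq(p, th)$label == "saddle")
  }
})
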