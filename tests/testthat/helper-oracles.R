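# Shared oracles and generators for the test suite.

# Baseline worked-example parameter set, used across files.
pA <- fixture_params("exampleA")

# Printed closed-form boundary roots, valid at kappa = 1; regression oracle
# for the first-principles quadratic.
boundary_roots_printed <- function(p) {
  s <- p$rho2 * p$rho3 / (p$rho4 * p$kappa)
  disc <- (1 - s)^2 - 4 * (p$rho1 * p$rho2 / (p$gamma1 * p$rho4 * p$kappa) - s)
  if (disc < 0) return(numeric(0))
  ((1 - s) + c(1, -1) * sqrt(disc)) / 2
}

# Independent 1-D root solve of the interior predator nullcline
# -gamma3 + gamma2*gamma4*u1^sigma = 0 by bracketing bisection.
interior_u1_bracketed <- function(p) {
  g <- function(u1) -p$gamma3 + p$gamma2 * p$gamma4 * u1^p$sigma
  stats::uniroot(g, lower = 1e-12, upper = 1e6, tol = 1e-14)$root
}

# Random 2x2 Jacobian with entries in [-2, 2].
random_jacobian <- function() {
  e <- stats::runif(4, -2, 2)
  jacobian_eval(e[1], e[2], e[3], e[4])
}

# A Jacobian with prescribed trace and determinant (companion form).
jac_from_trace_det <- function(alpha, beta) {
  jacobian_eval(0, 1, -beta, alpha)
}
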