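#' Jacobian of the vector field
#'
#' Evaluates the Jacobian matrix at a state with \eqn{u_1 > 0}, or at the
#' extinction state \eqn{(0,0)} where the limit matrix
#' \eqn{\mathrm{diag}(\gamma_1 - \rho_1/\rho_3,\; -\gamma_3)} applies.
#' For \eqn{u_1 > 0} the entries are
#' \deqn{a_{11} = \gamma_1 - \frac{2\gamma_1 u_1}{\kappa}
#'   - \sigma\gamma_2 u_1^{\sigma-1} u_2
#'   - \frac{\rho_1\rho_2^2\rho_3}{(\rho_2\rho_3+\rho_4 u_1)^2}, \quad
#'   a_{12} = -\gamma_2 u_1^\sigma,}
#' \deqn{a_{21} = \sigma\gamma_2\gamma_4 u_1^{\sigma-1} u_2, \quad
#'   a_{22} = -\gamma_3 + \gamma_2\gamma_4 u_1^\sigma.}
#' At \eqn{u_1 = 0} with \eqn{u_2 > 0} the off-diagonal factor
#' \eqn{u_1^{\sigma-1}} is singular for \eqn{\sigma < 1} and the call is an
#' error; no equilibrium of the model sits there.
#'
#' @param params A [model_params()] object.
#' @param state Numeric `c(u1, u2)` with `u1 > 0`, or exactly `c(0, 0)`.
#' @return A `jacobian_eval` object (see [jacobian_eval()]).
#' @examples
#' p <- fixture_params("exampleA")
#' pp_jacobian(p, c(0, 0))
#' eq <- interior_equilibrium(p)
#' pp_jacobian(p, c(eq$u1, eq$u2))
#' @export
pp_jacobian <- function(params, state) {
  stopifnot(inherits(params, "model_params"))
  u <- check_state(state)
  u1 <- u[1L]; u2 <- u[2L]
  if (u1 == 0) {
    if (u2 > 0)
      stop("Jacobian undefined at u1 = 0 with u2 > 0 (u1^(sigma-1) singular)",
           call. = FALSE)
    return(jacobian_eval(params$gamma1 - params$rho1 / params$rho3, 0,
                         0, -params$gamma3))
  }
  s <- params$sigma
  den <- params$rho2 * params$rho3 + params$rho4 * u1
  a11 <- params$gamma1 - 2 * params$gamma1 * u1 / params$kappa -
    s * params$gamma2 * u1^(s - 1) * u2 -
    params$rho1 * params$rho2^2 * params$rho3 / den^2
  a12 <- -params$gamma2 * u1^s
  a21 <- s * params$gamma2 * params$gamma4 * u1^(s - 1) * u2
  a22 <- -params$gamma3 + params$gamma2 * params$gamma4 * u1^s
  jacobian_eval(a11, a12, a21, a22)
}

#' Jacobian evaluation container
#'
#' Holds the four entries of a 2x2 Jacobian; the trace `alpha` and
#' determinant `beta` are always derived from the entries, never cached.
#'
#' @param a11,a12,a21,a22 Finite matrix entries.
#' @return Object of class `jacobian_eval` with fields `a11..a22`, `alpha`
#'   (trace) and `beta` (determinant).
#' @export
jacobian_eval <- function(a11, a12, a21, a22) {
  v <- c(a11, a12, a21, a22)
  if (!is.numeric(v) || length(v) != 4L || any(!is.finite(v)))
    stop("Jacobian entries must be finite numbers", call. = FALSE)
  structure(list(a11 = a11, a12 = a12, a21 = a21, a22 = a22,
                 alpha = a11 + a22, beta = a11 * a22 - a12 * a21),
            class = "jacobian_eval")
}

#' @export
print.jacobian_eval <- function(x, ...) {
  cat(sprintf("Jacobian [%.6g %.6g; %.6g %.6g]  trace = %.6g, det = %.6g\n",
              x$a11, x$a12, x$a21, x$a22, x$alpha, x$beta))
  invisible(x)
}

# Eigenvalues of a 2x2 from the characteristic quadratic (exact closed form).
jac_eigen <- function(J) {
  disc <- J$alpha^2 - 4 * J$beta
  if (disc >= 0) {
    r <- sqrt(disc)
    complex(real = c(J$alpha + r, J$alpha - r) / 2, imaginary = c(0, 0))
  } else {
    r <- sqrt(-disc)
    complex(real = c(J$alpha, J$alpha) / 2, imaginary = c(r, -r) / 2)
  }
}

new_stability_report <- function(eigenvalues, theta, label, theorem_branch) {
  structure(list(eigenvalues = eigenvalues,
                 args = Arg(eigenvalues),
                 threshold = theta * pi / 2,
                 theta = theta,
                 label = label,
                 theorem_branch = theorem_branch),
            class = "pp_stability")
}

#' @export
print.pp_stability <- function(x, ...) {
  ev <- paste(sprintf("%.6g%+.6gi", Re(x$eigenvalues), Im(x$eigenvalues)),
              collapse = ", ")
  cat(sprintf("Matignon classification at theta = %g: %s\n", x$theta, x$label))
  cat(sprintf("  eigenvalues: %s\n", ev))
  cat(sprintf("  |arg|: %s  vs threshold theta*pi/2 = %.6g\n",
              paste(sprintf("%.6g", abs(x$args)), collapse = ", "),
              x$threshold))
  if (!is.null(x$theorem_branch) && nzchar(x$theorem_branch))
    cat(sprintf("  branch: %s\n", x$theorem_branch))
  invisible(x)
}

#' Matignon stability classification
#'
#' Classifies an equilibrium of a two-dimensional Caputo system of order
#' `theta` from the eigenvalues of its Jacobian: it is locally
#' asymptotically stable iff every eigenvalue satisfies
#' \eqn{|\arg\lambda| > \theta\pi/2}, unstable if both violate it, and a
#' saddle if exactly one does.  Eigenvalues are computed from the
#' closed-form root formula \eqn{(\alpha \pm \sqrt{\alpha^2-4\beta})/2} of
#' the characteristic quadratic for exact reproducibility.  An eigenvalue
#' argument within `tol` of the threshold, or an eigenvalue within
#' `1e-12` of zero, yields `"inconclusive"` (the criterion is undefined at
#' the origin and the marginal case would require a multiplicity analysis).
#'
#' @param J A [jacobian_eval()] object.
#' @param theta Fractional order in (0, 1].
#' @param tol Absolute tolerance on `|arg| - theta*pi/2` (default `1e-10`).
#' @return A `pp_stability` report with eigenvalues, principal arguments,
#'   threshold and a label in `asymptotically_stable`, `unstable`,
#'   `saddle`, `inconclusive`.
#' @examples
#' matignon_classify(jacobian_eval(-1, 0, 0, -1), 0.9)
#' matignon_classify(jacobian_eval(1, 0, 0, -1), 0.5)   # saddle
#' @export
matignon_classify <- function(J, theta, tol = 1e-10) {
  stopifnot(inherits(J, "jacobian_eval"))
  theta <- check_theta(theta)
  ev <- jac_eigen(J)
  thr <- theta * pi / 2
  if (any(Mod(ev) < 1e-12))
    return(new_stability_report(ev, theta, "inconclusive",
                                "zero eigenvalue: criterion undefined"))
  rel <- abs(Arg(ev)) - thr
  if (any(abs(rel) <= tol))
    return(new_stability_report(ev, theta, "inconclusive",
                                "eigenvalue argument on the threshold ray"))
  label <- if (all(rel > 0)) "asymptotically_stable"
  else if (all(rel < 0)) "unstable"
  else "saddle"
  new_stability_report(ev, theta, label, "")
}

#' Stability of the extinction equilibrium
#'
#' The Jacobian at \eqn{(0,0)} is diagonal with eigenvalues
#' \eqn{\gamma_1 - \rho_1/\rho_3} and \eqn{-\gamma_3}: extinction is
#' asymptotically stable when harvesting pressure exceeds prey growth
#' (\eqn{\gamma_1 < \rho_1/\rho_3}) and a saddle when it does not;
#' equality is inconclusive.  Always identical to [matignon_classify()]
#' on the Jacobian there.
#'
#' @param params A [model_params()] object.
#' @param theta Fractional order in (0, 1].
#' @return A `pp_stability` report.
#' @export
classify_zero_eq <- function(params, theta) {
  rep <- matignon_classify(pp_jacobian(params, c(0, 0)), theta)
  lam1 <- params$gamma1 - params$rho1 / params$rho3
  rep$theorem_branch <- if (lam1 < 0)
    "extinction: gamma1 - rho1/rho3 < 0 (stable)"
  else if (lam1 > 0) "extinction: gamma1 - rho1/rho3 > 0 (saddle)"
  else "extinction: gamma1 = rho1/rho3 (marginal)"
  rep
}

#' Stability of a predator-free boundary equilibrium
#'
#' The Jacobian at \eqn{(u_1, 0)} is upper triangular, with eigenvalues
#' \eqn{\lambda_1 = a_{11}} and
#' \eqn{\lambda_2 = -\gamma_3 + \gamma_2\gamma_4 u_1^\sigma} (the predator
#' invasion rate).  Classification follows the Matignon criterion: stable
#' only when both diagonal rates are negative, a saddle when they differ
#' in sign, unstable when both are positive.  (Published case analyses for
#' this model sometimes pair stability with \eqn{\lambda_2 > 0}; a
#' positive real eigenvalue is never Matignon-stable, so the criterion is
#' applied directly and the sign pattern recorded in `theorem_branch`.)
#'
#' @param params A [model_params()] object.
#' @param eq A boundary `pp_equilibrium` from [boundary_equilibria()].
#' @param theta Fractional order in (0, 1].
#' @return A `pp_stability` report.
#' @export
classify_boundary_eq <- function(params, eq, theta) {
  stopifnot(inherits(eq, "pp_equilibrium"))
  if (eq$klass != "boundary")
    stop("classify_boundary_eq() requires a boundary equilibrium, got '",
         eq$klass, "'", call. = FALSE)
  J <- pp_jacobian(params, c(eq$u1, eq$u2))
  rep <- matignon_classify(J, theta)
  rep$theorem_branch <- sprintf(
    "boundary: lambda1 = a11 = %.6g, lambda2 = predator invasion rate = %.6g",
    J$a11, J$a22)
  rep
}

# Theorem-style case analysis on (alpha, beta) for a 2x2 Jacobian; shared by
# classify_interior_eq and the property tests.  Mirrors the sign and tangent
# conditions of the published interior-equilibrium theorems; for real pairs
# the determinant sign is consulted as well, because the printed alpha-only
# cases implicitly assume beta > 0 (always true at an interior equilibrium,
# not for arbitrary matrices).
interior_case_label <- function(alpha, beta, theta, tol = 1e-10) {
  disc <- alpha^2 - 4 * beta
  if (disc < 0) {
    # complex conjugate pair, necessarily nonzero
    if (abs(alpha) <= tol)
      return(list(label = "asymptotically_stable",
                  branch = "(i) alpha = 0: pure imaginary pair"))
    if (alpha < 0)
      return(list(label = "asymptotically_stable",
                  branch = "(iii) alpha < 0, complex pair"))
    ratio <- sqrt(-disc) / alpha
    thr <- tan(theta * pi / 2)
    if (abs(ratio - thr) <= tol)
      return(list(label = "inconclusive",
                  branch = "alpha > 0: pair on the threshold ray"))
    if (ratio > thr)
      return(list(label = "asymptotically_stable",
                  branch = "alpha > 0, complex pair above threshold"))
    return(list(label = "unstable",
                branch = "alpha > 0, complex pair below threshold"))
  }
  # real spectrum: eigenvalue signs follow from (alpha, beta)
  if (abs(beta) <= tol)
    return(list(label = "inconclusive",
                branch = "zero eigenvalue: criterion undefined"))
  if (beta < 0)
    return(list(label = "saddle", branch = "real pair of opposite signs"))
  if (alpha < -tol)
    return(list(label = "asymptotically_stable",
                branch = "(ii) alpha < 0, real pair"))
  if (alpha > tol)
    return(list(label = "unstable", branch = "alpha > 0, real pair"))
  list(label = "inconclusive", branch = "alpha ~ 0 with real spectrum")
}

#' Stability of the coexistence equilibrium
#'
#' Evaluates the Jacobian at the interior equilibrium and applies the
#' case analysis on its trace \eqn{\alpha} and determinant \eqn{\beta}:
#' asymptotically stable when \eqn{\alpha \le 0}, or when
#' \eqn{\alpha > 0}, \eqn{\alpha^2 - 4\beta < 0} and
#' \eqn{\sqrt{4\beta - \alpha^2}/\alpha > \tan(\theta\pi/2)}; unstable
#' when \eqn{\alpha > 0} with a real pair or with the tangent inequality
#' reversed.  The result always coincides with [matignon_classify()] on
#' the same Jacobian (asserted in the test suite); the case analysis is
#' exposed because its conditions are the ones a reader checks by hand.
#'
#' @param params A [model_params()] object.
#' @param theta Fractional order in (0, 1].
#' @return A `pp_stability` report.
#' @examples
#' classify_interior_eq(fixture_params("exampleA"), theta = 0.78)
#' @export
classify_interior_eq <- function(params, theta) {
  eq <- interior_equilibrium(params)
  if (is.null(eq))
    stop("no interior equilibrium exists for these parameters", call. = FALSE)
  theta <- check_theta(theta)
  J <- pp_jacobian(params, c(eq$u1, eq$u2))
  rep <- matignon_classify(J, theta)
  case <- interior_case_label(J$alpha, J$beta, theta)
  rep$theorem_branch <- case$branch
  rep
}
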