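#' Hopf indicator function p(theta)
#'
#' For a Caputo system of order \eqn{\theta}, the quantity
#' \deqn{p(\theta) = \frac{\theta\pi}{2} - \min_i |\arg\lambda_i|}
#' changes sign exactly where an eigenvalue argument meets the stability
#' threshold ray; a root \eqn{\theta_0 \in (0,1)} with nonzero
#' \eqn{dp/d\theta} at a complex pair with positive real part is the
#' fractional Hopf point.
#'
#' @param theta Fractional order in (0, 1].
#' @param J A [jacobian_eval()] object with nonzero eigenvalues.
#' @return The real value \eqn{p(\theta)}.
#' @examples
#' hopf_p(0.5, jacobian_eval(1, -1, 1, 1))   # alpha = 2, beta = 2: p = 0
#' @export
hopf_p <- function(theta, J) {
  stopifnot(inherits(J, "jacobian_eval"))
  theta <- check_theta(theta)
  ev <- jac_eigen(J)
  if (any(Mod(ev) < 1e-12))
    stop("p(theta) undefined: Jacobian has a (near-)zero eigenvalue",
         call. = FALSE)
  theta * pi / 2 - min(abs(Arg(ev)))
}

#' Transversality of the Hopf crossing
#'
#' For a fixed Jacobian the eigenvalue arguments do not depend on
#' \eqn{\theta}, so \eqn{dp/d\theta \equiv \pi/2} identically; the
#' transversality condition at any candidate critical order therefore
#' holds automatically.  The constant is returned explicitly so the
#' condition is inspectable (and cross-checkable by finite differences of
#' [hopf_p()]).
#'
#' @param J A [jacobian_eval()] object (unused beyond its presence; the
#'   derivative is independent of the matrix).
#' @return \eqn{\pi/2}.
#' @export
transversality <- function(J) {
  stopifnot(inherits(J, "jacobian_eval"))
  pi / 2
}

#' Critical fractional order of the coexistence equilibrium
#'
#' When the Jacobian at the interior equilibrium has a complex pair with
#' positive real part (\eqn{\alpha > 0}, \eqn{\alpha^2 - 4\beta < 0};
#' writing \eqn{\vartheta = \alpha/2}, \eqn{\psi = \sqrt{4\beta-\alpha^2}/2}),
#' the equilibrium is Matignon-stable for small orders and loses stability
#' at the critical order
#' \deqn{\theta_0 = \frac{2}{\pi}\arctan\frac{\psi}{\vartheta}
#'   = \frac{2}{\pi}\arctan\frac{\sqrt{4\beta-\alpha^2}}{\alpha},}
#' where the pair crosses the \eqn{|\arg\lambda| = \theta\pi/2} ray.  The
#' published statement of this criterion asks for \eqn{\alpha^2-4\beta > 0},
#' but its own derivation uses a complex conjugate pair
#' \eqn{\vartheta \pm i\psi}, which forces \eqn{\alpha^2-4\beta < 0}; the
#' complex-pair condition is the one implemented, and both readings are
#' recorded in the returned object.
#'
#' If \eqn{\alpha \le 0} the pair never crosses the ray for
#' \eqn{\theta \in (0,1]} and the analysis is marked not applicable with a
#' reason (this is the situation of both packaged worked examples, whose
#' source reports critical orders of 0.83 and 0.778 that do not follow
#' from the trace/determinant values; see the package vignette).
#'
#' @param params A [model_params()] object with an interior equilibrium.
#' @return Object of class `hopf_analysis` with fields `alpha`, `beta`,
#'   `disc`, `vartheta_re`, `psi`, `applicable`, `theta0` (or `NA`),
#'   `reason`, and `condition_note` recording the printed-vs-implemented
#'   discriminant condition.
#' @examples
#' critical_order(fixture_params("exampleA"))  # not applicable: alpha < 0
#' @export
critical_order <- function(params) {
  eq <- interior_equilibrium(params)
  if (is.null(eq))
    stop("no interior equilibrium exists for these parameters", call. = FALSE)
  J <- pp_jacobian(params, c(eq$u1, eq$u2))
  alpha <- J$alpha; beta <- J$beta
  disc <- alpha^2 - 4 * beta
  vartheta <- alpha / 2
  psi <- sqrt(abs(disc)) / 2
  applicable <- (disc < 0) && (alpha > 0)
  theta0 <- NA_real_
  reason <- ""
  if (applicable) {
    theta0 <- (2 / pi) * atan(sqrt(-disc) / alpha)
    if (theta0 >= 1) {
      applicable <- FALSE
      reason <- "critical order outside admissible range (0, 1)"
      theta0 <- NA_real_
    }
  } else if (disc >= 0) {
    reason <- "eigenvalues real: no complex pair to cross the threshold ray"
  } else {
    reason <- "complex pair has nonpositive real part (alpha <= 0): stable for every theta in (0, 1]"
  }
  structure(list(alpha = alpha, beta = beta, disc = disc,
                 vartheta_re = vartheta, psi = psi,
                 applicable = applicable, theta0 = theta0, reason = reason,
                 condition_note = paste(
                   "implemented: alpha > 0 and alpha^2 - 4*beta < 0",
                   "(complex pair); printed statement asks alpha^2 - 4*beta > 0,",
                   "inconsistent with its own complex-pair derivation")),
            class = "hopf_analysis")
}

#' @export
print.hopf_analysis <- function(x, ...) {
  cat("Fractional Hopf analysis at the coexistence equilibrium\n")
  cat(sprintf("  alpha (trace) = %.6g, beta (det) = %.6g, disc = %.6g\n",
              x$alpha, x$beta, x$disc))
  if (x$applicable)
    cat(sprintf("  critical order theta0 = %.9g (vartheta = %.6g, psi = %.6g)\n",
                x$theta0, x$vartheta_re, x$psi))
  else
    cat(sprintf("  not applicable: %s\n", x$reason))
  invisible(x)
}

#' Brute-force scan for the critical order
#'
#' Numerical oracle for [critical_order()]: locates the sign change of
#' [hopf_p()] over \eqn{\theta \in (0,1)} on a grid, then refines by
#' bisection to `1e-9`.  Returns `NA` when `p` has constant sign on the
#' interval.
#'
#' @param J A [jacobian_eval()] object.
#' @param grid_step Grid spacing in (0, 0.01].
#' @return The root \eqn{\theta_0}, or `NA_real_`.
#' @examples
#' scan_theta(jacobian_eval(1, -1, 1, 1))   # 0.5
#' @export
scan_theta <- function(J, grid_step = 0.005) {
  stopifnot(inherits(J, "jacobian_eval"))
  if (!is.numeric(grid_step) || length(grid_step) != 1L ||
      grid_step <= 0 || grid_step > 0.01)
    stop("grid_step must lie in (0, 0.01]", call. = FALSE)
  eps <- 1e-9
  grid <- seq(eps, 1 - eps, by = grid_step)
  pv <- vapply(grid, hopf_p, numeric(1), J = J)
  sgn <- sign(pv)
  flip <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  if (length(flip) == 0L) {
    exact <- which(pv == 0)
    if (length(exact)) return(grid[exact[1L]])
    return(NA_real_)
  }
  lo <- grid[flip[1L]]; hi <- grid[flip[1L] + 1L]
  # bisection to 1e-9 (p is affine increasing in theta, so this converges)
  while (hi - lo > 1e-9) {
    mid <- (lo + hi) / 2
    if (hopf_p(mid, J) * hopf_p(lo, J) <= 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}
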