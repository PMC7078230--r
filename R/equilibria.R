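#' @name equilibria
#' @title Equilibria of the harvested group-defense system
#'
#' @description Steady states solve \eqn{pp\_rhs(params, u) = 0}.  There are
#' three kinds: the extinction state \eqn{(0,0)} (always present),
#' predator-free boundary states \eqn{(u_1, 0)} with \eqn{u_1 > 0} solving
#' the prey nullcline, and the coexistence (interior) state with both
#' densities positive.
#'
#' Boundary states satisfy
#' \eqn{\gamma_1(1-u_1/\kappa) = \rho_1\rho_2/(\rho_2\rho_3+\rho_4 u_1)},
#' a quadratic in \eqn{u_1}:
#' \deqn{u_1^2 - \left(\kappa - \frac{\rho_2\rho_3}{\rho_4}\right)u_1
#'   + \kappa\left(\frac{\rho_1\rho_2}{\gamma_1\rho_4}
#'   - \frac{\rho_2\rho_3}{\rho_4}\right) = 0.}
#' Only real roots with \eqn{u_1 > 0} are biologically admissible and
#' returned.  The coexistence prey level comes from the predator nullcline,
#' \eqn{u_1^* = (\gamma_3/(\gamma_2\gamma_4))^{1/\sigma}}, and the predator
#' level from substituting into the prey nullcline:
#' \deqn{u_2^* = \frac{u_1^{*\,1-\sigma}}{\gamma_2}
#'   \left[\gamma_1\left(1-\frac{u_1^*}{\kappa}\right)
#'   - \frac{\rho_1\rho_2}{\rho_2\rho_3+\rho_4 u_1^*}\right].}
#' The interior equilibrium exists iff \eqn{u_2^* > 0}.
NULL

new_equilibrium <- function(u1, u2, klass, provenance) {
  structure(list(u1 = u1, u2 = u2, klass = klass,
                 admissible = is.finite(u1) && is.finite(u2) &&
                   u1 >= 0 && u2 >= 0,
                 provenance = provenance),
            class = "pp_equilibrium")
}

#' @export
print.pp_equilibrium <- function(x, ...) {
  cat(sprintf("%s equilibrium (%.6g, %.6g)%s  [%s]\n", x$klass, x$u1, x$u2,
              if (x$admissible) "" else " (inadmissible)", x$provenance))
  invisible(x)
}

# Coefficients of the monic boundary-nullcline quadratic in u1.
boundary_quadratic <- function(params) {
  co <- composites(params)
  c(b = -(params$kappa - co$h_den0 / params$rho4),
    c = params$kappa * (co$h_num / (params$gamma1 * params$rho4) -
                          co$h_den0 / params$rho4))
}

#' Predator-free boundary equilibria
#'
#' @rdname equilibria
#' @param params A [model_params()] object.
#' @return `boundary_equilibria()`: a (possibly empty) list of admissible
#'   boundary equilibria, each verified to annihilate the vector field.
#' @examples
#' boundary_equilibria(fixture_params("exampleA"))
#' @export
boundary_equilibria <- function(params) {
  stopifnot(inherits(params, "model_params"))
  q <- boundary_quadratic(params)
  disc <- q[["b"]]^2 - 4 * q[["c"]]
  # a tangency constructed to machine precision must classify as a double
  # root, not as two roots a rounding error apart
  tol <- 1e-12 * max(1, q[["b"]]^2)
  if (disc < -tol) return(list())
  double_root <- abs(disc) <= tol
  roots <- if (double_root) -q[["b"]] / 2 else
    (-q[["b"]] + c(1, -1) * sqrt(disc)) / 2
  roots <- roots[roots > 0]
  lab <- if (double_root) "double root of prey nullcline" else
    "prey-nullcline quadratic root"
  lapply(roots, function(r) new_equilibrium(r, 0, "boundary", lab))
}

#' Coexistence (interior) equilibrium
#'
#' @rdname equilibria
#' @return `interior_equilibrium()`: a `pp_equilibrium` with both
#'   coordinates positive, or `NULL` when the predator nullcline level
#'   yields a nonpositive predator density.
#' @examples
#' interior_equilibrium(fixture_params("exampleA"))  # (0.4096, 0.1580)
#' @export
interior_equilibrium <- function(params) {
  stopifnot(inherits(params, "model_params"))
  u1s <- (params$gamma3 / (params$gamma2 * params$gamma4))^(1 / params$sigma)
  u2s <- u1s^(1 - params$sigma) *
    (params$gamma1 * (1 - u1s / params$kappa) -
       params$rho1 * params$rho2 /
       (params$rho2 * params$rho3 + params$rho4 * u1s)) / params$gamma2
  if (!is.finite(u2s) || u2s <= 0) return(NULL)
  new_equilibrium(u1s, u2s, "interior", "predator-nullcline root")
}

#' Existence classification of all equilibria
#'
#' @rdname equilibria
#' @return `existence_report()`: a list of class `pp_existence` with
#'   `has_zero` (always `TRUE`), `boundary_count` of admissible boundary
#'   states, `has_interior`, the normalized discriminant
#'   \eqn{(1-\rho_2\rho_3/(\rho_4\kappa))^2 -
#'   4(\rho_1\rho_2/(\gamma_1\rho_4\kappa) - \rho_2\rho_3/(\rho_4\kappa))}
#'   of the boundary quadratic, and `branch`, the case of the published
#'   five-way classification that fired (the positivity filter may remove
#'   a formally counted negative root, so `branch` and `boundary_count`
#'   are reported independently).
#' @examples
#' existence_report(fixture_params("exampleA"))
#' @export
existence_report <- function(params) {
  stopifnot(inherits(params, "model_params"))
  co <- composites(params)
  s <- co$h_den0 / (params$rho4 * params$kappa)
  disc <- (1 - s)^2 -
    4 * (co$h_num / (params$gamma1 * params$rho4 * params$kappa) - s)
  bnd <- boundary_equilibria(params)
  interior <- interior_equilibrium(params)
  tol <- 1e-12 * max(1, (1 - s)^2)
  branch <- if (disc < -tol) "(2) no boundary equilibria"
  else if (abs(disc) <= tol && s < 1) "(3) unique (double) boundary equilibrium"
  else if (disc > tol && s < 1) "(4) two boundary roots"
  else "outside the printed classification (saturation ratio >= 1)"
  structure(list(has_zero = TRUE,
                 boundary_count = length(bnd),
                 has_interior = !is.null(interior),
                 discriminant = disc,
                 saturation_ratio = s,
                 branch = branch),
            class = "pp_existence")
}

#' @export
print.pp_existence <- function(x, ...) {
  cat("Equilibrium existence report\n")
  cat(sprintf("  zero equilibrium: always present\n"))
  cat(sprintf("  boundary equilibria (admissible): %d  [branch %s]\n",
              x$boundary_count, x$branch))
  cat(sprintf("  interior equilibrium: %s\n",
              if (x$has_interior) "exists" else "absent"))
  cat(sprintf("  discriminant = %.6g, saturation ratio = %.6g\n",
              x$discriminant, x$saturation_ratio))
  invisible(x)
}

#' All equilibria of a parameter set
#'
#' @rdname equilibria
#' @return `all_equilibria()`: list of every admissible equilibrium,
#'   beginning with the zero state.
#' @export
all_equilibria <- function(params) {
  eqs <- c(list(new_equilibrium(0, 0, "zero", "always present")),
           boundary_equilibria(params))
  interior <- interior_equilibrium(params)
  if (!is.null(interior)) eqs <- c(eqs, list(interior))
  eqs
}
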