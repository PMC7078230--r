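#' Read a parameter configuration file
#'
#' Accepts a flat JSON or YAML document (chosen by file extension, with a
#' JSON fallback) in either entry style: individual keys
#' `gamma1..gamma4, kappa, sigma, rho1..rho4`, or composite keys
#' `a, b, c_pred, c_gain, m, sigma, h_num, h_den0, rho4` (see
#' [composite_params()]).  Unknown or missing keys are errors naming the
#' offending key.
#'
#' @param path Path to a `.json`, `.yml`/`.yaml` file.
#' @return A [model_params()] object.
#' @export
read_params_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path) else jsonlite::read_json(path, simplifyVector = TRUE)
  params_from_list(cfg)
}

# Resolve a named list in either entry style into model_params.
params_from_list <- function(cfg) {
  individual <- c("gamma1", "gamma2", "gamma3", "gamma4", "kappa", "sigma",
                  "rho1", "rho2", "rho3", "rho4")
  composite <- c("a", "b", "c_pred", "c_gain", "m", "sigma",
                 "h_num", "h_den0", "rho4")
  keys <- names(cfg)
  style <- if (all(individual %in% keys)) "individual"
  else if (all(composite %in% keys)) "composite"
  else {
    miss_i <- setdiff(individual, keys)
    miss_c <- setdiff(composite, keys)
    miss <- if (length(miss_i) <= length(miss_c)) miss_i else miss_c
    stop("config is missing key(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  wanted <- if (style == "individual") individual else composite
  extra <- setdiff(keys, wanted)
  if (length(extra))
    stop("config has unrecognized key(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  cfg <- lapply(cfg[wanted], as.numeric)
  if (style == "individual") do.call(model_params, cfg)
  else do.call(composite_params, cfg)
}

#' Write a parameter configuration file
#'
#' Serializes the ten individual constants (full double precision) to JSON
#' or YAML by extension.  [read_params_config()] on the result reproduces
#' the parameters exactly.
#'
#' @param params A [model_params()] object.
#' @param path Destination path ending in `.json`, `.yml` or `.yaml`.
#' @return `path`, invisibly.
#' @export
write_params_config <- function(params, path) {
  stopifnot(inherits(params, "model_params"))
  vals <- unclass(params)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(lapply(vals, function(v)
      as.numeric(formatC(v, digits = 17, format = "g"))), path,
      precision = 17)
  } else {
    jsonlite::write_json(vals, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Full analysis bundle for one parameter set
#'
#' Aggregates the package's analytic output: the resolved parameters and
#' composites (so any reconciliation is auditable), the existence report,
#' every admissible equilibrium with its Matignon classification at the
#' given order, and the Hopf analysis of the coexistence equilibrium when
#' it exists.  The bundle is plain nested lists, deterministic
#' byte-for-byte for identical inputs (no timestamps), and serializes with
#' [write_report()].
#'
#' @param params A [model_params()] object.
#' @param theta Fractional order in (0, 1].
#' @return Nested list of class `pp_report` with a `schema_version` field.
#' @examples
#' rep <- run_report(fixture_params("exampleA"), theta = 0.78)
#' rep$equilibria[[1]]$stability$label   # extinction state: saddle
#' @export
run_report <- function(params, theta) {
  stopifnot(inherits(params, "model_params"))
  theta <- check_theta(theta)
  eqs <- all_equilibria(params)
  eq_entries <- lapply(eqs, function(eq) {
    stab <- switch(eq$klass,
      zero = classify_zero_eq(params, theta),
      boundary = classify_boundary_eq(params, eq, theta),
      interior = classify_interior_eq(params, theta))
    list(u1 = eq$u1, u2 = eq$u2,
         u1_4dp = round(eq$u1, 4), u2_4dp = round(eq$u2, 4),
         klass = eq$klass, provenance = eq$provenance,
         stability = list(
           label = stab$label,
           eigenvalues = lapply(stab$eigenvalues,
                                function(z) list(re = Re(z), im = Im(z))),
           args = stab$args,
           threshold = stab$threshold,
           theorem_branch = stab$theorem_branch))
  })
  hopf <- if (existence_report(params)$has_interior) {
    h <- critical_order(params)
    list(alpha = h$alpha, beta = h$beta, disc = h$disc,
         vartheta_re = h$vartheta_re, psi = h$psi,
         applicable = h$applicable, theta0 = h$theta0, reason = h$reason,
         condition_note = h$condition_note)
  } else NULL
  ex <- existence_report(params)
  structure(list(
    schema_version = "1.0",
    theta = theta,
    params = unclass(params),
    composites = composites(params),
    existence = unclass(ex),
    equilibria = eq_entries,
    hopf = hopf),
    class = "pp_report")
}

#' Write an analysis bundle or any report list as JSON
#'
#' @param report A list, e.g. from [run_report()].
#' @param path Destination `.json` path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Write a trajectory as CSV
#'
#' Header `t,u1,u2`, one row per grid point, full double precision.
#'
#' @param traj A `pp_trajectory` from [simulate_trajectory()].
#' @param path Destination `.csv` path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "pp_trajectory"))
  df <- data.frame(t = traj$t,
                   u1 = traj$states[, 1L],
                   u2 = traj$states[, 2L])
  utils::write.csv(format(df, digits = 17, trim = TRUE), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Amplitude scan over the fractional order
#'
#' Simulates the model over a grid of fractional orders and summarizes the
#' tail oscillation of each run, the quantitative counterpart of a
#' bifurcation diagram in \eqn{\theta}.
#'
#' @param params A [model_params()] object.
#' @param theta_min,theta_max Scan interval within (0, 1].
#' @param steps Number of grid points.
#' @param u0 Initial state.
#' @param settings A [solver_settings()] object.
#' @param tail_fraction Passed to [oscillation_stats()].
#' @return `data.frame` with columns `theta`, `amp_u1`, `amp_u2`,
#'   `period`, `label`.
#' @export
scan_orders <- function(params, theta_min, theta_max, steps,
                        u0 = c(0.3, 0.3), settings = solver_settings(),
                        tail_fraction = 0.5) {
  thetas <- seq(theta_min, theta_max, length.out = steps)
  rows <- lapply(thetas, function(th) {
    tr <- simulate_trajectory(params, th, u0, settings)
    st <- oscillation_stats(tr, tail_fraction)
    data.frame(theta = th, amp_u1 = st$amplitude[1L],
               amp_u2 = st$amplitude[2L], period = st$period,
               label = st$label)
  })
  do.call(rbind, rows)
}
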