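Package: fracprey
Title: Fractional-Order Predator-Prey Dynamics with Group Defense and
    Michaelis-Menten Harvesting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for a Caputo fractional-order predator-prey model in which
    prey exhibit group defense (a power-law functional response with exponent
    sigma) and are harvested at a saturating Michaelis-Menten rate.  Provides
    closed-form equilibria with existence classification, local stability
    analysis under the Matignon eigenvalue-argument criterion, the critical
    fractional order at which a coexistence equilibrium loses stability (the
    fractional Hopf point) with its transversality check, computable
    existence/boundedness constants (Lipschitz and dissipativity bounds), a
    full-memory Adams-Bashforth-Moulton predictor-corrector integrator for
    Caputo initial value problems, a Mittag-Leffler evaluator used as a solver
    oracle, and a seeded generator of parameter sets with prescribed dynamical
    regime (stable node, stable focus, Hopf-capable, no coexistence).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    pracma,
    withr,
    optparse
Config/testthat/edition: 3
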