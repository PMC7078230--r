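---
title: "Methods: fractional-order predator-prey dynamics with group defense and saturating harvest"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fractional-order predator-prey dynamics with group defense and saturating harvest}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fracprey)
```

## The model

`fracprey` analyses the two-species Caputo fractional-order system

$$
\begin{aligned}
D^\theta u_1 &= \gamma_1\Big(1-\frac{u_1}{\kappa}\Big)u_1
  - \gamma_2 u_1^{\sigma} u_2
  - \frac{\rho_1\rho_2 u_1}{\rho_2\rho_3+\rho_4 u_1},\\
D^\theta u_2 &= -\gamma_3 u_2 + \gamma_2\gamma_4 u_1^{\sigma} u_2,
\end{aligned}
$$

where $u_1, u_2 \ge 0$ are prey and predator densities and
$D^\theta$ is the Caputo derivative of order $\theta \in (0,1]$.  Three
ecological mechanisms meet here:

* **Logistic prey growth** with rate $\gamma_1$ and carrying capacity
  $\kappa$.
* **Group defense**: predation scales as $u_1^\sigma$ with
  $0 < \sigma < 1$ in the worked examples, so *per-capita* predation
  pressure $u_1^{\sigma-1}u_2$ falls as prey aggregate.  The flip side is
  that per-capita pressure diverges as $u_1 \to 0$, which makes
  finite-time prey extinction possible — a genuine feature of the model
  the numerics must respect, not a bug (see "Numerical choices").
* **Michaelis–Menten (saturating) harvesting** of prey with catchability
  $\rho_1$, effort $\rho_2$ and shape constants $\rho_3,\rho_4$.

The fractional order $\theta$ endows the flow with power-law memory and
acts as a bifurcation parameter: lowering $\theta$ widens the stability
sector of the linearization, so an equilibrium that spirals unstably in
the classical limit $\theta = 1$ can be asymptotically stable for smaller
$\theta$.

All ten constants are strictly positive.  The equations depend on the
harvesting constants only through $\rho_1\rho_2$, $\rho_2\rho_3$ and
$\rho_4$, and on $\gamma_2,\gamma_4$ only through $\gamma_2$ and the gain
$\gamma_2\gamma_4$ (plus $\gamma_4$ in the biomass weighting); the
composite entry style of `composite_params()` exists because one of the
shipped worked examples can only be stated unambiguously that way (below).

## Equilibria

Setting the right side to zero gives three families, all in closed form
(`all_equilibria()`):

* the extinction state $(0,0)$, always present;
* predator-free boundary states $(u_1, 0)$ where
  $\gamma_1(1-u_1/\kappa) = \rho_1\rho_2/(\rho_2\rho_3+\rho_4 u_1)$.  The
  package expands this into the monic quadratic
  $u_1^2 - (\kappa - \rho_2\rho_3/\rho_4)u_1
  + \kappa(\rho_1\rho_2/(\gamma_1\rho_4) - \rho_2\rho_3/\rho_4) = 0$
  derived from first principles, rather than using the published
  closed-form roots, which are dimensionally consistent only at
  $\kappa = 1$; at $\kappa = 1$ the two coincide and the printed forms
  serve as a regression oracle in the tests.  Only real roots with
  $u_1 > 0$ are returned;
* the coexistence state: the predator nullcline fixes
  $u_1^* = (\gamma_3/(\gamma_2\gamma_4))^{1/\sigma}$ and the prey
  nullcline then yields
  $u_2^* = u_1^{*\,1-\sigma}\big[\gamma_1(1-u_1^*/\kappa)
  - \rho_1\rho_2/(\rho_2\rho_3+\rho_4u_1^*)\big]/\gamma_2$, admissible
  iff $u_2^* > 0$.

`existence_report()` also evaluates the published five-branch existence
classification (discriminant of the boundary quadratic, saturation ratio
$\rho_2\rho_3/(\rho_4\kappa)$) and reports the branch *alongside* the
positivity-filtered count, because a formally counted root can be
negative and biologically inadmissible.

## Stability: the Matignon criterion

For a Caputo system an equilibrium is locally asymptotically stable iff
every Jacobian eigenvalue satisfies $|\arg\lambda| > \theta\pi/2$; with
one argument strictly inside and one outside the sector it is a saddle.
`matignon_classify()` computes the two eigenvalues from the closed-form
quadratic $(\alpha \pm \sqrt{\alpha^2-4\beta})/2$ in trace
$\alpha$ and determinant $\beta$ (no iterative eigensolver, for exact
reproducibility), and compares $|\arg\lambda|$ to $\theta\pi/2$ with
absolute tolerance $10^{-10}$.  Ties, and eigenvalues within $10^{-12}$
of zero, return `"inconclusive"`: the criterion is undefined at the
origin, and the marginal case would need a multiplicity analysis that is
moot for distinct eigenvalues of a $2\times 2$.

Wrappers evaluate the three equilibrium families.  Two structural facts
are worth knowing (both are asserted over hundreds of random parameter
sets in the test suite):

* at the coexistence equilibrium $a_{22} = -\gamma_3 +
  \gamma_2\gamma_4 u_1^{*\sigma} = 0$ by definition of $u_1^*$, and
  $\beta = \sigma\gamma_2^2\gamma_4 u_1^{*\,2\sigma-1}u_2^* > 0$ — so the
  coexistence state is **never a saddle**;
* the published case analysis for boundary states pairs "stable" with a
  positive predator invasion rate, which contradicts the Matignon
  criterion (a positive real eigenvalue is always unstable); the package
  classifies by the criterion itself and records the raw sign pattern in
  `theorem_branch` for traceability.

The case analysis on $(\alpha,\beta)$ exposed by
`classify_interior_eq()` ("stable when $\alpha\le 0$; when $\alpha>0$
with a complex pair, compare $\sqrt{4\beta-\alpha^2}/\alpha$ to
$\tan(\theta\pi/2)$") is the hand-checkable form; for real spectra with
$\beta \le 0$ — impossible at a coexistence state, possible for an
arbitrary matrix — the determinant sign is consulted so that the case
analysis and the eigenvalue-argument path agree everywhere except exact
boundaries.

## The fractional Hopf point

For a complex pair $\vartheta \pm i\psi$ with $\vartheta = \alpha/2 > 0$,
$\psi = \sqrt{4\beta-\alpha^2}/2$, the indicator
$p(\theta) = \theta\pi/2 - \min_i|\arg\lambda_i|$ is affine in $\theta$
with slope exactly $\pi/2$ (`transversality()`), and vanishes at

$$\theta_0 = \frac{2}{\pi}\arctan\frac{\psi}{\vartheta}
 = \frac{2}{\pi}\arctan\frac{\sqrt{4\beta-\alpha^2}}{\alpha} \in (0,1):$$

below $\theta_0$ the equilibrium is asymptotically stable, above it
unstable, with oscillations born at the crossing.  `critical_order()`
implements this; `scan_theta()` is an independent grid-plus-bisection
oracle on $p$ itself, and the two agree to $10^{-8}$ across generated
Hopf-capable parameter sets (an acceptance-level test).

Two documented discrepancies with the source material:

* the published theorem asks for $\alpha^2 - 4\beta > 0$, but its own
  proof takes a complex conjugate pair, which forces
  $\alpha^2-4\beta<0$; the complex-pair reading is implemented and both
  are recorded in the returned `condition_note`;
* the source reports critical orders $0.83$ and $0.778$ for its two
  worked examples, but at both examples' coexistence equilibria the trace
  is *negative* ($\alpha \approx -0.0155$ and $\approx -0.0375$), so no
  critical order exists under any parameter reading we could reconcile —
  the pair is a damped spiral for every $\theta \in (0,1]$.
  `critical_order()` therefore surfaces its own $\alpha,\beta$ and a
  reason string instead of reproducing those numbers, and the package's
  quantitative acceptance of the Hopf machinery rests on the
  closed-form-versus-bisection agreement and the stability flip at
  $\theta_0 \pm 0.01$ over hundreds of generated Hopf-capable sets.

## Existence and boundedness constants

`lipschitz_bound()` returns the constant $\vartheta$ certifying a
Lipschitz condition on the box $\max(|u_1|,|u_2|) < K$, exactly in its
published form — including a harvesting term written $\rho_1\rho_4/\rho_4$
(trivially $\rho_1$), kept verbatim because the constant is only
reported, never consumed downstream.

`asymptotic_bound()` bounds the weighted biomass
$U = \gamma_4u_1 + u_2$, which obeys
$D^\theta U + \gamma_3 U \le M$ with
$M = \gamma_4\kappa(\gamma_1+\gamma_3)^2/(4\gamma_1)$ after completing
the square.  The Mittag-Leffler comparison principle then gives
$\limsup U \le M/\gamma_3$, the default `"corrected"` value
$\gamma_4\kappa(\gamma_1+\gamma_3)^2/(4\gamma_1\gamma_3)$.  The constant
as originally printed omits the division by $\gamma_3$ and places
$\kappa$ in the denominator; for the baseline example it evaluates to
$0.09$, *below* the equilibrium biomass $0.2604$, so it cannot be an
attracting bound.  It is retained as `variant = "as_printed"` for
reference and never asserted against trajectories.

## The Caputo integrator

No discretization scheme is named by the source; the package uses the
de facto standard for Caputo initial value problems, the full-memory
Adams–Bashforth–Moulton predictor–corrector (PECE) on a uniform grid:
fractional rectangle-rule predictor with weights
$(h^\theta/\theta)[(n+1-j)^\theta - (n-j)^\theta]$, fractional
trapezoid-rule corrector with the standard weights and
$\Gamma(\theta+2)$ normalization.  The $O(N^2)$ history convolution is
implemented in C++ with precomputed lag-power tables.  Validation is by
analytic oracles, not self-consistency: $D^\theta u = -u$ against
$E_\theta(-t^\theta)$ (with $E_{1/2}(-1) = e\,\mathrm{erfc}(1)$ as an
independent closed form), $D^\theta u = 1$ against
$t^\theta/\Gamma(\theta+1)$, and the classical limit $\theta = 1$
against an adaptive `deSolve::lsoda` reference on the model itself.
Observed empirical orders on the linear test are 1.5–1.9 for
$\theta \in [0.5, 0.9]$ (the scheme's theoretical $1+\theta$ for smooth
solutions).

### Numerical choices

* **Positivity.**  With $\sigma < 1$ the term $u_1^\sigma$ amplifies
  tiny negative round-off into NaNs, so components dipping below zero
  are clamped to `positivity_floor` ($10^{-12}$) and counted in
  `clamped_count`; clamping is a guard, and shipped example runs are
  asserted clamp-free.  For scalar test problems whose solutions
  legitimately change sign, `clamp = FALSE` disables it.
* **Default grid.**  `h = 0.02`, `t_end = 500`, initial state
  $(0.3, 0.3)$ (none are stated by the source; all are recorded in every
  returned trajectory).  The step was set by resolution, not speed: the
  baseline example trajectory at $\theta = 0.78$ passes within about
  $10^{-4}$ of the prey axis, where the group-defense term has unbounded
  slope, and at $h = 0.05$ the corrector overshoots negative there
  (clamps fire), while at $h = 0.02$ the dip is resolved cleanly.
* **Classical-limit comparison.**  From $(0.3,0.3)$ the $\theta = 1$
  flow reaches the prey axis in *finite time* (verified independently
  with `lsoda` at `rtol = 1e-12`): group defense makes the field
  non-Lipschitz at $u_1 = 0$ and extinction in finite time is real
  dynamics, not solver failure.  Since no meaningful accuracy comparison
  exists across a non-Lipschitz collision, the solver-consistency check
  starts at $(0.42, 0.16)$, inside the coexistence basin, where the
  classical solution stays smooth on the comparison window $[0, 50]$.
* **Oscillation summaries.**  `oscillation_stats()` reports tail
  amplitudes $(\max-\min)/2$, strict-local-maxima peak spacing as a
  period estimate, and labels amplitudes below $10^{-4}$ as
  `"damped/steady"`.  The source's figures suggest sustained oscillation
  at $\theta \in \{0.9, 1\}$ for the baseline example even though its
  computed pair is (weakly) damped, $\mathrm{Re}\,\lambda \approx
  -0.0077$; whether those figures show limit cycles or slow transients
  cannot be decided from the material, so `scan_orders()` reports
  amplitudes without asserting either reading.

## The scenario generator

The analytic claims are quantified over generated parameter sets rather
than a single example.  `generate_scenarios()` rejection-samples the ten
constants uniformly from ranges bracketing both worked examples
($\gamma_1,\gamma_2 \in [0.5,1.5]$, $\gamma_3 \in [0.05,0.5]$,
$\gamma_4 \in [0.1,0.5]$, $\kappa \in [0.5,3]$, $\sigma \in [0.2,0.9]$,
$\rho_1 \in [0,0.3]$, $\rho_2,\rho_4 \in [0.5,1.5]$,
$\rho_3 \in [0.1,0.5]$) until the coexistence equilibrium satisfies a
requested regime predicate: stable node ($\alpha<0$, real pair), stable
focus ($\alpha<0$, complex pair), Hopf-capable ($\alpha>0$, complex
pair, $\theta_0 \in (0.05,0.95)$ — the margin keeps $\theta_0\pm0.05$
probes inside $(0,1)$), or no coexistence ($u_2^* \le 0$).  Empirical
acceptance rates under the default ranges are roughly 10–20% per regime,
so the $10^5$-draw budget is comfortable.  Each set carries a
certificate $(\alpha,\beta,\theta_0)$ that the tests re-derive through
the public modules — the generator is never trusted as an oracle.  What
generated sets do *not* emulate: any real ecological data (the source
contains none), parameter correlations, or observation noise; passing
tests demonstrate internal mathematical consistency of the analysis
chain, not fit to field data.

## The two worked parameter sets

`fixture_params("exampleA")` is the baseline set
($\gamma_1=\gamma_2=\kappa=\rho_2=\rho_4=1$, $\gamma_3=0.2$,
$\gamma_4=0.25$, $\sigma=0.25$, $\rho_1=0.2$, $\rho_3=0.3$), with
coexistence equilibrium exactly $(0.8^4, 0.1580) = (0.4096, 0.1580)$.

`fixture_params("exampleB")` required reconciliation.  Its source prints
an individual-parameter list ($\gamma_4 = 25/9$, $\kappa = 500/499$,
$\rho_2 = 1.1$, $\rho_3 = 0.25$) that contradicts the system of
equations displayed beside it: the list's predator gain would be
$\gamma_2\gamma_4 = 2.5$ (the displayed equation has $0.25$, and the
printed equilibrium requires $0.25$), and the list's harvest saturation
$\rho_2\rho_3 = 0.275$ (the displayed denominator is $0.25 + u_1$).  The
package re-derived, by brute-force nullcline evaluation over the
candidate readings, that the *unique* reading reproducing both printed
equilibrium coordinates $(0.4168, 0.1465)$ to 4 decimals is the
composite one taken from the displayed equations: growth
$(0.999 - 0.998u_1)u_1$, $\gamma_2 = 0.9$, gain $0.25$,
$\sigma = 0.255$, $\gamma_3 = 0.2$, $\rho_1\rho_2 = 0.22$,
$\rho_2\rho_3 = 0.25$, $\rho_4 = 1$.  That is the default fixture.
`"exampleB-literal"` keeps the printed $\rho_2\rho_3 = 0.275$ instead
and yields $u_2^* = 0.1534$, preserving the inconsistency as an
inspectable object rather than silently discarding it.

## Problem sizes and limitations

The shipped tests quantify claims at these sizes, chosen as the package's
own balance of statistical weight against a commodity single-core run:
300 Hopf-capable sets for the closed-form/bisection agreement and
stability flip, 1000 random matrices for the case-analysis/criterion
agreement, 500 sets for the structural identities, 50 stable sets
simulated to $t = 500$ for the dissipativity bound, and solver
validation at $h$ down to $1/2048$ (linear tests) and $10^{-3}$
(classical-limit comparison, $5\times 10^4$ steps).

Known limitations: no delayed or non-autonomous variants; no
limit-cycle amplitude/frequency prediction or bifurcation-direction
(normal form) analysis; no short-memory acceleration or adaptive
stepping in the integrator (full memory is $O(N^2)$); the
Mittag-Leffler evaluator is a series implementation restricted to
$|z| \le 50$; and marginal (`"inconclusive"`) spectra are reported, not
resolved.
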