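---
title: "Contact inhibition and the growth laws it generates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contact inhibition and the growth laws it generates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cigrow)
```

## The model

`cigrow` studies a single microscopic mechanism — a cell cannot divide when
every site of its *birth neighborhood* is occupied — and the family of
macroscopic growth laws that emerge from it in different migration regimes.

The microscopic picture is an exclusion process on a lattice of $l$ sites.
Each of $n$ cells attempts division at rate $\lambda$, placing a daughter on
a uniformly chosen empty site of its birth neighborhood $\Omega$ (of size
$\omega$); if the neighborhood is full the division is blocked. Death occurs
at rate $\delta$ independent of crowding, and cells may migrate at rate $m$
within a migration neighborhood $\Phi$. Averaging the blocked probability
$P(\omega \mid n)$ over cells gives the mean-field law

$$\dot u = \lambda u \left(1 - \mathbb{E}[P(\omega \mid n)]\right) - \delta u,
\qquad u = n/l .$$

Everything else in the package is a specialization of
$\mathbb{E}[P(\omega\mid n)]$:

* **Well-mixed** (fast migration, exchangeable positions): the occupancy of
  a focal cell's neighborhood is hypergeometric,
  $P(x \mid n) = \binom{\omega}{x}\binom{l-\omega-1}{n-x-1}/\binom{l-1}{n-1}$,
  and the fully-blocked probability is
  $\prod_{j=0}^{\omega-1}\frac{n-1-j}{l-1-j} \to (n/l)^\omega$ for
  $l, n \gg \omega$. Substituting $(n/l)^\omega$ yields the generalized
  logistic (Richards) law $\dot u = \lambda u (1 - u^{\bar\omega}) - \delta u$;
  a Taylor expansion around small $\bar\omega$ yields Gompertz,
  $\dot u = -\lambda\bar\omega\, u \ln u - \delta u$, with second-order
  corrections in $\ln u$ involving the neighborhood-size spread
  $\sigma_\omega$ (`gen_logistic_corrected`, `gompertz_corrected`).
* **No migration, compact growth**: only surface cells divide. With
  $n = (R/r)^d$ the blocked probability is the bulk fraction
  $(1 - n^{-1/d})^d \approx 1 - d\,n^{-1/d}$, giving surface-limited growth
  $\dot n = \lambda d\, n^{(d-1)/d} - \delta n$ (Von Bertalanffy at $d=3$).
* **Rough interfaces**: if the surface-cell count scales as
  $n_s \propto n^{D/d}$ with a fractal dimension $d-1 < D \le d$, growth
  follows $\dot n = \lambda a\, n^{D/d} - \delta n$.
* **Neighborhood spanning the lattice** ($\omega = l-1$): blocking is the
  indicator $I_{n \ge l}$ and growth is exponential until saturation — not
  logistic.

A note on the radial blocked probability: a published tabulation of these
limits prints it as $1 - n^{-1}$; the derivation from the surface/bulk
partition gives $(1 - n^{-1/d})^d$, which is what the package implements.

## Gompertz validity

The Gompertz expansion is valid when
$2\bar\omega/(\sigma_\omega^2 + \bar\omega^2) \gg |\ln u|$: the population
must not be too sparse, or the mean neighborhood must be very small. The
qualitative "much greater" is operationalized in
`gompertz_condition_margin()` by a multiplicative strictness factor, default
10 — a deliberately conservative reading; the factor is exposed because no
quantitative threshold exists in the underlying theory. This condition
predicts the package's central statistical observation: Gompertz fits
improve, relative to generalized logistic fits, as seeding confluency
increases.

Only the composite rate $g = \lambda\bar\omega$ is identifiable from a
Gompertz curve, so `growth_params()` and `fit_growth_law()` parameterize
Gompertz by $g$; separate $\lambda$ and $\omega$ estimates always come from
the generalized logistic fit.

For the corrected generalized logistic law the second-order term is
implemented as $u^{\bar\omega}\bigl(1 + \tfrac12\sigma_\omega^2(\ln u)^2\bigr)$,
i.e. the correction multiplies $u^{\bar\omega}$ inside the saturation
bracket. The alternative placement (multiplying the whole bracket) is not
consistent with recovering the uncorrected law at $\sigma_\omega = 0$ term
by term in the expansion; we flag the choice here because the source
typesetting is ambiguous.

## The simulator

`run_abm()` implements the fixed-time-step loop: at each step the cells
alive at step start are visited in uniformly shuffled order; each attempts
migration (probability $\min(m\,\Delta t, 1)$, uniform empty target in
$\Phi$, or anywhere on the lattice under `full_domain` migration), then
birth (probability $\min(\lambda\,\Delta t, 1)$, uniform empty target in
$\Omega$), and — only if no daughter was placed — death (probability
$\min(\delta\,\Delta t, 1)$). Decisions that were genuinely open:

* *A blocked birth attempt exposes the cell to the death check.* The loop's
  stated rule is "in the absence of birth, the cell may die"; we read
  "birth" as a successfully placed daughter.
* *Daughters act only from the next step* (the shuffled list is a snapshot),
  preventing within-step cascades.
* *A cell that migrates may still divide in the same step*, in that order.
* *Boundaries are periodic by default*; closed boundaries truncate
  neighborhoods, and a site outside a closed domain neither hosts daughters
  nor counts as empty space.
* All randomness flows through R's RNG, so a seed makes trajectories
  bit-reproducible, including from C++.

Two estimators connect simulations to the theory. `blocked_fraction()`
counts cells whose whole birth neighborhood is filled, normalized per cell
(the estimator of $\mathbb{E}[P(\omega\mid n)]$ entering the growth law) or
per lattice site (a convention used in some graphical summaries; per-cell is
the default because it is the quantity the theory needs).
`fractal_dimension_estimate()` inverts $n_s \propto n^{D/d}$ as
$\hat D = d \ln n_s / \ln n$; the scaling-prefactor is absorbed, which is
adequate for trend detection (the estimator's purpose here) but makes
individual values scale-dependent at small $n$.

`wellmixed_gillespie()` simulates the exact continuous-time birth–death
chain with per-capita birth rate $\lambda(1 - (n/l)^\omega)$, the stochastic
counterpart of the generalized logistic law. Its drift and diffusion are
estimated by `empirical_drift_diffusion()` from binned density increments.
Two biases matter and are handled explicitly: the window width must be short
relative to $1/|a'(u)|$ (finite-window bias), and the estimator measures the
*bin average* of $a(u)$, not its midpoint value — pass `drift_fun` to get
the matching bin-averaged reference.

## Fitting and model comparison

`fit_growth_law()` minimizes squared confluency residuals using the closed
forms, with Levenberg–Marquardt restarts from a fixed grid
($\lambda \in \{0.01, 0.1, 1\}$, $\bar\omega \in \{0.5, 2, 8\}$;
$g \in \{0.01, 0.1, 1\}$) so that fits are reproducible without stochastic
multistarts. $u_0$ is free by default because seeding confluency is noisy;
$\delta$ is fixed (default 0) because a free death rate is not identifiable
from a single saturating curve — pass `fit_delta = TRUE` to override.

Model comparison uses the least-squares AIC,
$n\ln(\mathrm{RSS}/n) + 2(k+1)$, counting the error variance as a
parameter. The comparison statistic is the ratio
$\mathrm{AIC}_\text{Gompertz}/\mathrm{AIC}_\text{gen.log.}$; with both AICs
negative, values above 1 favor Gompertz. The ratio is meaningless when the
AICs differ in sign, so `normalized_aic()` flags that case rather than
resolving it.

## What the synthetic data emulate — and what they do not

`generate_invitro_dataset()` stands in for a multi-line confluency
experiment: 7 lines, seeding levels $\{0.01, 0.05, 0.1, 0.2, 0.4\}$, 3
replicates, sampled every 4 h over 120 h. Per-line truths follow the
generalized logistic law with birth rates log-spaced over 0.05–0.25 per
hour and neighborhood sizes 1–8 — the range expected for cells on a 2D
substrate. Noise is multiplicative Gaussian (CV 2%, the scale of
imaging-derived confluency) plus a small additive floor (SD 0.002), clipped
to $[10^{-6}, 1]$. These curves share the statistical *structure* the
fitting pipeline assumes, not the biology of real lines: there is no
plate-edge effect, no density-dependent measurement bias, no
replicate-level growth-rate variation, and the true law really is
generalized logistic. Passing recovery tests therefore validates the
pipeline's correctness, not its robustness to model misspecification.

`generate_abm_dataset()` produces the in-silico counterpart: for each
$\omega \in \{4, 8, 12, 24\}$ the birth rate is set by the fixed product
$\lambda\omega = 0.1$ with $\delta = 0.001$, run well-mixed on a
$64 \times 64$ periodic lattice. Replicates are seeded at 1% confluency
rather than from a single cell: ensemble-averaging sigmoid curves that are
laterally jittered by early-time stochasticity flattens the mean curve and
biases fitted $\bar\omega$ downward, and at 1% seeding (the lowest
in-vitro level) the jitter is negligible while the growth range remains
wide. Fitting the mean curves and regressing $\ln\hat\omega$ on
$\ln\hat\lambda$ recovers the simulated trade-off.

## Competition

The two-subpopulation model couples the laws through *total* confluency
$u = u_1 + u_2$ in the saturation/logarithm term while each subpopulation
keeps its own $\lambda_i, \omega_i$:

$$\dot u_i = \lambda_i u_i (1 - u^{\omega_i}) - \delta u_i
\quad\text{or}\quad
\dot u_i = -\lambda_i \omega_i u_i \ln u - \delta u_i .$$

Shared-space coupling is the reading consistent with competition for one
pool of sites and with the observed phenomenology that a larger birth
neighborhood can compensate a lower birth rate: at the resident's steady
state $u^\*$, an invader grows iff
$\lambda_2 (1 - u^{\*\,\omega_2}) > \delta$, which is easier for larger
$\omega_2$. Whether the original two-type description coupled through total
density or through independent capacities is not printed anywhere we could
check; the choice is documented here as this package's model.
`invasion_outcome()` integrates to (numerical) equilibrium — maximum
derivative below $10^{-9}$, horizon-capped with a flag — and classifies by
the invader's asymptotic share with tolerance $10^{-3}$.

## Numerical choices

* ODE integration: `lsoda` at `rtol = 1e-8`, `atol = 1e-10`; closed forms
  and numerical solutions agree to $10^{-6}$ sup-norm in tests.
* The discontinuous exponential-saturating law is solved analytically
  (growth to 1, then a sliding state) instead of giving the integrator a
  discontinuous right-hand side.
* The generalized logistic closed form has a removable singularity at
  $\lambda = \delta$; a dedicated algebraic branch
  $u = (u_0^{-\bar\omega} + \lambda\bar\omega t)^{-1/\bar\omega}$ handles it.
* Occupancy probabilities for large lattices are evaluated as products of
  ratios (no factorial overflow up to at least $l = 10^6$). The exact mode
  for $l \le 64$ uses an internal arbitrary-precision integer type
  (base-$10^6$ digit vectors with a Pascal-triangle cache), so the pmf
  normalization and the enumeration-oracle comparisons are bit-exact
  rational identities, not floating-point approximations.
* Infeasible binomial configurations return probability 0 (the
  $\binom{a}{b} = 0$ for $b > a$ convention), keeping the pmf total over
  $x$.
* The first-order radial approximation $1 - d\,n^{-1/d}$ is clamped at 0
  where small $n$ would make it negative.

## Problem sizes

The test suite and the reproduction script run simulations at desk scale,
chosen so each check has clear statistical power while the whole suite
stays fast: $64 \times 64$ lattices with 10 replicate seeds for the ABM
regime checks and the $\lambda\omega$-recovery study, 20 Gillespie runs at
$l = 10^4$ for the mean-field and drift checks, 20 noise seeds for
parameter recovery, and the full 7-line synthetic design (105 series, two
fits each) for the AIC-trend replication. The exact-rational occupancy
sweep covers all $7896$ combinations of $l \le 64$, $n \le l$,
$\omega \in \{4, 8, 12, 24\}$.

## Limitations

The simulator is two-dimensional and ignores nutrient fields and cell–cell
adhesion; the occupancy theory covers only the no-migration and well-mixed
limits, with no pair-approximation corrections for intermediate migration;
the competition model is deterministic and mean-field (no stochastic clone
dynamics); and the synthetic data generators make no attempt to emulate
microscopy artifacts. AIC ratios are reported as defined even though their
interpretation degrades when fits are poor enough to flip the AIC sign —
the flag, not the number, should be trusted in that regime.
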