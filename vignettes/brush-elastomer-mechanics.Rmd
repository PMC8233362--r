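---
title: "Methods: mechanics of injectable bottlebrush elastomers"
author: "brushmech"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mechanics of injectable bottlebrush elastomers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brushmech)
```

## The constitutive model

Bottlebrush elastomers are networks of backbone strands densely grafted
with polymeric side chains. Grafting dilutes the stress-supporting
strands and pre-extends them, which is what lets these materials combine
gel-like softness with tissue-like strain stiffening. Uniaxial true
stress is modeled as

$$\sigma_{true}(\lambda) = \frac{E}{9}\left(\lambda^2-\lambda^{-1}\right)
\left[1 + 2\left(1-\frac{\beta(\lambda^2+2\lambda^{-1})}{3}\right)^{-2}\right]$$

with the elongation ratio $\lambda = L/L_0$. The two parameters have
distinct physical roles:

* the **structural modulus** $E$ (kPa) scales with crosslink density and
  sets the overall stress level;
* the **firmness** $\beta = \langle R_{in}^2\rangle / R_{max}^2 \in (0,1)$
  is the squared ratio of a strand's initial end-to-end distance to its
  contour length: strands that start closer to full extension stiffen
  sooner and harder.

Two derived quantities carry most of the practical meaning. The
**Young's modulus** (softness) is the initial slope,
$E_0 = (E/3)(1 + 2/(1-\beta)^2)$, and the **theoretical elongation at
break** is $\lambda_{max} = \beta^{-1/2}$, the stretch at which strands
reach their contour length. The model's stress diverges at the larger
*singular* elongation where $\beta(\lambda^2 + 2\lambda^{-1})/3 = 1$;
`lambda_sing()` locates it by bisection on $[1, 10/\sqrt\beta]$ to an
absolute tolerance of $10^{-10}$ (a closed-form cubic solution exists
but is messier and no faster at this scale). The package verifies
numerically, rather than assumes, that the singular elongation bounds
$\beta^{-1/2}$ from above.

Assumptions worth keeping in mind: the deformation is uniaxial and
quasi-static; the material is incompressible, so engineering stress
converts as $\sigma_{true} = \lambda\,\sigma_{eng}$ (curves declare
which stress they carry, and `as_true_stress()` converts explicitly);
compression ($\lambda < 1$) is admitted by the formula and returned as
negative stress with the same singularity guard. Stress is kPa
throughout the tensile interface; rheology moduli are Pa, matching the
instrument's axes — the conversion is never implicit.

## Fitting

`fit_constitutive()` minimizes
$\sum_i w_i(\sigma_{model}(\lambda_i; E, \beta) - \sigma_i)^2$ by
bounded Levenberg–Marquardt (minpack.lm) with $E > 0$ and
$\beta \in (10^{-6}, 1-10^{-6})$, at most 500 iterations and tight
(1e−15) step/function tolerances so that exact-model inputs are
recovered to near machine precision. Points that fall within 1 % of the
*current iterate's* singular elongation would produce unbounded
residuals; they instead contribute a large smooth quadratic penalty,
keeping the objective finite and differentiable. Residual weighting is
uniform by default; a relative option exists because measured curves
span roughly two decades of stress, and on exact-model curves the choice
is immaterial (this is tested). Starting values come from
`initial_guess()`: the small-strain slope (smallest-strain 20 % of
points, at least 3) estimates $E_0$, $\beta$ starts at
$\mathrm{clamp}(1/\lambda_{last}^2, 0.01, 0.9)$, and $E$ follows by
inverting the $E_0$ relation; a flat leading region falls back to the
global secant. The experimental elongation at break is defined as the
last recorded $\lambda$ — the input curve is assumed truncated at
rupture, and nothing is extrapolated.

Randomness enters fitting only through the Monte-Carlo
`recovery_study()`, which requires an explicit seed. At the study
conditions used by the tests (60-point curves, 2 % multiplicative noise,
200 replicates) the median relative error of both parameters is around
1–2 %.

## Gel-point detection

During cure the storage modulus $G'$ grows past the loss modulus $G''$;
the gel point is the crossover time. `find_gel_point()` works on
$d(t) = \log G' - \log G''$ and takes the **first sustained** sign
change — $d > 0$ for $\min(3, \text{remaining})$ consecutive samples —
so single-sample flickers from noise are skipped (and counted in
`n_crossings`). Whether a published crossover refers to the first or
only crossing in noisy data is generally unstated; first-sustained is
this package's convention. $t_{gel}$ is interpolated linearly in
(log-modulus, linear-time) coordinates within the bracketing pair,
because the moduli traverse decades during cure while the time grid is
linear; $G_{cross}$ is interpolated in log space at $t_{gel}$. Detection
is invariant to rescaling both moduli by a common constant. No smoothing
is applied by default; a 3-point running median is available for noisy
sweeps. Temperatures are kelvin internally; file interfaces accept
Celsius.

An all-liquid window ($G'' > G'$ throughout) and an all-solid window
($G' > G''$ throughout) raise distinguishable classed errors rather than
a generic failure, since they call for opposite experimental responses.

`tgel_trend()` summarizes cure-time trends across a formulation
variable. The functional forms behind published stoichiometry and
temperature correlations are not stated, so both a log–log (power-law)
and an Arrhenius ($\log t_{gel}$ vs $1/T$) model are offered and neither
is privileged. Duplicate covariate values are rejected as a degenerate
design.

## Texture profile analysis

The instrument literature names springiness, resilience, and
cohesiveness without fixing formulas; this package adopts the common
instrument-software conventions on the **force–time** signal (the area
basis is time, not displacement, because the measurement protocol
records force–time curves):

* cohesiveness $= (A_{2,down}+A_{2,up})/(A_{1,down}+A_{1,up})$,
* resilience $= A_{1,up}/A_{1,down}$,
* springiness $=$ (contact-to-peak time of cycle 2)/(cycle 1) —
  time-based; a distance-based variant exists in some software and is
  deliberately not implemented.

Segmentation (`segment_cycles()`) estimates the baseline as the median
of the low-level samples (within 1 % of full range above the force
floor), which makes it invariant to a constant offset; lobes above a 1 %
contact threshold are then extended outward to the baseline return, so
each cycle carries its full loading and unloading area under trapezoidal
integration. Exactly two cycles are required; any other count is an
error naming the detected number. All three metrics are invariant to
force rescaling and time shifts, and an ideal elastic trace scores
exactly (1, 1, 1).

## Scaling law, calibration, and inverse design

Theory predicts $E \cong 3k_BT\,(l^{3/2}/v^{3/2})\,\beta/(1+n_{sc})^{3/2}$.
The monomer volume $v$ has no established value for these copolymer
brushes, so the analytic prefactor is available only when the user
supplies $v$; the default mode calibrates the prefactor $C$ (kPa) as the
least-squares slope **through the origin** of $E$ against
$\beta/(1+n_{sc})^{3/2}$ over reference formulations
(`calibrate_scaling()`). Through-origin is chosen because the theory is
strictly proportional; whether the published correlation line carries an
intercept is unstated. Calibration is exactly scale-equivariant and
reports residuals and the Pearson correlation.

Inverse design (`propose_architectures()`) searches a grid of
$[n_x, n_{sc}]$ pairs. No closed form links $\beta$ to $n_x$, so the
packaged reference rows act as empirical anchors: $\beta(n_x)$ is
interpolated log-linearly in $n_x$ within each side-chain family, and
out-of-range grid points are clamped and flagged `extrapolated`. Each
candidate's structural modulus then comes from the calibrated scaling
law and its $E_0$ from the constitutive relation; candidates inside the
tolerance bands are ranked by summed relative error. The coupling
between a target $E_0$ and the $\beta$ the scaling law can deliver at a
given $n_{sc}$ is solved by a damped fixed-point iteration (damping 0.5,
tolerance $10^{-10}$, at most 100 iterations) and reported per $n_{sc}$
as `beta_required`, a feasibility diagnostic. The search itself is fully
deterministic. Crosslinking chemistry is carried as a label only — the
reference data show the mechanics are essentially chemistry-invariant,
and no chemistry-selection logic is attempted.

`match_tissue()` ranks candidate parameter sets against a target tissue
curve by root-mean-square *relative* deviation over the overlapping
admissible elongation range; published tissue curves are not shipped, so
a weakly strain-stiffening synthetic tissue (any `gen_tensile()` curve
with small $\beta$) stands in.

The packaged reference table (`reference_table()`, 11 formulations) is
shipped verbatim at its printed precision. Because its $E$ and $\beta$
cells are themselves rounded, recomputing the derived $E_0$ column can
land one rounding unit away from the printed cell in some rows;
`verify_table1()` therefore reports both the one-decimal match flag
(round-half-up, matching the table's printed convention — base R's
round-half-even cannot reproduce cells that sit on a half) and the
unrounded deviation, which stays within 0.3 kPa on every row. Two rows'
printed elongation columns are internally inconsistent with
$\beta^{-1/2}$ at one decimal for the same reason; they are flagged, not
"corrected".

## Synthetic data

The generators exist so that every analysis stage has inputs with known
ground truth:

* `gen_tensile()` forward-evaluates the equation of state on a uniform
  grid ending at $\beta^{-1/2}$ — where real specimens rupture — rather
  than at the model singularity. Multiplicative Gaussian noise (default
  2 % when enabled) reflects load-cell error scaling with load.
* `gen_rheology()` builds sigmoidal moduli
  $G'(t) = G'_\infty u(t)$, $G''(t) = G''_0 + (G''_\infty - G''_0)u(t)$
  with $u = t^h/(t^h + t_c^h)$, choosing $t_c$ in closed form so the
  curves intersect exactly at the requested $t_{gel}$; the construction
  is self-checked before returning. Additive noise is the default model,
  mimicking the instrument floor that dominates the liquid phase.
* `gen_tpa()` emits a piecewise-linear two-cycle force trace whose
  vertices are sample nodes, so trapezoidal areas equal the requested
  areas to machine precision and the closed-form metric ground truth is
  exact.

Noise magnitudes are conventions, not measured values — realistic levels
cannot be recovered from published figures. Every noisy generator
requires a seed and is bit-reproducible. What the generators do *not*
emulate: rupture artifacts and slack at grip engagement in tensile
records, secondary relaxation and drift in rheology, adhesion
(negative-force) tails and instrument compliance in TPA. Passing
recovery tests on these inputs therefore demonstrates correctness of the
estimators under the stated model, not robustness to every instrument
pathology.

## Problem sizes and limitations

The test suite and the acceptance script run at desk scale: 60-point
tensile curves, a 3×4 factorial noiseless recovery sweep, 200 noisy
replicates at one parameter point, 200-point rheology sweeps at three
cure times, and 25 samples per TPA segment — sizes chosen as the
smallest at which grid-resolution effects are negligible relative to the
tolerances being checked.

Known limitations: uniaxial only (no multiaxial or finite-element use of
the model); no viscoelastic fitting — curves are assumed quasi-static;
no cure-kinetics chemistry; no hardness/gumminess/chewiness TPA
variants; the spacer DP $n_g$ is named as an architectural parameter but
carried as metadata only, since no reference values exist to anchor it.

```{r example}
# end-to-end: generate, fit, verify
fit <- fit_constitutive(gen_tensile(E = 4.2, beta = 0.10, n_points = 60)$curve)
c(E = fit$params$E_struct, beta = fit$params$beta, E0 = fit$E0)
```
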