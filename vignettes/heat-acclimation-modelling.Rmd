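---
title: "Modelling biphasic heat-acclimation trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling biphasic heat-acclimation trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heatacclim)
```

## The scientific problem

When growing pigs are moved from thermoneutral conditions (around 22 °C) to a
multi-day heat challenge (32 °C), two responses unfold on different time
scales. Feed intake collapses within the first day and then gradually
recovers; core body temperature rises sharply and then gradually declines as
the animal acclimates, often ending below its prechallenge level
(heat-induced hypothermia). Both trajectories are *biphasic*: an acute phase,
an acclimation phase, and a plateau.

`heatacclim` models a daily trajectory $Y(d)$ (feed intake scaled by
metabolic body weight, in g/d/kg^0.60^, or daily-mean core temperature, in
°C) around a challenge starting at day $d = 0$ with a smooth two-threshold
broken-line function:

$$
Y(d) = y_0 + v_1 d
  - r_1 (v_1 - v_2)\,\mathrm{ln}\!\left[1 + e^{(d - td_1)/r_1}\right]
  - r_2 v_2\,\mathrm{ln}\!\left[1 + e^{(d - td_2)/r_2}\right]
$$

The curve has slope $v_1$ before the first threshold day $td_1$, slope $v_2$
between $td_1$ and the second threshold $td_2$, and slope 0 afterwards, so
the response plateaus once acclimation is complete. $y_0$ anchors the curve:
in the sharp-transition limit it is the value of $Y$ at day 0. The signs of
both ln-terms are fixed by requiring a zero terminal slope; with a positive
sign on the last term the curve would keep drifting after $td_2$, which
contradicts the plateau that motivates the model.

The smoothness parameters $r_1, r_2 > 0$ (in days) set the width of the
transitions. As $r_1, r_2 \to 0$ the curve converges to the piecewise-linear
broken stick (`acclim_curve_sharp()`), which the package uses both as a
verification oracle and as the scale on which derived summaries (extremum
value, earliest minimum day, end-of-window contrast) are unambiguous.

## Parameters and defaults

| Parameter | Meaning | Units | Default |
|---|---|---|---|
| `y0` | value at challenge onset (sharp limit) | g/d/kg^0.60^ or °C | estimated |
| `v1` | slope of the acute phase | units/d | estimated |
| `v2` | slope of the acclimation phase | units/d | estimated |
| `td1`, `td2` | threshold days (onset of acclimation, onset of plateau) | d | estimated, bounded to [0, 10] |
| `r1`, `r2` | transition smoothness | d | fixed at 0.25 |
| `sigma_r2` | between-animal intercept variance | units² | estimated |
| `sigma_e2` | residual variance | units² | estimated |

The smoothness values are not estimable with useful precision from 12 daily
means per animal, so they are fixed — at 0.25 d by default, shared across
temperature treatments (the transitions are treated as a property of the
variable, not of the treatment). A transition half-width of about half a day
is the natural scale for daily-averaged data: sharper values are
indistinguishable on an integer-day grid, and much larger values blur the
two phases together. `acclim_control(profile_r = TRUE)` instead profiles
$r_1 = r_2$ over {0.05, 0.1, 0.25, 0.5, 1.0} by maximised log-likelihood.

## The mixed model and its likelihood

Daily observations of animal $i$ are modelled as

$$ y_{ij} = Y(d_{ij};\,\theta_{g(i)}) + b_i + \varepsilon_{ij}, \qquad
   b_i \sim N(0, \sigma^2_r), \quad \varepsilon_{ij} \sim N(0, \sigma^2_e), $$

with one mean-parameter vector $\theta_g = (y_0, v_1, v_2, td_1, td_2)$ per
treatment group and a single additive random intercept per animal. The
random effect is placed on $y_0$ only: one between-animal variance is
reported per fit, and an animal-level shift of the whole trajectory is the
simplest structure consistent with that. Random slopes or multivariate
random effects are out of scope.

Because the random intercept is additive and Gaussian, each animal's vector
is multivariate normal with compound-symmetry covariance
$\sigma^2_e I + \sigma^2_r J$, and the marginal likelihood is available in
closed form — this is the reference implementation in `acclim_loglik()`. An
adaptive Gauss–Hermite quadrature path (default 9 nodes, centred at each
animal's conditional posterior mode) is kept as an independent cross-check;
for a Gaussian integrand adaptive quadrature is exact for any node count, so
closed form and quadrature must agree to numerical precision, which the test
suite asserts at 31 nodes.

Estimation is plain maximum likelihood (not REML). `fit_acclim()` maximises
the closed-form likelihood with `stats::nlminb()` over the per-group mean
parameters (natural scale, box constraints on the thresholds) and the two
variance components (log scale). Standard errors come from the inverse
observed information, computed by finite differences at the optimum.

### Initialisation and multi-start

The likelihood surface of breakpoint models is multimodal, so the fitter
starts from a deterministic lattice search: `(td1, td2)` pairs on a 0.25-d
grid, each solved for `(y0, v1, v2)` by ordinary least squares on the
sharp-limit basis, keeping the lattice minimiser of the residual sum of
squares. Four additional starts jitter this initialiser (5% relative noise
on linear parameters, ±0.75 d on thresholds) under a fixed seed; the best
final log-likelihood wins, with ties broken by the smallest parameter norm.
The fitter verifies that the final log-likelihood is at least the starting
value and flags the fit otherwise.

### Threshold bounds

Threshold days are constrained to [0, 10] by default (configurable via
`acclim_control(bounds = ...)`), while the fit window is days −1 to 10. Two
reasons. First, the thresholds are days of *exposure* to the challenge, which
are non-negative by definition. Second, with daily observations starting at
day −1, a threshold below 0 leaves a single observed day on the first
segment, so its slope is unidentified: in recovery simulations an unbounded
fit occasionally drifts onto degenerate ridge optima (threshold near −0.85,
absurdly steep $v_1$, collapsed $y_0$) that are genuine global maxima of the
unbounded likelihood but scientifically meaningless. Requiring at least two
design points per segment is the standard estimability condition in
segmented regression, and on this day grid it means $td_1 \ge 0$.

### Adjusted R²

`adjusted_r2()` implements
$1 - [\mathrm{SSE}/(n - p - 1)]/[\mathrm{CTSS}/(n - 1)]$. For mixed fits the
SSE uses *conditional* residuals — observed minus predicted with each
animal's empirical-Bayes intercept
$\hat b_i = \sigma^2_r \sum_j e_{ij} / (n_i \sigma^2_r + \sigma^2_e)$
plugged in — so between-animal variation captured by the random effect
counts as explained; marginal residuals would understate the fit badly
whenever $\sigma^2_r$ is comparable to $\sigma^2_e$. The parameter count $p$
is the number of estimated parameters (five mean parameters per group plus
the two variances).

### Group contrasts

`compare_acclim_groups()` tests each pairwise difference of each mean
parameter with a Wald z-statistic from the joint covariance, and summarises
the pattern with a compact letter display at level `alpha` (default 0.05):
groups sorted by estimate, each maximal run of mutually non-significant
groups sharing a letter.

## The synthetic cohort generator

No animal-level data accompany the published estimates, so the package
generates its own test beds at two levels.

`simulate_trajectories()` draws single-variable cohorts exactly under the
model's stochastic assumptions, using the built-in presets
(`acclim_presets()`): the published parameter estimates and variance
components for each variable × period × group fit. This pair —
generator plus fitter — is the package's parameter-recovery engine.

`simulate_study()` builds a whole 45-animal trial: five treatment groups
(TTT, HTT, THT, TTH, HHH) × three 15-day periods, with the challenged
group-periods following the matching preset curves and the repeatedly
challenged group (HHH) switching to its attenuated per-period presets, so
acclimation across repeated challenges is built in. Around the challenge
curves it adds:

* linear body-weight growth (default 1.2 kg/d from a 68.6 ± 4.3 kg start,
  matching the reported growth envelope), recorded on weigh days −3, 0, 5
  and 12 of each period with additive N(0, 0.5 kg²) weighing noise — the
  magnitude is a package choice motivated by gut-fill variation, not a
  published value;
* feed intake generated on the metabolic scale and multiplied back by
  interpolated BW^0.60^, so the pipeline's rescaling step is exercised
  nontrivially and round-trips exactly;
* a thermoneutral core-temperature baseline declining linearly with age
  (default −0.0045 °C/d, anchored at 38.82 °C the day before the first
  challenge). The published account only states that thermoneutral core
  temperature declines over the trial; the rate is a free configuration
  parameter chosen so the baseline meets the challenged groups' day −1
  levels across periods.

The thermoneutral feed-intake baseline is flat at the period preset's
day −1 level, $y_0 - v_1$. This is deliberate: $y_0$ is the *day-0* value,
after the acute drop has begun, so a baseline at $y_0$ would place
unchallenged animals ~20% below the challenged animals' own prechallenge
level and distort every percent-change summary; the $y_0 - v_1$ level keeps
unchallenged and prechallenge intake continuous and reproduces the reported
challenge-interval decreases in magnitude and ordering.

What the generator does **not** emulate: within-day temperature rhythms
(daily means only), respiratory rate, skin temperature, hormones,
within-animal autocorrelation beyond the shared intercept, non-Gaussian
noise, missing data, or mortality. Body-weight growth is also decoupled
from intake, so challenge effects on daily gain and feed:gain are *not*
reproduced by the generator — those worked summaries are validated against
the published interval means instead. Passing recovery tests therefore show
that the estimation machinery is correct under the model's own assumptions —
not that real trajectories satisfy those assumptions.

## The study pipeline

`assign_pools()` reproduces the per-period pooling of treatment groups with
identical room history (e.g. in P1 all not-yet-challenged groups pool to
"T", the two challenged groups to "H"). `interval_performance()` splits each
period into days [−3, 0), [0, 5) and [5, 12) and computes ADFI, ADG (from
boundary weigh days; the day-12 weight is the end-of-period weighing) and
feed:gain per pool, flagging intervals with missing boundary weights or
non-positive gain. `percent_change()` reports challenge decreases as
percentages of the prechallenge value, rounded half away from zero.
`daily_average()` collapses sub-daily sensor streams to the daily means the
model consumes, flagging days with low coverage.

## Numerical choices

* **Stable softplus.** $\ln(1 + e^x)$ is evaluated as
  $x + \ln(1 + e^{-x})$ for $x > 0$; a naive `exp` overflows for sharp
  transitions (small $r$), which the oracle tests exercise down to
  $r = 10^{-9}$.
* **Threshold separation.** A smooth quadratic penalty keeps
  $td_2 - td_1 \ge 0.1$ d during optimisation; coincident thresholds make
  $v_2$ unidentifiable.
* **Convergence.** Relative log-likelihood tolerance $10^{-8}$, maximum 500
  iterations; non-convergence flags the fit and suppresses standard errors.
* **Degenerate inputs.** Zero residual variance, non-positive smoothness,
  non-finite parameters and $td_1 \ge td_2$ are rejected with errors;
  summaries over windows that do not contain both thresholds are flagged
  undefined rather than extrapolated; a threshold estimate pinned at a
  bound raises a warning flag on the fit.
* **Ties.** The earliest-minimum day of a flat segment is its left endpoint,
  so a plateau minimum is dated at $td_2$ — the convention that makes "the
  trajectory reached its minimum at $td_2$" well defined.

## Problem sizes used by the tests

The recovery experiments fit 20 replicate cohorts of 18 animals × 12 days
per variable — the same cohort size as the published pooled first-period
fits — which bounds the Monte-Carlo error of mean estimates at roughly
SE/√20 while keeping a full test run around a minute. The group-contrast
error-rate checks use 6 (null) and 8 (alternative) replicates of two groups
of 18 animals; at the published group size of 9 the power for the
second-phase slope contrast is only ~50%, so the package checks
discrimination at a size where detection is expected in most replicates.
These sizes are package choices for its own quality checks, not re-creations
of the published analysis.

## Known limitations

* The model assumes a common $r_1 = r_2$ smoothness per variable and a
  single random intercept; heteroscedastic residuals and random slopes are
  explicitly out of scope.
* $y_0$, $v_1$ and $td_1$ are strongly correlated when $td_1$ is near 0
  (the acute drop happens between the only two prechallenge observations),
  so their individual standard errors are large even when the fitted curve
  is tight; interpret the curve, not single coordinates, in that regime.
* Derived summaries are defined on the sharp limit; on the smooth curve the
  response still changes slightly beyond $td_2$, so "day of minimum" is a
  convention, not a property of the smooth function.
* The generator's thermoneutral drift and weighing-noise magnitudes are
  configurable assumptions, not published values.
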