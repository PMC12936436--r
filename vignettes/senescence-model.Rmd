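---
title: "Modelling selection on senescence rate under Gompertz-Makeham mortality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling selection on senescence rate under Gompertz-Makeham mortality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(senesce)
```

## The model

Classic theory treats senescence-modifying genes as acting from a fixed age
of onset, so that selection on them is governed by how much reproduction
remains at that age. `senesce` instead models genes that act on the *shape*
of mortality throughout life. Mortality follows the Gompertz-Makeham hazard

$$\mu(x) = G\,e^{Rx} + M,$$

where `G` is the potential mortality risk from internal damage (the hazard
that damage contributes at age 0), `R` is the senescence rate (the
exponential pace of damage accumulation), and `M` is external,
age-independent mortality. All rates are per year and ages in years; the
unit is fixed to avoid silent mixing. `R = 0` encodes negligible
senescence: a constant hazard. Survival from birth is

$$l(x) = \exp\!\left(-\tfrac{G}{R}\left(e^{Rx}-1\right) - Mx\right),$$

with the constant-hazard limit $e^{-(G+M)x}$ at `R = 0`. The branch switch
happens below `R = 1e-10`, and the `R > 0` branch is written with `expm1`,
so the two branches join without cancellation — the test suite checks
continuity to `1e-6` across the age grid.

Reproduction starts at the maturity age `xs` and is, by default, a constant
rate `zeta` from then on (an arbitrary integrable rate function of age is
also accepted). Juvenile mortality is assumed independent of senescence and
over before `xs`; it enters only through the effective reproduction rate at
calibration (below).

### The truncation convention

Every age integral "to infinity" is evaluated by adaptive quadrature
(`stats::integrate`, relative tolerance `1e-10`) on `[lower, x_d]`, where
the *certain-mortality age* `x_d` solves `l(x_d) = 1e-4`. The same `x_d` is
the package's definition of "death" wherever a single age is needed (the
viability mask, the `Rmax` rule). The threshold is a modelling convention,
not a tolerance: quantities weighted towards old ages (for example the
$x^2$-weighted negligible-senescence limit) agree with their
improper-integral closed forms only to the fraction of mass beyond `x_d`
(about 0.5% there), and the tests account for that explicitly.

Two consequences of a *moving* truncation age are worth spelling out,
because they shape how identities are verified:

* Identities that hold for the improper integrals — "regulation through
  external mortality leaves selection on `R` unchanged", "the closed-form
  gradient equals the finite difference of fitness" — are checked on a
  *common* integration window (the `truncation_age` argument of `lrs()`,
  `euler_lotka_r()`, `dlrs_dR()` and `dr_dR()`). With the window recomputed
  on each side, both sides shift at the order of the threshold (`~1e-4`
  relative), which says nothing about the identity itself.
* `apply_density_dependence()`'s external-mortality regime refines the
  compensating increment by fixed-point iteration (one correction per step,
  since `dr/dM = -1`) until the regulated growth rate is zero under the
  adjusted history's *own* truncation age, rather than adding the
  unregulated `r` verbatim.

## Fitness and density dependence

Two fitness estimators are provided. For exponentially growing or declining
populations, the intrinsic growth rate `r` solves the Euler-Lotka equation

$$1 = \int_{x_s}^{\infty} e^{-rx}\, l(x)\, m(x)\, dx,$$

found by bracketed root search from `[-1, 1]` per year with geometric
expansion and Brent refinement to `1e-12` (the integrand's exponent is
capped at 200 during bracket probing: strongly negative trial rates would
otherwise overflow, and near the root the cap is never reached). For
populations held stationary by density dependence on reproduction, fitness
is the lifetime reproductive success

$$LRS = \int_{x_s}^{\infty} l(x)\, m(x)\, dx.$$

Four regimes connect the two: no regulation (use `r`); regulation through
reproduction, which divides `m` by the unregulated `LRS` so the stationary
population has `LRS = 1` (use `LRS`); regulation through external risk,
which absorbs the growth rate into `M` (use `r`; selection gradients are
then identical to the unregulated case, because `e^{-rx} l(x)` and the
`M`-inflated survival are the same function); and growing/declining
populations, whose reproduction is the reproduction-regulated schedule
times `theta` (defaults 10 and 0.1).

## Selection gradients

Differentiating the two estimators in the senescence rate gives the
closed forms implemented in `dlrs_dR()` and `dr_dR()`:

$$\frac{dLRS}{dR} = \frac{G}{R^2}\int_{x_s}^{\infty}
  \left(e^{Rx} - Rx\,e^{Rx} - 1\right) l\, m\, dx,
\qquad
\frac{dr}{dR} = \frac{G}{R^2}\,
  \frac{\int_{x_s}^{\infty}\left(e^{Rx} - Rx\,e^{Rx} - 1\right) e^{-rx} l\, m\, dx}
       {\int_{x_s}^{\infty} x\, e^{-rx} l\, m\, dx}.$$

The integrand factor is negative for `x > 0` (zero at `x = 0`), so faster
senescence never raises fitness; it is assembled in log space so that
`e^{Rx}` overflow is absorbed by the survival term instead of producing
`Inf * 0`. With constant reproduction, `m` vanishes below `xs`, so starting
the denominator at `xs` (as written) or at 0 is the same integral. Both
closed forms are verified against central finite differences of the
estimators on a common window, on the four bundled species and on fifty
randomized parameter sets, at relative tolerance `1e-4`.

As `R -> 0` the integrand factor tends to $-\tfrac{G}{2}x^2$;
`gradient_r0_limit()` evaluates that limit for either estimator, and for
constant reproduction it reproduces the closed form
$-\tfrac{G\zeta}{2} e^{-c x_s}\!\left(\tfrac{x_s^2}{c} + \tfrac{2x_s}{c^2}
+ \tfrac{2}{c^3}\right)$ with $c = G + M$ (up to the truncated tail noted
above). Selection does not vanish at `R = 0` unless `G` does.

Gradients for `G`, `M`, `xs` and `zeta` use central finite differences with
step `max(1e-6, 1e-4 |value|)` and one Richardson extrapolation level;
closed forms exist for special cases (LRS is linear in `zeta`) and are used
as test oracles rather than separate code paths. `hamilton_gradient()`
implements the classic sensitivity of `r` to a permanent additive mortality
increment from onset age `a`, for comparison with the shape-based
gradients. Note one property of the permanent-increment form: at `a = 0`
it equals `dr/dM = -1` exactly, and its magnitude declines *linearly* in
`a` below `xs` before tailing off — only the instantaneous-increment
variant is flat below maturity.

### The gradient curve under regulation

Profiles of selection against senescence rate (`run_gradient_profile()`)
and everything built on them treat each grid value of `R` as a *resident*
population regulated by the chosen scenario. Under regulation through
reproduction, the resident at rate `R` has its reproduction renormalised so
`LRS = 1`; the LRS gradient along that curve is therefore
`(dLRS/dR)/LRS` — the constant `zeta` cancels. This construction matters
for curvature: differentiating the *unregulated* `dLRS/dR` in `R` gives the
convexity of an exponentially decaying function (positive nearly
everywhere) and contradicts every published sign pattern, while the
regulated curve produces them all. The same per-resident regulation defines
the negligible-senescence surfaces: on the stationary-population scale,
selection for negligible senescence strengthens with later maturity.

## Evolutionary feedback

Feedback on senescence evolution is the second derivative of fitness in
`R`, computed by central differencing of the scenario-adjusted closed-form
first derivative (step `max(1e-5, 1e-3 R)`; a one-sided second-order scheme
anchored at the `R = 0` limit is used at the origin). Positive values mean
slowing senescence strengthens selection for slowing it further.
`mixed_derivative()` differentiates the same curve in `G`, `M`, `xs` or
`zeta`; smoothness makes the mixed derivatives symmetric, which the tests
confirm against reversed-order differencing (relative `1e-3`) and a
four-point stencil of LRS.

`feedback_map()` evaluates a chosen derivative over a parameter grid.
Cells where survival to `xs` falls to `1e-4` or below are masked: no
survivor reproduces, fitness is treated as zero, the derivative is `NA`.
For display, `log_modulus()` (`sign(v) log10(1 + |v|)`) compresses the
span of the values while preserving sign.

Two advisory closed-form conditions accompany the computed derivatives.
Near `R = 0`, positive feedback is expected when
`G > (M/2) exp(-0.12 xs)`. The printed source of this condition is
typographically ambiguous; the `(M/2)` reading is the default because it
matches the sign of the computed second derivative on at least 90% of a
log-uniform sample of `(G, M, xs)` (the `M^2` alternative, kept behind
`reading = "squared"`, agrees on barely 70%). Away from `R = 0`, positive
feedback is expected while `xs` is far from `x_d`, operationalised as
`xs < 0.5 x_d`; "close to `x_d`" in the tests means `xs > x_d / 1.3`.
These thresholds are advisory labels, never substitutes for the computed
derivatives.

## Trade-off and ESS

A single allocation `z` in `[0, 1]` couples senescence to reproduction:

$$R(z) = (R_{max} - R_{min})\,z^{\alpha} + R_{min}, \qquad
  \zeta(z) = (\zeta_{max} - \zeta_{min})\left(1 - (1-z)^{\beta}\right) +
  \zeta_{min}, \qquad \alpha, \beta \ge 1.$$

The ESS is the interior root of `dLRS/dz` with negative curvature,
assembled by the chain rule from `dlrs_dR()` and the linear
`zeta`-gradient, located by a sign scan plus root refinement to `1e-8` in
`z` (curvature by a central second difference, step `1e-4`). If fitness is
monotone along the trade-off the boundary optimum is reported and flagged
as not an ESS.

Defaults follow the published construction: `beta = 1`, `Rmin = 1e-4`,
`zeta_min = 0`, and `Rmax` from `rmax_rule()` — the senescence rate at
which the certain-mortality age equals `xs`, i.e. maturity just precedes
death under the global truncation convention. For constant reproduction
the ESS allocation is independent of `zeta_max` (the gradient condition
divides through by it), which breaks an otherwise circular dependency:
`fit_alpha()` searches `alpha` by brute force (grid `[1, 3]` step `0.01`,
refined to `0.001`) with a placeholder `zeta_max = 1`, and
`infer_zeta_max()` afterwards rescales the ceiling so the trade-off passes
through the observed `(R, zeta)`. At an interior ESS the fitted `alpha`
is also independent of `Rmax` — it satisfies
`alpha = -LRS / ((R - R_{min})\, dLRS/dR)` at the observed rate — which is
a useful cross-check on the brute-force search and the reason convention
choices for `Rmax` move the implied `zeta_max` but not the fitted shape.

## Calibration and synthetic data

`fit_gompertz_makeham()` estimates `(G, R, M)` from a life table by
nonlinear least squares on survivorship (not log-hazard: fitting the
survival curve is the stated construction, and the alternative would weight
the oldest, emptiest ages most). Observed survivorship is renormalised to 1
at the first age at or above `xs` and compared with the model survival
conditional on reaching that age, so juvenile mortality cannot bias the
adult fit. Levenberg-Marquardt (`minpack.lm`) runs from a 27-point
log-spaced multi-start grid and the best converged start wins. Noise-free
tables generated on an annual grid return the generating parameters to
machine precision; the identifiability tests require `1e-4` relative.

Juvenile mortality enters through the effective reproduction rate
`effective_reproduction_rate()`:
$\zeta = (1 - l(x_s) + l^*(x_s))\,\bar m$, where `l*` includes juvenile
deaths and $\bar m$ is the mean observed fecundity from `xs` on. The
printed source of this formula is also ambiguous; this additive reading is
the default because it reduces exactly to $\bar m$ when no extra juvenile
mortality occurred, while the ratio reading `l*/l * m` (kept behind
`adjustment = "ratio"`) is the other defensible parse. Both are tested.

`simulate_life_table()` generates tables with known truth. Deterministic
mode tabulates the closed-form survival on a grid (default step: 1 year,
an annual life table). Stochastic mode follows a cohort with binomial
deaths per interval and Poisson-sampled fecundity observations, optionally
with a constant extra juvenile hazard before `xs` producing the `lx_star`
column; a seed argument gives reproducible tables without touching the
caller's RNG state. The generator emulates the sampling noise of cohort
life tables — binomial thinning and fecundity counting error — and *not*
age-measurement error, heterogeneous frailty, time-varying environments or
the smoothing steps real databases apply; parameter-recovery results here
therefore bound what idealised cohort data can do, not what field data
will.

## Problem sizes and runtimes

The test suite runs the full brute-force fits for all four bundled species
(about 200 + 21 candidate `alpha` values each, with a 61-point ESS scan
per candidate), fifty randomized gradient cross-checks, and a
parameter-recovery study of 50 stochastic replicates at each cohort size
in `{1e3, 1e4, 1e5}`; the whole suite completes in well under a minute on
one CPU. The acceptance script repeats the fits and the limit evaluation
from scratch.

## Known limitations

* The hazard family is fixed: no Siler-type juvenile term inside the
  model, no age-varying `G` or `M`.
* Density dependence acts equally on all ages; no age-structured
  regulation, no stochastic demography.
* The trade-off couples `R` and `zeta` only; other parameter pairs are
  out of scope.
* The `G -> 0` limit of the senescence-rate gradient is demonstrated on a
  fixed demographic window (the reference organism's truncation age).
  With the truncation age recomputed per `G`, the numerical horizon
  recedes like `log(1/G)/R` and the truncated values grow with it; true
  convergence of the improper integral (driven by the `G^{M/R}` factor)
  only sets in at values of `G` far below double precision. On the fixed
  window the gradient is linear in `G` and the extrapolated limit is zero
  at machine precision — which is the statement the limit makes about the
  gradient, separated from the behaviour of the truncation device.
* Species-level numbers are demonstrations on four parameter sets, not
  comparative inference.
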