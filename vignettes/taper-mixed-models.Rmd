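---
title: "Multilevel mixed-effects stem taper models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multilevel mixed-effects stem taper models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(pinetaper)
```

## The model

`pinetaper` is built around the Kozak (2004) variable-exponent taper
equation.  For a tree with breast-height diameter $d$ (cm) and total height
$h$ (m), the over-bark diameter at stem height $h_i$ is

$$d_i = a_0\, d^{a_1} h^{a_2}\, x^{\,b_1 q^4 + b_2 e^{-d/h} + b_3 x^{0.1}
  + b_4/d + b_5 h^{w} + b_6 x},$$

with $q = h_i/h$, $w = 1 - q^{1/3}$, and
$x = (1 - q^{1/3})/(1 - (1.3/h)^{1/3})$.  The changing exponent lets one
smooth curve pass from the neiloid butt through the paraboloid mid-stem to
the conic top.  Two structural anchors matter throughout the package:
$x = 1$ at $h_i = 1.3$ m, so terms driven by powers of $x$ cannot move the
curve at breast height, and $x = 0$ at the tip, where we define $d_i = 0$
by convention (the limit for a positive exponent; a guard warns if the
exponent is non-positive there, where no finite limit exists).

The hierarchical extension gives each subject (plot $i$, tree $j$ within
plot) its own parameter vector $\beta + b_i + b_{ij}$, where only a chosen
subset of coefficients (`random`, typically `a1` and `b3`) carries random
effects:

$$b_i \sim N(0, D_p), \qquad b_{ij} \sim N(0, D_t), \qquad
  \varepsilon_{ijk} \sim N(0,\ \sigma^2 d_{ij}^{2\delta}),$$

optionally with continuous-AR(1) correlation
$\mathrm{corr}(\varepsilon_{ijk}, \varepsilon_{ijk'}) =
\phi^{|h_{ijk}-h_{ijk'}|}$ within a tree, the natural choice when sections
are unequally spaced.

A note on the variance function: the residual weight $g = d^\delta$
multiplies the residual *standard deviation* (the `varPower` convention),
so the variance is $\sigma^2 d^{2\delta}$.  With the packaged mixed-model
coefficient set ($\sigma^2 = 6.117\times10^{-3}$, $\delta = 0.7405$) this
yields a residual s.d. of $0.078 \times 24^{0.7405} \approx 0.82$ cm for a
24-cm tree, which is consistent with the set's reported ordinary-residual
variance of 0.6866; reading $g$ as a variance multiplier would imply an
implausible 0.25 cm.  The same convention is used in estimation, in the
calibration equations (there $R_i = \sigma^2 g^2 M_i$ per tree) and in the
synthetic-data generator.

## Estimation

`taper_fit()` offers three methods.

**OLS** minimizes the unweighted residual sum of squares by damped
Gauss-Newton with step halving, from the fixed default start
(`a0 = 1, a1 = 1, a2 = 0, b1..b6 = 0.1`) so that results are reproducible
without tuning.  $\sigma^2$ is reported as $SSE/(n-p)$.

**GLS** maximizes the Gaussian likelihood with the variance function and/or
CAR(1) correlation.  The coefficients are profiled out: for each candidate
$(\delta, \phi)$ the inner Gauss-Newton solves the whitened least-squares
problem (warm-started from the previous evaluation), $\sigma^2$ is profiled
analytically, and `optim(L-BFGS-B)` drives the two remaining parameters
($\phi$ through a logistic link onto $[0,1)$).

**FOCE** implements the first-order conditional expectation scheme for the
two-level nonlinear mixed model as an alternation of two steps
(Lindstrom-Bates style), which matches the definition of FOCE —
linearization about the *current* EBLUPs rather than about zero:

1. *Penalized nonlinear least squares.*  At fixed variance parameters,
   minimize over $(\beta, \{b_i\}, \{b_{ij}\})$ the criterion
   $\sum \lVert y - f \rVert^2_{R^{-1}} + \sum b' D^{-1} b$.  Each
   Gauss-Newton step is solved through the mixed-model equations
   plot-by-plot — the update for the stacked effects is exactly the EBLUP
   formula $b = D Z' V^{-1}(u - X\,\delta\beta)$ with
   $V_i = Z_i D Z_i' + R_i$ — with step halving on the penalized
   objective.  Because $\sigma^2$ scales both $D$ and $R$, the inner
   problem only needs the variance parameters on the $\sigma^2$-relative
   scale.
2. *Working linear mixed model.*  At the current $(\hat\beta, \hat b)$ the
   model is linearized, $w = y - f + X\hat\beta + Z\hat b$, and the
   profiled ML or REML deviance of $w = X\beta + Zb + \varepsilon$ is
   minimized over the variance parameters with `optim(L-BFGS-B)`,
   warm-started from the previous outer iteration.  Both $\beta$ and
   $\sigma^2$ are profiled analytically, leaving only the two log-Cholesky
   factors of $D_p/\sigma^2$ and $D_t/\sigma^2$ (three numbers each for
   two random terms), $\delta$, and optionally $\phi$.

The outer loop stops when the deviance changes by less than $10^{-8}$
relative between iterations (cap 200); an additional absolute tolerance of
$10^{-6}$ on the $-2\log L$ change stops the loop when the criterion merely
oscillates at numerical noise level, which this class of models is known to
do.  Starting values: OLS estimates for $\beta$ (computed internally unless
`start` is given), $D_p/\sigma^2 = D_t/\sigma^2 = 0.01 I$ on the
transformed scale, $\delta = 0.5$, $\phi = 0.5$.  The log-Cholesky
parameterization keeps both covariance matrices positive semidefinite by
construction; a variance collapsing toward zero simply drives its
log-diagonal toward the box bound, producing a boundary fit rather than a
failure.

Derivatives of the taper function with respect to coefficients — the $X$
and $Z$ matrices — are central finite differences with step
$10^{-6}\max(1, |\theta|)$.  The same machinery serves any active-parameter
subset, and because random effects enter additively in the coefficients,
the columns of $Z$ are identical to the corresponding columns of $X$
evaluated at the subject's current parameters.

REML is reported as the REML criterion of the working linearized model at
convergence, the standard FOCE interpretation.  AIC and BIC use
$k = p + 1 + [\delta] + [\phi] + 2\cdot n_r(n_r+1)/2$.  Likelihood-ratio
tests in `anova()` use the naive $\chi^2$ reference also for
boundary variance components, which is conservative; REML fits with
different fixed structures are refused.

The implementation was cross-checked against `nlme::nlme` on synthetic
data (single-random-parameter configuration, where `nlme` converges
reliably): log-likelihoods agree to $10^{-4}$ and fitted population curves
to about 0.01 cm.  `nlme` serves only as a test oracle; all estimation
code here is self-contained.

## Calibration

For a new plot with trees carrying at least one extra diameter measurement,
`calibrate()` iterates the multilevel EBLUP update

$$\hat b = \hat D Z_i'(Z_i \hat D Z_i' + \hat R_i)^{-1}
  [\,y_i - f(x_i, \hat\beta, \hat b) + Z_i \hat b\,]$$

from $\hat b = 0$ until the largest absolute update falls below $10^{-8}$
(cap 100).  $\hat D$ is block-diagonal — one plot block, one tree block per
tree — and $Z_i$ repeats the plot-effect columns across all rows with
tree-effect blocks on the block diagonal, so several trees of one plot
share the estimation of the plot effect exactly as the block structure
dictates; the single-tree-new-plot case is the same code with one block.
$Z$ is re-evaluated at the current effects on every pass (FOCE-consistent);
`update_z = FALSE` holds the first linearization for users who prefer the
one-shot approximation.  When the expanded coefficient enters the
prediction linearly (e.g. `a0`), the update converges in one step to the
closed-form BLUP, which the tests verify against hand algebra, and for
small systems the fixed point is verified against direct numerical
minimization of the penalized criterion.

`calibration_sweep()` repeats, for every evaluation tree and every measured
section, a single-section calibration followed by prediction of all
remaining sections and of total stem volume, pooling errors by the relative
height of the calibrating section (0.1-wide classes by default).  Empty
classes are reported as missing rather than zero.  Predicted volumes
integrate from the first measured section to the tip — the same interval
the observed volume covers (frustums between sections plus a terminal
cone) — so the comparison is like-for-like; whether "total" volume should
instead start at ground level is exposed through the `lower` argument of
the volume functions rather than decided silently.  In the per-class RMSE
the fixed-parameter count is apportioned to cells in proportion to their
share of observations, which makes the group-wise $RMSE_g^2(n_g - p_g)$
identity with the pooled statistic exact; cells smaller than their share
are reported unpenalized.

## Responses and evaluation statistics

Three response types are compared with the same two statistics,
$RMSE = \sqrt{\sum (y - \hat y)^2 / (n - p)}$ and
$\bar e\% = 100\,\overline{(y - \hat y)}/\bar y$: the mean response M
(fixed parameters only), the population-averaged response PA (Monte-Carlo
mean over the random-effects distribution: effects drawn once from
$N(0, D_p + D_t)$, 2000 draws by default, shared across evaluation points
and reproducible by seed), and subject-specific responses SS at plot or
tree level.  PA uses plain Monte Carlo rather than quadrature: two
correlated bivariate levels would make Gauss-Hermite four-dimensional,
while the MC error is controllable and scales as $1/\sqrt{n_{draws}}$
(verified empirically).  PA volumes exploit that the random-effects average
and the height integral commute, integrating the pointwise MC average of
$\pi (d_i/200)^2$.  The denominator penalty $p$ is the fixed-parameter
count for all response types — no random-effect penalty is charged — and is
configurable.

## Sensitivity envelopes

`taper_envelope()` shows how much stem shape varies across the estimated
random-effects distribution for a probe tree.  In separate mode each
expanded coefficient is set to normal quantiles of its summed plot- plus
tree-level marginal variance (a new tree is the sum of two independent
draws) with the others at zero.  In joint mode effect vectors are drawn
from $N(0, D_p + D_t)$ with the full covariance and the band is the
pointwise empirical quantile of the simulated curve ensemble.  The
ensemble reading was chosen over evaluating curves at multivariate
"quantile parameters" because pointwise quantiles respect the correlation
structure, which is the entire motivation for the joint analysis; both
readings exist in the literature and the alternative is noted here
deliberately.  Structural facts the tests assert: bands driven by `b3`
alone pinch to zero width at breast height (the $x = 1$ anchor), and bands
nest with their probability levels.

Where the joint band pinches depends entirely on the correlation between
the expanded coefficients.  If the `a1` and `b3` effects are strongly
negatively correlated, every simulated curve crosses the mean response
near one height ($u \ln d + v\, x^{0.1}\ln x \approx 0$ at a common
$x$ when $u/v$ is nearly constant) and the band necks there, around
one-third of tree height for a mid-sized tree.  With the packaged
whole-data covariance, however, the combined correlation is only
$+0.04$, and the band width instead shows a shallow minimum near the
breast-height anchor — where the dominant `b3` effect is pinned — and
tapers to zero only at the tip.  Users analysing their own fits should
therefore read the joint envelope together with the estimated
correlation rather than expect a mid-stem waist in general.

## The synthetic-data generator

`simulate_taper_data()` emulates the study design the packaged coefficient
sets come from: 70 plots of 6 felled trees by default.  Design choices,
fixed once:

* **DBH**: lognormal with meanlog 3.071 and sdlog 0.415 (mean 23.5 cm,
  s.d. 10.2 cm), resampled into the observed 6.5-56.9 cm range.
* **Height**: $h = 1.3 + 1.01\, d^{0.8}$ with lognormal noise (sdlog
  0.12), resampled into 3.6-29.5 m.  The study reports no height-diameter
  law; any smooth allometry spanning the observed ranges serves, and this
  one reproduces the observed mean height (13.9 m) at the mean DBH.
* **Sections**: a stump section at Uniform(0.03, 0.40) m, then log ends at
  uniform increments of 0.3-2.5 m, capped at an eighth of the stem span so
  short stems still produce full schedules, stopping 0.3 m below the tip
  and capped at 24 sections.  Generated per-tree counts stay within the
  observed 7-24 range.
* **Measurement rounding**: recorded `d_i` to 0.1 cm and `h_i` to 0.01 m,
  like the field protocol (switchable off for numerical tests).
* Negative simulated diameters (possible near the tip at high noise) are
  truncated at zero and counted in attribute `n_truncated`.

True subject effects are returned alongside the data, which makes the
parameter-recovery harness (`recovery_experiment()`) straightforward:
generate, fit, compare, report bias, empirical SE, coverage and
convergence failures.

What passing recovery tests show — and what they do not: the generator
reproduces the *assumed* statistical structure exactly, so recovery
demonstrates internal consistency of estimation, calibration and
evaluation, not robustness to the ways real stems deviate from the model
(local swellings and knots, non-Gaussian tails, crew measurement habits,
sociological-class differences).  Conclusions about real forests still
require real stem analysis data, such as the public 420-tree Asturias
dataset the packaged coefficient sets were estimated from; the acceptance
tests that reproduce those published estimates run only when a local copy
of that file is supplied (`options(pinetaper.s1_dataset = ...)`), since it
is not redistributed here.

## Numerical choices and problem sizes

Volumes integrate $\pi (d_i(t)/200)^2$ with `stats::integrate` at absolute
tolerance $10^{-8}$ m³, well below the 4-significant-figure volumes of
interest; the quadrature is tested against a $10^6$-panel midpoint Riemann
sum.  Merchantable height brackets the upper, monotone-decreasing crossing
by scanning 512 grid points from the tip downward and refines it with
`uniroot` (tolerance $10^{-10}$); a top diameter above the whole profile
returns `NA`.  Duplicate section heights within a tree are an error on
ingest, not averaged, because cross-measurements are averaged upstream in
this kind of protocol.  Heights are metres, diameters centimetres, volumes
cubic metres everywhere; unit conversion happens only inside the volume
routines.

The test-suite problem sizes were chosen to exercise every code path at
desk scale: shared fixtures use 12 plots of 4 trees, the oracle comparisons
15 plots of 4 trees, and the acceptance checks run one full-scale study
(70 plots x 6 trees, about 5,700 sections) plus ten replicate fits at that
scale for parameter recovery.  A full-scale FOCE fit takes roughly half a
minute on one CPU.

## Known limitations

* FO (expansion about zero), Laplacian, adaptive quadrature and MCMC
  estimation are out of scope; FOCE is the only mixed-effects scheme.
* Standard errors come from the observed information of the working
  linearized model, as usual for FOCE, and share its approximations.
* The CAR(1) coefficient is weakly identified when random effects already
  absorb most within-tree correlation; expect flat likelihoods there.
* `random` applies the same expansion at both levels, mirroring the
  published analysis; level-specific expansions are not supported.
* Bark thickness and alternative taper functions are not modelled.
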