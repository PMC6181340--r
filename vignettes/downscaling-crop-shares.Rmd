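---
title: "Downscaling administrative crop shares to pixels: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Downscaling administrative crop shares to pixels: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cropdown)
```

## The problem

Crop harvested areas are reported by administrative units — states or
provinces (Level 1), sometimes districts or counties (Level 2) — while
the biophysical drivers of where crops grow (growing-season temperature
and precipitation, elevation, soil pH and carbon, slope) are available
on a fine latitude/longitude grid, typically 5 arc-minute cells of
roughly 100 km² at the equator.  `cropdown` estimates the *fraction of
each pixel* devoted to each crop from data observed only at the unit
level, by exploiting within-unit variation in the pixel covariates.

## Model

Let $y_{jk}$ be the observed fraction of land in unit $j$ devoted to
category $k$, with $k = 1$ the base category ("any other land use") and
$\sum_k y_{jk} = 1$.  The unobserved pixel-level fraction has
conditional mean modelled as a multinomial logit in transformed
covariates $W_{ij}$:

$$G_{ijk} = \frac{\exp(W_{ij}\beta_k)}{\sum_{l=1}^{K}\exp(W_{ij}\beta_l)},
\qquad \beta_1 \equiv 0 ,$$

where pinning $\beta_1 = 0$ identifies the remaining $K-1$ coefficient
vectors relative to the base allocation.  Because the outcome is only
observed at the unit level, the pixel mean is aggregated by area
weighting over the $I_j$ pixels of unit $j$:

$$H_{jk} = \frac{\sum_{i \in I_j} G_{ijk} A_{ij}}{\sum_{i \in I_j} A_{ij}},$$

with $A_{ij}$ the pixel's land area.  Coefficients maximize the
multinomial quasi-log-likelihood

$$L(\beta) = \sum_j \sum_k y_{jk} \log H_{jk}(\beta).$$

Maximizing $L$ is consistent for $\beta$ whenever the conditional mean
$H$ is correctly specified, regardless of the true distribution of the
shares — the defining property of quasi-maximum likelihood in the
linear exponential family.  No distributional model of $y$ around $H$
is required (or assumed) by the estimator.

Inference uses the robust sandwich covariance
$A^{-1} B A^{-1} / J$ with $A = \frac1J \sum_j \nabla^2 L_j$ and
$B = \frac1J \sum_j s_j s_j'$, where $s_j$ is the score contribution of
unit $j$ — the administrative unit is the independent sampling block.
The averaged (per-unit) normalization of $A$ and $B$ is a convention;
any consistent pairing gives the identical product, and the convention
used is recorded in serialized fits.  A unit-level block bootstrap
(resample units with replacement, carry all pixels of each sampled
unit, refit) is provided as a cross-check and agrees closely with the
sandwich standard errors in the package's acceptance runs.

## Design terms and marginal effects

The design `W(X)` is built from explicit terms — linear, square,
interaction, hinge pair `max(pivot − x, 0)` / `max(x − pivot, 0)`
(used for soil pH around the agronomic optimum 6.5, allowing an
asymmetric response), and 0/1 group indicators (e.g. country) that
absorb political and economic factors that do not vary within a group.
Indicator columns are shared across crops like any other column.

Marginal effects propagate through the chain rule: the derivative of
the linear index with respect to a fundamental covariate collects every
term containing it, and the multinomial-logit Jacobian
$\partial G_k / \partial \eta_{k'} = G_k(1\{k = k'\} - G_{k'})$ maps
index changes to share changes.  Effects therefore sum to zero over
categories at every pixel.  Reported values are unweighted means over
the included (non-excluded) pixels; area-weighted averaging is
available as an option.  At a hinge pivot the derivative of both hinge
terms is taken to be 0 (a subgradient choice — measure-zero and
documented).  Group indicators are reported as discrete changes (mean
share with the indicator on minus at the base level), not derivatives.
Odds ratios are `exp(beta)` exactly for covariates entering through a
single linear term; for covariates in squares or interactions the
local log-odds derivative varies by pixel and the per-pixel
`exp(d eta / d x)` is averaged.

## Prediction, rescaling, validation

Predictions evaluate the fitted logit at any pixel table carrying the
design covariates.  To reproduce observed unit totals exactly, pixel
fractions are rescaled per unit and crop by $r_{jk} = y_{jk}/H_{jk}$;
a pixel pushed above 1 is capped at 1 with a warning quantifying the
unit's shortfall — the simplest transparent rule; no redistribution is
attempted, and since scaling is per-crop independent the scaled grid
is calibrated crop by crop rather than as a joint composition.
Validation compares unit-level aggregates of the predictions with
observed shares via the RMSE, the calibration regression, and the
squared Pearson correlation; Level-2 comparisons on a Level-1-scaled
grid are genuinely out of sample because Level-2 data never enter the
estimation.  The calibration regression is run as observed-on-predicted
(the direction under which "intercept 0, slope 1" is the 45° line with
predictions on the horizontal axis); the opposite direction is
available via a switch.  The constant-share baseline
(`naive_allocation()`) assigns every pixel its Level-2 unit's observed
share and is the natural benchmark: a model adds value only through
within-unit variation.

## Geometry and filters

Pixel areas use the spherical-quadrilateral formula
$A = R^2\,\Delta\lambda\,(\sin\varphi_{top} - \sin\varphi_{bot})$ with
the mean Earth radius $R = 6371$ km — a documented convention.  Grid
cells are half-open $[lo, hi)$ aligned to the graticule starting at
$(-90, -180)$, so a centre on a boundary belongs to exactly one cell;
coarse-to-fine covariate transfer (`block_downscale()`, e.g. 30′ → 5′)
assigns every fine cell its parent coarse value (36 fine cells per
coarse cell).  Urban and protected pixels are excluded before
estimation; a unit losing all pixels is an error.  Sample selection
keeps units with at least 0.5% of land in every crop of interest
(inclusive — "at least" — at the boundary) and drops units whose
listed crop shares sum above 1.

## The synthetic generator

Because the real census and biophysical inputs cannot be redistributed,
all testing runs on a seeded generator that emulates their structure:
pixels nested in Level-1 units with nested Level-2 districts, unit
latitude/longitude placement, cell areas from the geometry, exclusion
flags, and bounded covariates with realistic continental-scale
presets (means, SDs, bounds for temperature, precipitation, elevation,
pH deviations, soil carbon, slope by region).  Each covariate is drawn
from a scaled Beta distribution moment-matched to the preset mean and
SD within the preset bounds; a Gaussian copula with intra-unit
correlation `icc` (default 0.3) gives each unit a random level, so
covariates cluster spatially within units as real biophysical fields
do.  The Beta family was chosen because a truncated normal cannot
reach strongly skewed bound-hugging cases (e.g. a pH deviation with
mean 0.03 and SD 0.10 on [0, 0.64]) while the Beta family can match
any feasible mean/SD pair exactly.

Observed shares are either the exact model aggregates (`noise =
"none"`, giving a zero-noise recovery target) or Dirichlet draws
$y_j \sim \text{Dirichlet}(c \cdot H_j)$, whose mean is exactly $H_j$
— so the estimator's single substantive assumption (correct
conditional mean) holds by construction and the concentration $c$
controls signal-to-noise.  The Dirichlet is a *testing device* at the
unit level, not a claim about real census noise.  Defaults are chosen
once as the package's study conditions: 196 units (a continental-scale
single-crop sample), 6–20 pixels per unit, exclusion rate 5%,
concentration 500.

What passing tests do **not** show about real data: the generator
draws covariates independently of one another (real biophysical
variables are correlated), has no spatial autocorrelation beyond the
unit intercept, no reporting gaps or year mismatches, and its true
model is exactly the fitted one — so recovery results certify the
estimator and its implementation, not the model's adequacy for any
particular landscape.

## Numerical choices

* Softmax rows are computed with a log-sum-exp shift; linear
  predictors up to |700| are safe.
* Optimization: BFGS ascent from $\beta = 0$ (the uniform-share model,
  a neutral always-feasible start) with the analytic score, relative
  tolerance $10^{-14}$, up to 4 restarts, followed by damped Newton
  polishing using the finite-difference Hessian of the analytic score;
  convergence requires gradient max-norm below `tol` (default
  $10^{-6}$).  During line searches the objective floors $H$ at the
  smallest normal double so extreme trial steps stay finite.
* The Hessian for the sandwich uses central differences of the
  analytic score with step $10^{-5}\max(1, |\beta_m|)$ — a fully
  analytic Hessian adds complexity without measurable benefit at
  these problem sizes.
* Rank-deficient designs are refused up front (QR rank check) and a
  near-singular information matrix (condition number above $10^{10}$)
  is an error pointing to collinearity.
* Divergence past $|\beta| > 10^3$ is treated as separation and
  reported as an error rather than returned.
* Parameters are stored flat, crop-major ($\beta_2$ block, then
  $\beta_3$, ...), so covariance indexing is unambiguous.
* `0 · log(anything) = 0` in the quasi-log-likelihood: categories a
  unit does not report contribute exactly nothing.

## Problem sizes used by the test-suite

The suite exercises the estimator at the sizes its claims are stated
for: noiseless recovery and noise studies at $J = 200$ units
($\approx 2{,}500$ pixels, $K = 2$, $M = 4$); 100 Dirichlet replicates
for the 3-SE recovery check; 200 block-bootstrap replicates for the
sandwich comparison; the consistency probe runs 30 replicates at each
of $J \in \{25, 100, 400\}$.  Small algebraic oracles (finite
differences, the fractional-logit reduction, hand-computed RMSE and
calibration cases) run at 2–60 units.

## Known limitations

* Rescaled ("calibrated") grids are per-crop; after capping, crop sums
  per pixel need not equal 1.
* The observed share denominators are taken as given in the share
  table; whether they derive from total unit land or non-excluded land
  is an upstream question the package does not arbitrate.
* No panel / correlated-random-effects variant; no raster (GeoTIFF)
  import or export — interfaces are delimited text.
* Hinge-variable effects are validated against finite differences
  of the model, not against any external nonlinear-effect tabulation.
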