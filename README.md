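# cropdown

Statistical downscaling of administrative crop statistics to pixels.

Crop harvested areas are reported for states and provinces; the
biophysical factors that determine *where inside* a state the crops
grow — growing-season temperature and precipitation, elevation, soil
pH and carbon, slope — are available on a 5 arc-minute grid.
`cropdown` bridges the two supports with an **aggregated fractional
multinomial logit**: the share of pixel *i* (unit *j*) in crop *k* is

    G_ijk = exp(W_ij b_k) / sum_l exp(W_ij b_l),     b_1 = 0,

the unit-level mean is the area-weighted aggregate

    H_jk = sum_i G_ijk A_ij / sum_i A_ij,

and the coefficients maximize the multinomial quasi-log-likelihood

    L(b) = sum_j sum_k y_jk log H_jk(b)

of the observed unit shares `y_jk` — consistent whenever the
conditional mean is correctly specified, whatever the true share
distribution.  The package provides the estimator (BFGS with analytic
score plus Newton polish), sandwich and unit-block-bootstrap
covariances, average marginal effects and odds ratios through
quadratic/interaction/hinge terms, pixel prediction with per-unit
rescaling to observed totals, RMSE/calibration/R² validation at two
administrative levels, a constant-share baseline, and a seeded
synthetic-landscape generator so everything is testable without any
restricted data.

Intended users: agricultural economists, land-use and integrated
assessment modellers who need gridded crop allocations (or the
marginal effect of a biophysical driver on allocation) where only
administrative statistics exist.

## Worked example

Simulate a landscape of 60 states with known coefficients, fit the
model, and validate the downscaled predictions:

```r
library(cropdown)

cfg  <- synthetic_config(J = 60, seed = 4, noise = "dirichlet",
                         concentration = 500)
land <- simulate_landscape(cfg)     # pixels nested in units, covariates
y    <- simulate_shares(land, cfg)  # observed unit-level shares

fit <- fit_qmle(y, land, cfg$design)
fit
#> Aggregated fractional multinomial logit (QMLE)
#>   crops: other, maize (base: other)
#>   units: 60   pixels: 758   parameters: 4
#>   log-quasi-likelihood: -14.703841   converged: TRUE (|grad| = 3.75e-12, 114 evals)

tidy(fit)
#> # A tibble: 4 × 5
#>   crop  term          estimate std.error statistic
#>   <chr> <chr>            <dbl>     <dbl>     <dbl>
#> 1 maize (Intercept)    -5.08     0.148      -34.2
#> 2 maize temperature     0.0789   0.00684     11.5
#> 3 maize precipitation   0.508    0.106        4.82
#> 4 maize soil_carbon     0.106    0.0120       8.78
```

The estimates sit near the generator's truth (−5, 0.08, 0.5, 0.1), and
each t-value (estimate / robust SE) reads as in any regression table.
Downscale, rescale to the observed state totals, and validate out of
sample at the district level:

```r
grid   <- predict_pixels(fit)                       # raw pixel fractions
scaled <- scale_to_level1(grid, y, crops = "maize") # match state totals
y2     <- simulate_shares(land, cfg, level = "unit_l2")
level2_report(scaled, y2[y2$crop == "maize", ])
#> # A tibble: 1 × 13
#>   level crop    rmse intercept slope se_intercept se_slope t_intercept_0
#>   <dbl> <chr>  <dbl>     <dbl> <dbl>        <dbl>    <dbl>         <dbl>
#> 1     2 maize 0.0172    0.0123 0.873      0.00294   0.0375           4.2
#> # ... with t_slope_1 -3.4, r_squared 0.77, n_units 164
```

RMSE is in share units (fractions of district land); an intercept near
0 and slope near 1 mean the predictions track the 45° line; `r_squared`
is the squared correlation between predicted and observed district
shares.  Marginal effects and odds ratios per covariate:

```r
marginal_effects(fit)     # d share / d covariate, averaged over pixels
odds_ratios(fit)          # exp(beta) for linear-entry covariates
autoplot(fit)             # coefficient plot with 95% Wald intervals
```

Published coefficient tables can be deployed without refitting via
`qmle_fit_from_coefficients()`; see
`inst/extdata/maize_model_coefficients.csv` for a continental-scale
maize example whose linear-entry odds ratios (soil carbon 1.170,
elevation 0.940, ...) the acceptance suite reproduces.

A shell pipeline mirroring the above (`simulate`, `fit`, `predict`,
`scale`, `effects`, `validate`, `report` subcommands):

```sh
cli=$(Rscript -e 'cat(cropdown::cropdown_cli_path())')
Rscript $cli simulate --J 60 --seed 4 --out-pixels px.csv --out-shares y.csv
Rscript $cli fit --pixels px.csv --shares y.csv --out fit.rds
Rscript $cli predict --fit fit.rds --pixels px.csv --out grid.csv
```

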