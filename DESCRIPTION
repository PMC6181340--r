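Package: cropdown
Title: Downscaling Administrative Crop Shares to Pixels via Aggregated
    Fractional Multinomial Logit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates pixel-level crop-share surfaces from crop area
    fractions observed only at the administrative-unit level.  Pixel
    shares follow a multinomial logit in biophysical covariates; the
    unit-level mean is the area-weighted aggregate of pixel shares, and
    parameters are estimated by quasi-maximum likelihood with analytic
    gradients.  Includes sandwich and block-bootstrap covariance
    estimators, average marginal effects and odds ratios (with
    quadratic, interaction and hinge terms), per-crop rescaling of
    predictions to match observed unit totals, validation metrics
    (RMSE, calibration regression, squared correlation) at two
    administrative levels, and a seeded synthetic-landscape generator
    for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
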