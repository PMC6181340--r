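# Descriptive statistics of the biophysical covariates by region
# (growing-season temperature in deg C, precipitation in m/yr, elevation
# in km, soil-pH hinge deviations around 6.5, soil carbon in kg/m^2,
# slope index, latitude in degrees), used as realistic generator presets.
covariate_preset_table <- function() {
  tibble::tribble(
    ~region,           ~variable,       ~mean,   ~sd,    ~min,    ~max,
    "north_america",   "temperature",   16.660,  6.087,  1.833,  28.667,
    "north_america",   "precipitation",  0.813,  0.361,  0.068,   3.258,
    "north_america",   "elevation",      0.569,  0.601, -0.227,   3.704,
    "north_america",   "ph_below",       0.466,  0.617,  0.000,   2.300,
    "north_america",   "ph_above",       0.342,  0.466,  0.000,   1.665,
    "north_america",   "soil_carbon",    6.351,  2.895,  1.608,  22.356,
    "north_america",   "slope",          0.056,  0.065,  0.003,   0.375,
    "north_america",   "latitude",      37.326,  9.612, 14.625,  56.792,
    "central_america", "temperature",   23.474,  2.514, 15.833,  27.500,
    "central_america", "precipitation",  2.256,  0.739,  1.142,   4.678,
    "central_america", "elevation",      0.674,  0.609, -0.197,   3.300,
    "central_america", "ph_below",       0.611,  0.422,  0.000,   1.400,
    "central_america", "ph_above",       0.030,  0.101,  0.000,   0.640,
    "central_america", "soil_carbon",    6.900,  1.740,  3.984,  12.724,
    "central_america", "slope",          0.134,  0.088,  0.003,   0.375,
    "central_america", "latitude",      13.263,  2.156,  7.292,  16.042,
    "south_america",   "temperature",   22.493,  3.967, -0.167,  28.500,
    "south_america",   "precipitation",  1.181,  0.494,  0.000,   5.667,
    "south_america",   "elevation",      0.564,  0.709, -0.132,   4.783,
    "south_america",   "ph_below",       0.690,  0.609,  0.000,   1.869,
    "south_america",   "ph_above",       0.194,  0.392,  0.000,   1.563,
    "south_america",   "soil_carbon",    5.147,  1.646,  1.325,  13.183,
    "south_america",   "slope",          0.054,  0.065,  0.003,   0.375,
    "south_america",   "latitude",     -18.537, 11.908, -40.958, 11.458
  )
}

#' Covariate presets for the synthetic landscape generator
#'
#' Per-region means, standard deviations and bounds of the biophysical
#' covariates (continental-scale growing-season climate, terrain and
#' soil summaries).  The `latitude` row is used for unit placement, the
#' others for covariate simulation.
#'
#' @param region `"north_america"`, `"central_america"` or
#'   `"south_america"`.
#' @return A tibble `variable`, `mean`, `sd`, `min`, `max`.
#' @export
covariate_preset <- function(region = c("north_america", "central_america",
                                        "south_america")) {
  region <- match.arg(region)
  tb <- covariate_preset_table()
  tb[tb$region == region, -1L]
}

# Shape parameters of the Beta distribution on [lo, hi] matching a
# target mean and sd exactly.  Errors when no Beta distribution on the
# interval has those moments.
beta_match <- function(mean, sd, lo, hi) {
  if (!(hi > lo)) abort("infeasible bounds: max must exceed min")
  m <- (mean - lo) / (hi - lo)
  s <- sd / (hi - lo)
  if (m <= 0 || m >= 1 || s <= 0 || s^2 >= m * (1 - m)) {
    abort(sprintf(
      "infeasible covariate bounds: no distribution on [%g, %g] has mean %g and sd %g",
      lo, hi, mean, sd
    ), class = "cropdown_infeasible_bounds")
  }
  nu <- m * (1 - m) / s^2 - 1
  list(shape1 = m * nu, shape2 = (1 - m) * nu)
}

#' Configuration for the synthetic landscape generator
#'
#' Bundles the study conditions for a simulated estimation problem:
#' the number of Level-1 units, pixels per unit, crop categories, the
#' covariate preset, the true coefficients, and the noise model linking
#' observed unit shares to their model means.
#'
#' Covariates are drawn from scaled Beta distributions moment-matched
#' to the preset mean/SD within the preset bounds, with a Gaussian
#' copula giving each unit a random level (intra-unit correlation
#' `icc`), emulating the spatial clustering of biophysical conditions
#' inside administrative units.  Observed shares are either the exact
#' model aggregates (`noise = "none"`) or Dirichlet draws centred on
#' them (`noise = "dirichlet"`, concentration `c` — the mean is
#' preserved, so the QMLE remains correctly specified).
#'
#' @param J Number of Level-1 units (default 196, a continental-scale
#'   single-crop sample).
#' @param pixels_per_unit Integer range (min, max) of pixels per unit.
#' @param K Number of crop categories including the base (default 2).
#' @param crops Crop names, base first; defaults to
#'   `c("other", "maize", "soybeans", "wheat")[1:K]`.
#' @param region Covariate preset region.
#' @param design A [design_spec()]; default intercept + linear
#'   temperature, precipitation and soil carbon.
#' @param beta_true Free-coefficient matrix (M x K-1) or vector
#'   (K = 2); a default consistent with the default design produces
#'   unit crop shares of a few percent.
#' @param noise `"dirichlet"` (default) or `"none"`.
#' @param concentration Dirichlet concentration (default 500).
#' @param exclusion_rate Fraction of pixels flagged urban/protected.
#' @param icc Intra-unit correlation of the covariate copula.
#' @param seed Integer seed.
#'
#' @return A `synthetic_config` object (a list).
#' @export
synthetic_config <- function(J = 196, pixels_per_unit = c(6, 20), K = 2,
                             crops = NULL,
                             region = "north_america",
                             design = NULL, beta_true = NULL,
                             noise = c("dirichlet", "none"),
                             concentration = 500,
                             exclusion_rate = 0.05, icc = 0.3,
                             seed = 1L) {
  noise <- match.arg(noise)
  stopifnot(J >= 2, length(pixels_per_unit) == 2L,
            pixels_per_unit[1] >= 1,
            pixels_per_unit[2] >= pixels_per_unit[1],
            K >= 2, icc >= 0, icc < 1,
            exclusion_rate >= 0, exclusion_rate < 1)
  if (noise == "dirichlet" && !(is.numeric(concentration) && concentration > 0)) {
    abort("dirichlet concentration must be > 0")
  }
  crops <- crops %||% c("other", "maize", "soybeans", "wheat")[seq_len(K)]
  stopifnot(length(crops) == K)
  design <- design %||% design_spec(
    term_linear("temperature"), term_linear("precipitation"),
    term_linear("soil_carbon")
  )
  if (is.null(beta_true)) {
    # default: shares of a few percent, responsive to all covariates
    b <- c(-5, 0.08, 0.5, 0.1)
    M <- length(design$terms) + design$intercept
    if (M != length(b)) {
      abort("supply beta_true for non-default designs")
    }
    beta_true <- matrix(rep(b, K - 1L), ncol = K - 1L)
    if (K > 2L) {
      # separate the crops so multi-crop fits are identified
      for (k in 2:(K - 1L)) {
        beta_true[, k] <- beta_true[, k] * (1 + 0.15 * (k - 1)) -
          c(0.5 * (k - 1), rep(0, M - 1L))
      }
    }
  }
  if (is.null(dim(beta_true))) beta_true <- matrix(beta_true, ncol = K - 1L)
  stopifnot(ncol(beta_true) == K - 1L)
  structure(
    list(J = J, pixels_per_unit = as.integer(pixels_per_unit), K = K,
         crops = crops, region = region, design = design,
         beta_true = beta_true, noise = noise,
         concentration = concentration,
         exclusion_rate = exclusion_rate, icc = icc,
         seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat(sprintf(
    "<synthetic_config> J=%d units, %d-%d pixels/unit, K=%d (%s), region=%s,\n  noise=%s%s, exclusion_rate=%g, icc=%g, seed=%d\n",
    x$J, x$pixels_per_unit[1], x$pixels_per_unit[2], x$K,
    paste(x$crops, collapse = ","), x$region, x$noise,
    if (x$noise == "dirichlet") sprintf("(c=%g)", x$concentration) else "",
    x$exclusion_rate, x$icc, x$seed
  ))
  invisible(x)
}

#' Simulate a pixel landscape
#'
#' Generates a pixel table with the structure the estimator assumes:
#' pixels nested in Level-1 units (with nested Level-2 sub-units), 5'
#' cell areas from the unit's latitude, bounded covariates with a
#' unit-level random component, and urban/protected exclusion flags.
#' Fully reproducible given the config seed.
#'
#' @param config A [synthetic_config()].
#' @return A pixel tibble: `pixel_id`, `unit_l1`, `unit_l2`, `lat`,
#'   `lon`, `area_km2`, `excluded`, plus one column per preset
#'   covariate.
#' @export
simulate_landscape <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  preset <- covariate_preset(config$region)
  lat_row <- preset[preset$variable == "latitude", ]
  covs <- preset[preset$variable != "latitude", ]

  withr::with_seed(config$seed, {
    J <- config$J
    unit_ids <- sprintf("u%03d", seq_len(J))
    npix <- sample(seq(config$pixels_per_unit[1], config$pixels_per_unit[2]),
                   J, replace = TRUE)
    unit_lat <- runif(J, lat_row$min, lat_row$max)
    unit_lon <- runif(J, -125, -35)
    n <- sum(npix)
    uidx <- rep(seq_len(J), npix)

    px <- tibble::tibble(
      pixel_id = sprintf("px%06d", seq_len(n)),
      unit_l1 = unit_ids[uidx],
      unit_l2 = NA_character_,
      lat = pmin(pmax(unit_lat[uidx] + runif(n, -0.5, 0.5), -89.9), 89.9),
      lon = unit_lon[uidx] + runif(n, -0.5, 0.5)
    )
    # 2-4 nested Level-2 districts per unit
    nl2 <- sample(2:4, J, replace = TRUE)
    px$unit_l2 <- paste0(px$unit_l1, "_d",
                         unlist(lapply(seq_len(J), function(j) {
                           sample.int(nl2[j], npix[j], replace = TRUE)
                         })))
    px$area_km2 <- pixel_area(px$lat)
    px$excluded <- runif(n) < config$exclusion_rate

    z_unit <- matrix(rnorm(J * nrow(covs)), J)
    for (v in seq_len(nrow(covs))) {
      row <- covs[v, ]
      sh <- beta_match(row$mean, row$sd, row$min, row$max)
      z <- sqrt(config$icc) * z_unit[uidx, v] +
        sqrt(1 - config$icc) * rnorm(n)
      px[[row$variable]] <- row$min + (row$max - row$min) *
        stats::qbeta(pnorm(z), sh$shape1, sh$shape2)
    }
    px
  })
}

#' Simulate observed unit shares from a landscape
#'
#' The forward model: pixel shares from the multinomial logit at the
#' true coefficients, aggregated to Level-1 (and Level-2) units by
#' area weighting over non-excluded pixels; observed shares are either
#' these aggregates exactly (`noise = "none"`) or Dirichlet draws
#' centred on them, `y_j ~ Dirichlet(c * H_j)`, whose mean is `H_j` —
#' so the estimator's conditional-mean assumption holds by
#' construction.
#'
#' @param pixels A pixel table from [simulate_landscape()] (or any
#'   table with the design covariates, areas and unit memberships).
#' @param config A [synthetic_config()]; its design, true coefficients,
#'   crops, noise model and seed are used unless overridden.
#' @param level `"unit_l1"` (default) or `"unit_l2"`.
#' @param noise,concentration,seed Optional overrides of the config.
#'
#' @return A long share tibble: `unit_l1` (or `unit_l2`), `crop`,
#'   `share`; shares sum to 1 within each unit.
#' @export
simulate_shares <- function(pixels, config, level = "unit_l1",
                            noise = NULL, concentration = NULL,
                            seed = NULL) {
  stopifnot(inherits(config, "synthetic_config"),
            level %in% c("unit_l1", "unit_l2"))
  noise <- noise %||% config$noise
  concentration <- concentration %||% config$concentration
  seed <- seed %||% (config$seed + 1L)
  if (noise == "dirichlet" && !(is.numeric(concentration) && concentration > 0)) {
    abort("dirichlet concentration must be > 0")
  }
  px <- if ("excluded" %in% names(pixels)) {
    apply_exclusions(pixels, quiet = TRUE)
  } else {
    pixels
  }
  W <- build_design(px, config$design)
  G <- pixel_shares(W, config$beta_true, config$crops)
  H <- agg_shares_matrix(G, px$area_km2, px[[level]])

  y <- if (noise == "none") {
    H
  } else {
    withr::with_seed(seed, {
      gm <- matrix(rgamma(length(H), shape = concentration * H),
                   nrow = nrow(H))
      gm / rowSums(gm)
    })
  }
  out <- tibble::tibble(
    unit = rep(rownames(H), times = ncol(H)),
    crop = rep(config$crops, each = nrow(H)),
    share = as.vector(y)
  )
  names(out)[1] <- level
  dplyr::arrange(out, .data[[level]], .data$crop)
}
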