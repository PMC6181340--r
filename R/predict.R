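# Align a freshly built design matrix with the column layout of a fit.
# Indicator levels absent from the new data become all-zero columns
# (those pixels sit in other groups); columns the fit has never seen are
# an error, as no coefficient exists for them.
align_design <- function(W, terms) {
  extra <- setdiff(colnames(W), terms)
  if (length(extra) > 0L) {
    abort(sprintf("design columns not present in the fitted model: %s",
                  paste(extra, collapse = ", ")),
          class = "cropdown_unseen_level")
  }
  miss <- setdiff(terms, colnames(W))
  if (length(miss) > 0L) {
    W <- cbind(W, matrix(0, nrow(W), length(miss),
                         dimnames = list(NULL, miss)))
  }
  W[, terms, drop = FALSE]
}

#' Predict pixel-level crop fractions
#'
#' Evaluates the fitted multinomial logit at each pixel of `pixels`
#' (which may be the estimation sample or any other grid carrying the
#' design covariates).  Fractions are strictly inside (0,1) and sum to
#' one over crops within each pixel; aggregating the predictions on the
#' estimation pixels reproduces the fitted unit shares exactly.
#'
#' @param fit A [fit_qmle()] object.
#' @param pixels Pixel table; defaults to the estimation pixels.
#'   Must carry every design covariate, plus `pixel_id`, `unit_l1` and
#'   `area_km2`/`lat` (carried through for later scaling and area
#'   conversion).
#'
#' @return A long tibble (`pixel_id`, `unit_l1`, optionally `unit_l2`,
#'   `crop`, `raw_fraction`, `area_km2`), the raw prediction grid.
#' @export
predict_pixels <- function(fit, pixels = NULL) {
  stopifnot(inherits(fit, "qmle_fit"))
  pixels <- pixels %||% fit$problem$pixels
  if ("excluded" %in% names(pixels)) {
    pixels <- apply_exclusions(pixels, quiet = TRUE)
  }
  if (!"area_km2" %in% names(pixels)) {
    pixels$area_km2 <- pixel_area(pixels$lat)
  }
  W <- align_design(build_design(pixels, fit$design), fit$terms)
  G <- pixel_shares(W, fit$beta_mat, fit$crops)
  n <- nrow(pixels)
  out <- tibble::tibble(
    pixel_id = rep(pixels$pixel_id, times = fit$problem$K),
    unit_l1 = rep(pixels$unit_l1, times = fit$problem$K),
    crop = rep(fit$crops, each = n),
    raw_fraction = as.vector(G),
    area_km2 = rep(pixels$area_km2, times = fit$problem$K)
  )
  if ("unit_l2" %in% names(pixels)) {
    out <- tibble::add_column(out,
      unit_l2 = rep(pixels$unit_l2, times = fit$problem$K),
      .after = "unit_l1")
  }
  out
}

#' Rescale pixel predictions to match observed unit totals
#'
#' Within each Level-1 unit j and crop k, all pixel fractions are
#' multiplied by `r_jk = y_jk / H_jk`, the ratio of the observed unit
#' share to the area-weighted aggregate of the raw predictions, so that
#' the aggregated scaled fractions equal the observed shares exactly.
#' A pixel whose scaled fraction would exceed 1 is capped at 1 (with a
#' warning quantifying the unit's resulting shortfall); no
#' redistribution is attempted.  Scaling is per-crop independent: the
#' scaled grid is calibrated crop by crop and pixel-level sums across
#' crops are no longer exactly 1.
#'
#' @param grid A raw prediction grid from [predict_pixels()] or
#'   [naive_allocation()].
#' @param observed Observed share table (`unit_l1`, `crop`, `share`)
#'   covering every unit in the grid for each crop being scaled.
#' @param crops Crops to scale; default all crops present in `observed`.
#'
#' @return The grid with a `scaled_fraction` column added (restricted to
#'   the scaled crops).
#' @export
scale_to_level1 <- function(grid, observed, crops = NULL) {
  stopifnot(is.data.frame(grid), is.data.frame(observed),
            all(c("unit_l1", "crop", "share") %in% names(observed)))
  fcol <- intersect(c("raw_fraction", "fraction"), names(grid))[1]
  if (is.na(fcol)) abort("grid has no raw fraction column")
  crops <- crops %||% intersect(unique(grid$crop), unique(observed$crop))
  g <- grid[grid$crop %in% crops, , drop = FALSE]

  H <- aggregate_shares(
    dplyr::rename(g, fraction = dplyr::all_of(fcol)),
    level = "unit_l1"
  ) |> dplyr::rename(unit_l1 = "unit", H = "share")

  miss <- dplyr::anti_join(H, observed, by = c("unit_l1", "crop"))
  if (nrow(miss) > 0L) {
    abort(sprintf("no observed share for unit/crop: %s",
                  paste(paste(miss$unit_l1, miss$crop, sep = "/"),
                        collapse = ", ")),
          class = "cropdown_missing_observed")
  }
  ratio <- H |>
    dplyr::inner_join(observed[, c("unit_l1", "crop", "share")],
                      by = c("unit_l1", "crop")) |>
    dplyr::mutate(r = .data$share / .data$H)
  if (any(!is.finite(ratio$r))) {
    abort("aggregated raw fraction is 0 for a unit/crop; cannot scale",
          class = "cropdown_zero_aggregate")
  }
  out <- g |>
    dplyr::left_join(ratio[, c("unit_l1", "crop", "r")],
                     by = c("unit_l1", "crop")) |>
    dplyr::mutate(scaled_fraction = pmin(.data[[fcol]] * .data$r, 1))

  capped <- out$scaled_fraction < out[[fcol]] * out$r - 1e-15
  if (any(capped)) {
    short <- out |>
      dplyr::summarise(
        shortfall = sum((.data[[fcol]] * .data$r - .data$scaled_fraction) *
                          .data$area_km2) / sum(.data$area_km2),
        .by = c("unit_l1", "crop")
      ) |>
      dplyr::filter(.data$shortfall > 1e-15)
    warn(sprintf(
      "%d pixel fraction(s) capped at 1; aggregate shortfall by unit/crop: %s",
      sum(capped),
      paste(sprintf("%s/%s %.4g", short$unit_l1, short$crop,
                    short$shortfall), collapse = ", ")
    ))
  }
  dplyr::select(out, -"r")
}

#' Convert crop fractions to harvested areas
#'
#' A pixel's harvested area in a crop is its land area times its crop
#' fraction; unit totals are sums over member pixels and are additive
#' across nesting levels (Level-2 totals within a Level-1 unit sum to
#' the Level-1 total).
#'
#' @param grid A prediction grid with `area_km2` and a fraction column
#'   (`scaled_fraction` if present, else `raw_fraction`/`fraction`).
#'
#' @return The grid with a `harvested_km2` column.
#' @seealso [harvested_totals()]
#' @export
harvested_area <- function(grid) {
  fcol <- intersect(c("scaled_fraction", "raw_fraction", "fraction"),
                    names(grid))[1]
  if (is.na(fcol)) abort("grid has no fraction column")
  if (!"area_km2" %in% names(grid)) abort("grid has no area_km2 column")
  dplyr::mutate(grid, harvested_km2 = .data[[fcol]] * .data$area_km2)
}

#' @rdname harvested_area
#' @param level Unit column to total over (`"unit_l1"` or `"unit_l2"`).
#' @return `harvested_totals()`: tibble `unit`, `crop`, `harvested_km2`.
#' @export
harvested_totals <- function(grid, level = "unit_l1") {
  stopifnot(level %in% names(grid))
  harvested_area(grid) |>
    dplyr::summarise(harvested_km2 = sum(.data$harvested_km2),
                     .by = dplyr::all_of(c(level, "crop"))) |>
    dplyr::rename(unit = dplyr::all_of(level)) |>
    dplyr::arrange(.data$unit, .data$crop)
}

#' Naive constant-share baseline allocation
#'
#' The benchmark allocation that assigns every pixel the observed share
#' of its enclosing Level-2 unit — a piecewise-constant surface with no
#' within-unit variation.  Aggregating it back to Level 2 returns the
#' input shares.
#'
#' @param level2_shares Observed Level-2 share table (`unit_l2`, `crop`,
#'   `share`).
#' @param pixels Pixel table with `unit_l2` membership for every pixel.
#'
#' @return A prediction grid (`pixel_id`, `unit_l1`, `unit_l2`, `crop`,
#'   `raw_fraction`, `area_km2`).
#' @export
naive_allocation <- function(level2_shares, pixels) {
  stopifnot(is.data.frame(level2_shares),
            all(c("unit_l2", "crop", "share") %in% names(level2_shares)))
  if (!"unit_l2" %in% names(pixels) || any(is.na(pixels$unit_l2))) {
    bad <- if ("unit_l2" %in% names(pixels)) {
      pixels$pixel_id[is.na(pixels$unit_l2)]
    } else {
      pixels$pixel_id
    }
    abort(sprintf("pixel(s) without a Level-2 unit: %s%s",
                  paste(head(bad, 10L), collapse = ", "),
                  if (length(bad) > 10L) ", ..." else ""),
          class = "cropdown_missing_unit")
  }
  if ("excluded" %in% names(pixels)) {
    pixels <- apply_exclusions(pixels, quiet = TRUE)
  }
  if (!"area_km2" %in% names(pixels)) {
    pixels$area_km2 <- pixel_area(pixels$lat)
  }
  out <- tidyr::crossing(
    pixels[, intersect(c("pixel_id", "unit_l1", "unit_l2", "area_km2"),
                       names(pixels))],
    crop = unique(level2_shares$crop)
  ) |>
    dplyr::left_join(level2_shares[, c("unit_l2", "crop", "share")],
                     by = c("unit_l2", "crop"))
  if (any(is.na(out$share))) {
    bad <- unique(out$unit_l2[is.na(out$share)])
    abort(sprintf("no Level-2 share for unit(s): %s",
                  paste(head(bad, 10L), collapse = ", ")),
          class = "cropdown_missing_observed")
  }
  dplyr::rename(out, raw_fraction = "share") |>
    dplyr::relocate("pixel_id", "unit_l1", "unit_l2", "crop",
                    "raw_fraction", "area_km2")
}
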