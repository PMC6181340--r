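#' Spherical area of a latitude/longitude grid cell
#'
#' Area of the cell of width `resolution` arc-minutes centred at
#' `lat_center`, on a sphere of radius 6371 km:
#' `A = R^2 * d_lambda * (sin(phi_top) - sin(phi_bottom))`.
#' Cells shrink towards the poles (about 86 km^2 at the equator for 5'
#' cells, near zero at the poles) and are symmetric in +/- latitude.
#'
#' @param lat_center Latitude(s) of the cell centre, degrees in \[-90, 90\].
#' @param resolution Cell width in arc-minutes (default 5).
#'
#' @return Cell area(s) in km^2.
#' @examples
#' pixel_area(0)        # ~85.9 km^2
#' pixel_area(45)       # ~60.7 km^2
#' @export
pixel_area <- function(lat_center, resolution = 5) {
  stopifnot(is.numeric(lat_center), is.numeric(resolution),
            length(resolution) == 1L, resolution > 0)
  half <- resolution / 120         # half cell height, degrees
  if (any(!is.finite(lat_center)) || any(abs(lat_center) + half > 90 + 1e-12)) {
    abort("grid cell crosses a pole: |lat_center| + resolution/120 must be <= 90",
          class = "cropdown_pole_cell")
  }
  dlam <- (resolution / 60) * pi / 180
  top <- (lat_center + half) * pi / 180
  bot <- (lat_center - half) * pi / 180
  EARTH_RADIUS_KM^2 * dlam * (sin(top) - sin(bot))
}

# Index of the half-open graticule cell [lo, lo + size) containing a
# coordinate; the graticule starts at (-90, -180).
grid_cell_index <- function(coord, origin, size) {
  as.integer(floor((coord - origin) / size + 1e-9))
}

#' Assign coarse-grid values to fine pixel centres
#'
#' Covariates available only on a coarse grid (e.g. 30 arc-minute climate
#' and soil layers) are downscaled to the fine pixel grid by constant
#' assignment: every fine cell whose centre falls inside a coarse cell
#' inherits that cell's value.  A full 30' cell covers 36 5' cells.
#' Cells are half-open `[lo, hi)` aligned to the global graticule
#' starting at (-90, -180), so centres on a boundary belong to exactly
#' one coarse cell.
#'
#' @param coarse A data frame of coarse cells: columns `lat`, `lon` (cell
#'   centres, degrees) plus one or more value columns.
#' @param pixels A pixel table with `lat`, `lon` centre columns (and
#'   optionally `pixel_id` for error messages).
#' @param coarse_resolution Coarse cell width in arc-minutes (default 30).
#'
#' @return `pixels` with the coarse value columns appended.
#' @export
block_downscale <- function(coarse, pixels, coarse_resolution = 30) {
  stopifnot(is.data.frame(coarse), is.data.frame(pixels),
            all(c("lat", "lon") %in% names(coarse)),
            all(c("lat", "lon") %in% names(pixels)))
  value_cols <- setdiff(names(coarse), c("lat", "lon"))
  if (length(value_cols) == 0L) abort("coarse grid has no value columns")
  size <- coarse_resolution / 60

  key <- function(lat, lon) {
    paste(grid_cell_index(lat, -90, size), grid_cell_index(lon, -180, size))
  }
  ck <- key(coarse$lat, coarse$lon)
  if (anyDuplicated(ck)) abort("duplicate coarse cells for the same grid cell")
  fk <- key(pixels$lat, pixels$lon)
  idx <- match(fk, ck)
  if (anyNA(idx)) {
    bad <- which(is.na(idx))
    ids <- if ("pixel_id" %in% names(pixels)) {
      pixels$pixel_id[bad]
    } else {
      paste("row", bad)
    }
    abort(sprintf(
      "%d fine pixel(s) fall outside the coarse grid coverage: %s%s",
      length(bad), paste(head(ids, 10L), collapse = ", "),
      if (length(bad) > 10L) ", ..." else ""
    ), class = "cropdown_uncovered_pixel")
  }
  out <- pixels
  for (vc in value_cols) {
    vals <- coarse[[vc]][idx]
    if (any(is.na(vals))) {
      bad <- which(is.na(vals))
      abort(sprintf(
        "coarse value '%s' is missing for the cell covering pixel(s): %s",
        vc,
        paste(head(if ("pixel_id" %in% names(pixels)) pixels$pixel_id[bad]
                   else paste("row", bad), 10L), collapse = ", ")
      ), class = "cropdown_missing_coarse_value")
    }
    out[[vc]] <- vals
  }
  tibble::as_tibble(out)
}

#' Drop urban / protected pixels
#'
#' Removes pixels flagged `excluded` (built-up land, protected areas)
#' before estimation and prediction, reporting how many pixels each unit
#' lost.  A unit whose pixels are all excluded cannot be modelled and is
#' an error.
#'
#' @param pixels Pixel table with logical column `excluded` and `unit_l1`.
#' @param quiet Suppress the per-unit removal message.
#'
#' @return The pixel table restricted to `excluded == FALSE`.
#' @export
apply_exclusions <- function(pixels, quiet = FALSE) {
  stopifnot(is.data.frame(pixels), "excluded" %in% names(pixels),
            "unit_l1" %in% names(pixels))
  excl <- as.logical(pixels$excluded)
  if (anyNA(excl)) abort("excluded flag contains missing values")
  units_all <- unique(pixels$unit_l1)
  kept <- pixels[!excl, , drop = FALSE]
  lost <- setdiff(units_all, unique(kept$unit_l1))
  if (length(lost) > 0L) {
    abort(sprintf("unit(s) with all pixels excluded cannot be modelled: %s",
                  paste(lost, collapse = ", ")),
          class = "cropdown_empty_unit")
  }
  if (!quiet && any(excl)) {
    removed <- table(pixels$unit_l1[excl])
    inform(sprintf(
      "apply_exclusions: removed %d of %d pixels (%d unit(s) affected: %s)",
      sum(excl), length(excl), length(removed),
      paste(sprintf("%s-%d", names(removed), as.integer(removed)),
            collapse = ", ")
    ))
  }
  tibble::as_tibble(kept)
}

#' Restrict the sample to units with non-negligible crop area
#'
#' Keeps administrative units in which every crop of interest occupies at
#' least `min_share` of the land (inclusive, default 0.5%) and in which
#' the crop shares of interest sum to at most 1.  Units with negligible
#' area in a crop carry no information about its location; share sums
#' above 1 indicate multiple cropping seasons or data inconsistencies.
#'
#' @param shares Long share table: columns `unit_l1`, `crop`, `share`.
#' @param crops Character vector of the crops of interest (excluding the
#'   base "all other uses" category).
#' @param min_share Inclusive lower bound on each listed crop's share.
#' @param quiet Suppress the filter summary message.
#'
#' @return The share table restricted to retained units (all crop rows
#'   kept).  Idempotent.
#' @export
select_units <- function(shares, crops, min_share = 0.005, quiet = FALSE) {
  stopifnot(is.data.frame(shares),
            all(c("unit_l1", "crop", "share") %in% names(shares)))
  if (!is.numeric(min_share) || min_share < 0 || min_share >= 1) {
    abort("min_share must lie in [0, 1)")
  }
  missing_crops <- setdiff(crops, unique(shares$crop))
  if (length(missing_crops) > 0L) {
    abort(sprintf("crop(s) not present in share table: %s",
                  paste(missing_crops, collapse = ", ")))
  }
  keep_tbl <- shares |>
    dplyr::filter(.data$crop %in% crops) |>
    dplyr::summarise(
      ok = all(.data$share >= min_share) &&
        sum(.data$share) <= 1 + 1e-12 &&
        dplyr::n_distinct(.data$crop) == length(crops),
      .by = "unit_l1"
    )
  keep <- keep_tbl$unit_l1[keep_tbl$ok]
  if (length(keep) == 0L) {
    abort("no unit satisfies the selection criteria",
          class = "cropdown_empty_selection")
  }
  if (!quiet) {
    inform(sprintf("select_units: kept %d of %d units", length(keep),
                   dplyr::n_distinct(shares$unit_l1)))
  }
  tibble::as_tibble(shares[shares$unit_l1 %in% keep, , drop = FALSE])
}
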