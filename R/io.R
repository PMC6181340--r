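#' Read and write the delimited-text data formats
#'
#' Pixel tables are CSV with columns `pixel_id, unit_l1, unit_l2, lat,
#' lon, excluded, <covariate columns>` (an `area_km2` column is
#' accepted; otherwise areas are computed from `lat` at the given
#' resolution on read).  Share tables are long CSV
#' `unit_l1` (or `unit_l2`)`, crop, share`.  Prediction grids are long
#' CSV with one row per pixel and crop.
#'
#' @param path File path.
#' @param resolution Cell size in arc-minutes used to compute missing
#'   areas.
#' @return `read_pixel_table()` and `read_share_table()` return tibbles;
#'   the writers return `path` invisibly.
#' @name cropdown_io
NULL

#' @rdname cropdown_io
#' @export
read_pixel_table <- function(path, resolution = 5) {
  px <- readr::read_csv(path, show_col_types = FALSE)
  need <- setdiff(c("pixel_id", "unit_l1", "lat", "lon"), names(px))
  if (length(need) > 0L) {
    abort(sprintf("pixel table %s lacks column(s): %s", path,
                  paste(need, collapse = ", ")))
  }
  if (anyDuplicated(px$pixel_id)) {
    abort(sprintf("duplicate pixel_id in %s", path))
  }
  if (!"excluded" %in% names(px)) px$excluded <- FALSE
  px$excluded <- as.logical(px$excluded)
  if (!"area_km2" %in% names(px)) {
    px$area_km2 <- pixel_area(px$lat, resolution)
  }
  px
}

#' @rdname cropdown_io
#' @param x Object to write (pixel table, share table, grid, ...).
#' @export
write_pixel_table <- function(x, path) {
  readr::write_csv(x, path)
  invisible(path)
}

#' @rdname cropdown_io
#' @param unit_col Expected unit column (`"unit_l1"` or `"unit_l2"`).
#' @export
read_share_table <- function(path, unit_col = "unit_l1") {
  sh <- readr::read_csv(path, show_col_types = FALSE)
  need <- setdiff(c(unit_col, "crop", "share"), names(sh))
  if (length(need) > 0L) {
    abort(sprintf("share table %s lacks column(s): %s", path,
                  paste(need, collapse = ", ")))
  }
  sh
}

#' @rdname cropdown_io
#' @export
write_share_table <- function(x, path) {
  readr::write_csv(x, path)
  invisible(path)
}

#' Serialize a fitted model to JSON
#'
#' Writes the coefficient table (crop, term, estimate, SE, t-value),
#' the log-quasi-likelihood, unit/pixel counts, the fitting options and
#' the covariance convention to a plain JSON document; the covariance
#' matrix itself is included so the fit can be reloaded losslessly for
#' prediction.
#'
#' @param fit A [fit_qmle()] object.
#' @param path Output path.
#' @param seed Optional seed to record.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path, seed = NULL) {
  stopifnot(inherits(fit, "qmle_fit"))
  doc <- list(
    tool = paste0("cropdown ", as.character(utils::packageVersion("cropdown"))),
    coefficients = tidy(fit),
    loglik = fit$loglik,
    n_units = fit$n_units,
    n_pixels = fit$n_pixels,
    crops = fit$crops,
    base = fit$base,
    converged = fit$converged,
    grad_norm = fit$grad_norm,
    options = fit$options,
    seed = seed,
    vcov = fit$vcov
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
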