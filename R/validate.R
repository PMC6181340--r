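#' Root mean squared error between predicted and observed unit shares
#'
#' `RMSE = sqrt( (1/J) * sum_j (predicted_j - observed_j)^2 )` over the
#' J aligned units, computed per crop when a `crop` column is present.
#'
#' @param predicted,observed Tibbles with columns `unit`, `share` and
#'   optionally `crop`.  The unit (and crop) sets must match exactly;
#'   a mismatch is an error naming the difference.
#'
#' @return A tibble `crop` (if any), `rmse`, `n_units`.
#' @examples
#' p <- tibble::tibble(unit = c("a", "b"), share = c(0.2, 0.5))
#' o <- tibble::tibble(unit = c("a", "b"), share = c(0.3, 0.2))
#' share_rmse(p, o)  # sqrt(0.05)
#' @export
share_rmse <- function(predicted, observed) {
  stopifnot(is.data.frame(predicted), is.data.frame(observed),
            all(c("unit", "share") %in% names(predicted)),
            all(c("unit", "share") %in% names(observed)))
  keys <- intersect(c("unit", "crop"), intersect(names(predicted),
                                                 names(observed)))
  pk <- do.call(paste, c(predicted[keys], sep = "\r"))
  ok <- do.call(paste, c(observed[keys], sep = "\r"))
  if (!setequal(pk, ok) || anyDuplicated(pk) || anyDuplicated(ok)) {
    diff <- union(setdiff(pk, ok), setdiff(ok, pk))
    abort(sprintf(
      "predicted and observed unit sets differ%s",
      if (length(diff) > 0L) {
        paste0(": ", paste(gsub("\r", "/", head(diff, 10L)), collapse = ", "))
      } else {
        " (duplicated keys)"
      }
    ), class = "cropdown_unit_mismatch")
  }
  m <- dplyr::inner_join(
    dplyr::rename(predicted, predicted = "share"),
    dplyr::rename(observed, observed = "share"),
    by = keys
  )
  if ("crop" %in% keys) {
    dplyr::summarise(m,
      rmse = sqrt(mean((.data$predicted - .data$observed)^2)),
      n_units = dplyr::n(), .by = "crop")
  } else {
    tibble::tibble(rmse = sqrt(mean((m$predicted - m$observed)^2)),
                   n_units = nrow(m))
  }
}

#' Calibration regression of observed on predicted shares
#'
#' OLS of the observed unit shares on the predicted ones (the default
#' direction; ideal predictions give intercept 0 and slope 1 against
#' the 45-degree line).  Reports conventional OLS standard errors,
#' t-statistics for intercept = 0 and slope = 1 with their p-values,
#' and the squared Pearson correlation of the two series as R-squared.
#'
#' @param predicted,observed Numeric vectors of aligned unit shares
#'   (at least 3 units; the predictor must have nonzero variance).
#' @param direction `"obs_on_pred"` (default) or `"pred_on_obs"`.
#'
#' @return A one-row tibble: `intercept`, `slope`, `se_intercept`,
#'   `se_slope`, `t_intercept_0`, `t_slope_1`, `p_intercept`,
#'   `p_slope`, `r_squared`, `n_units`.
#' @export
calibration <- function(predicted, observed,
                        direction = c("obs_on_pred", "pred_on_obs")) {
  direction <- match.arg(direction)
  stopifnot(is.numeric(predicted), is.numeric(observed),
            length(predicted) == length(observed))
  n <- length(predicted)
  if (n < 3L) abort("calibration needs at least 3 units")
  x <- if (direction == "obs_on_pred") predicted else observed
  yv <- if (direction == "obs_on_pred") observed else predicted
  if (var(x) == 0) {
    abort("zero variance in the regression predictor",
          class = "cropdown_zero_variance")
  }
  m <- lm(yv ~ x)
  est <- coef(m)
  se <- suppressWarnings(sqrt(diag(vcov(m))))
  # an (essentially) exact fit degenerates the OLS SEs; the tests are
  # then 0 when the coefficient hits its reference value and +/-Inf
  # (p = 0) otherwise
  tstat <- function(diff, se) {
    if (se > 1e-14) return(diff / se)
    if (abs(diff) <= 1e-10) 0 else sign(diff) * Inf
  }
  t0 <- tstat(est[1], se[1])
  t1 <- tstat(est[2] - 1, se[2])
  df <- n - 2L
  tibble::tibble(
    intercept = unname(est[1]), slope = unname(est[2]),
    se_intercept = unname(se[1]), se_slope = unname(se[2]),
    t_intercept_0 = unname(t0), t_slope_1 = unname(t1),
    p_intercept = unname(2 * pt(abs(t0), df, lower.tail = FALSE)),
    p_slope = unname(2 * pt(abs(t1), df, lower.tail = FALSE)),
    r_squared = cor(predicted, observed)^2,
    n_units = n
  )
}

#' Validation report at an administrative level
#'
#' Aggregates a prediction grid to the requested administrative level
#' (restricted to the units present in the observed table — partial
#' Level-2 coverage is common) and computes, per crop, the RMSE and the
#' calibration regression against the observed shares.  Level-2 reports
#' on a Level-1-scaled grid are the out-of-sample check: Level-2 data
#' never enter the estimation.
#'
#' @param grid A prediction grid; the fraction used is
#'   `scaled_fraction` when present, else the raw fractions.
#' @param observed Observed shares at the target level: columns
#'   `unit_l1` or `unit_l2` (or `unit`), `crop`, `share`.
#' @param level 1 or 2.
#' @param pixels Optional pixel table supplying unit membership or
#'   areas missing from the grid.
#'
#' @return A tibble with one row per crop: `level`, `crop`, `rmse`,
#'   calibration columns, `r_squared`, `n_units`.
#' @export
validation_report <- function(grid, observed, level = 1, pixels = NULL) {
  stopifnot(level %in% c(1, 2))
  ucol <- paste0("unit_l", level)
  obs <- observed
  if (ucol %in% names(obs)) obs <- dplyr::rename(obs, unit = dplyr::all_of(ucol))
  if (!all(c("unit", "crop", "share") %in% names(obs))) {
    abort(sprintf("observed table needs columns %s/unit, crop, share", ucol))
  }
  pred <- aggregate_shares(grid, pixels = pixels, level = ucol)
  pred <- pred[pred$unit %in% unique(obs$unit) &
                 pred$crop %in% unique(obs$crop), , drop = FALSE]
  if (nrow(pred) == 0L) {
    abort("no overlapping units between the grid and the observed shares",
          class = "cropdown_unit_mismatch")
  }
  obs <- obs[obs$unit %in% unique(pred$unit), c("unit", "crop", "share")]
  purrr::map_dfr(sort(unique(pred$crop)), function(cr) {
    p <- pred[pred$crop == cr, ]
    o <- obs[obs$crop == cr, ]
    r <- share_rmse(p[, c("unit", "share")], o[, c("unit", "share")])
    m <- dplyr::inner_join(dplyr::rename(p, predicted = "share"),
                           dplyr::rename(o, observed = "share"),
                           by = "unit")
    cal <- calibration(m$predicted, m$observed)
    dplyr::bind_cols(tibble::tibble(level = level, crop = cr,
                                    rmse = r$rmse), cal)
  })
}

#' @rdname validation_report
#' @export
level2_report <- function(grid, observed, pixels = NULL) {
  validation_report(grid, observed, level = 2, pixels = pixels)
}
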