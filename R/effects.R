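# Derivative of the design matrix with respect to one fundamental
# covariate, pixel by pixel.  Columns not involving the variable are 0;
# hinge terms use the subgradient 0 exactly at the pivot.
design_derivative <- function(pixels, spec, variable) {
  n <- nrow(pixels)
  cols <- list()
  if (spec$intercept) cols[["(Intercept)"]] <- rep(0, n)
  for (tm in spec$terms) {
    lab <- format(tm)
    if (tm$type == "indicator") {
      x <- as.character(pixels[[tm$var]])
      levs <- sort(unique(x))
      base <- tm$base %||% levs[1L]
      for (lv in setdiff(levs, base)) {
        cols[[paste0(tm$var, "=", lv)]] <- rep(0, n)
      }
      next
    }
    v <- as.numeric(pixels[[tm$var]])
    d <- rep(0, n)
    if (tm$type == "linear" && tm$var == variable) d <- rep(1, n)
    if (tm$type == "square" && tm$var == variable) d <- 2 * v
    if (tm$type == "interaction") {
      if (tm$var == variable) d <- d + as.numeric(pixels[[tm$var_b]])
      if (tm$var_b == variable) d <- d + as.numeric(pixels[[tm$var]])
    }
    if (tm$type == "hinge_below" && tm$var == variable) d <- -(v < tm$pivot)
    if (tm$type == "hinge_above" && tm$var == variable) d <- +(v > tm$pivot)
    cols[[lab]] <- d
  }
  D <- do.call(cbind, cols)
  colnames(D) <- names(cols)
  D
}

# Per-pixel derivative of the linear predictors (free crops) w.r.t. a
# variable: n x (K-1).
eta_derivative <- function(fit, pixels, variable) {
  D <- design_derivative(pixels, fit$design, variable)
  D %*% fit$beta_mat
}

#' Average marginal effects on pixel crop shares
#'
#' The derivative of each pixel's crop share with respect to a
#' fundamental covariate, propagated by the chain rule through every
#' design term containing it (linear, square, interaction, hinge) and
#' through the multinomial-logit Jacobian
#' `dG_k = G_k (d_eta_k - sum_l G_l d_eta_l)` (with the base category's
#' index derivative 0), then averaged over pixels.  Shares sum to one,
#' so effects sum to zero over the K categories at every pixel.  At a
#' hinge pivot the derivative of both hinge terms is taken as 0.
#' Grouping variables used in indicator terms are reported as discrete
#' changes: the mean share with the indicator set minus the mean share
#' at the base level.
#'
#' @param fit A [fit_qmle()] object.
#' @param pixels Pixel table to evaluate at; defaults to the estimation
#'   pixels (after exclusions).
#' @param variables Covariates to report; defaults to every fundamental
#'   variable in the design.
#' @param average `"unweighted"` (mean over included pixels, the
#'   default) or `"area"` (area-weighted mean).
#' @param by_pixel Return per-pixel effects instead of averages.
#'
#' @return A tibble `variable`, `crop`, `marginal_effect`, `type`
#'   (`"derivative"` or `"discrete"`); with `by_pixel = TRUE` also
#'   `pixel_id`.
#' @export
marginal_effects <- function(fit, pixels = NULL, variables = NULL,
                             average = c("unweighted", "area"),
                             by_pixel = FALSE) {
  stopifnot(inherits(fit, "qmle_fit"))
  average <- match.arg(average)
  pixels <- pixels %||% fit$problem$pixels
  spec <- fit$design
  cont <- design_continuous_vars(spec)
  ind_terms <- Filter(function(tm) tm$type == "indicator", spec$terms)
  ind_vars <- vapply(ind_terms, function(tm) tm$var, character(1))
  variables <- variables %||% c(cont, ind_vars)

  G <- pixel_shares(build_design(pixels, spec), fit$beta_mat, fit$crops)
  wts <- if (average == "area") {
    a <- pixels$area_km2 %||% pixel_area(pixels$lat)
    a / sum(a)
  } else {
    rep(1 / nrow(pixels), nrow(pixels))
  }

  out <- list()
  for (v in intersect(variables, cont)) {
    deta <- cbind(0, eta_derivative(fit, pixels, v))   # n x K
    dG <- G * (deta - rowSums(G * deta))
    if (by_pixel) {
      out[[v]] <- tibble::tibble(
        pixel_id = rep(pixels$pixel_id, times = fit$problem$K),
        variable = v,
        crop = rep(fit$crops, each = nrow(pixels)),
        marginal_effect = as.vector(dG),
        type = "derivative"
      )
    } else {
      out[[v]] <- tibble::tibble(
        variable = v, crop = fit$crops,
        marginal_effect = as.numeric(crossprod(dG, wts)),
        type = "derivative"
      )
    }
  }

  if (length(ind_terms) > 0L) {
    Wobs <- align_design(build_design(pixels, spec), fit$terms)
  }
  for (tm in ind_terms[ind_vars %in% variables]) {
    x <- as.character(pixels[[tm$var]])
    levs <- sort(unique(x))
    base <- tm$base %||% levs[1L]
    lvl_cols <- grep(paste0("^", tm$var, "="), fit$terms, value = TRUE)
    # counterfactual: put every pixel at level lv by editing the 0/1
    # columns of this indicator term only
    at_level <- function(lv) {
      Wl <- Wobs
      for (nm in lvl_cols) {
        Wl[, nm] <- as.numeric(nm == paste0(tm$var, "=", lv))
      }
      as.numeric(crossprod(pixel_shares(Wl, fit$beta_mat, fit$crops), wts))
    }
    g_base <- at_level(base)
    for (nm in lvl_cols) {
      lv <- sub(paste0("^", tm$var, "="), "", nm)
      out[[nm]] <- tibble::tibble(
        variable = nm, crop = fit$crops,
        marginal_effect = at_level(lv) - g_base,
        type = "discrete"
      )
    }
  }

  missing_vars <- setdiff(variables, c(cont, ind_vars))
  for (v in missing_vars) {
    warn(sprintf("variable '%s' appears in no design term; effect is 0", v))
    out[[v]] <- tibble::tibble(variable = v, crop = fit$crops,
                               marginal_effect = 0, type = "derivative")
  }
  dplyr::bind_rows(out)
}

#' Odds ratios implied by the fitted share model
#'
#' For a covariate entering the index only through a single linear term,
#' a one-unit increase multiplies the odds of crop k against the base
#' category by exactly `exp(beta_km)`.  For covariates in squares,
#' interactions or hinges, the local log-odds derivative varies by
#' pixel, and the reported value is the mean over included pixels of
#' `exp(d eta_k / d x)` (`method = "average"`).  Indicator levels are
#' linear 0/1 entries, so their odds ratio is exact.
#'
#' @inheritParams marginal_effects
#' @return A tibble `variable`, `crop` (free crops only), `odds_ratio`,
#'   `method` (`"exact"` or `"average"`).
#' @export
odds_ratios <- function(fit, pixels = NULL, variables = NULL) {
  stopifnot(inherits(fit, "qmle_fit"))
  spec <- fit$design
  cont <- design_continuous_vars(spec)
  ind_terms <- Filter(function(tm) tm$type == "indicator", spec$terms)
  ind_vars <- vapply(ind_terms, function(tm) tm$var, character(1))
  variables <- variables %||% c(cont, ind_vars)
  free <- fit$crops[-1L]
  td <- tidy(fit)

  linear_only <- function(v) {
    touching <- Filter(function(tm) {
      tm$type != "indicator" && v %in% c(tm$var, tm$var_b)
    }, spec$terms)
    length(touching) == 1L && touching[[1]]$type == "linear"
  }

  out <- list()
  for (v in intersect(variables, cont)) {
    if (linear_only(v)) {
      est <- td$estimate[td$term == v]
      out[[v]] <- tibble::tibble(variable = v, crop = free,
                                 odds_ratio = exp(est), method = "exact")
    } else {
      px <- pixels %||% fit$problem$pixels
      deta <- eta_derivative(fit, px, v)      # n x (K-1)
      out[[v]] <- tibble::tibble(
        variable = v, crop = free,
        odds_ratio = as.numeric(colMeans(exp(deta))),
        method = "average"
      )
    }
  }
  for (tm in ind_terms[ind_vars %in% variables]) {
    lvl_terms <- grep(paste0("^", tm$var, "="), unique(td$term), value = TRUE)
    for (nm in lvl_terms) {
      est <- td$estimate[td$term == nm]
      out[[nm]] <- tibble::tibble(variable = nm, crop = free,
                                  odds_ratio = exp(est), method = "exact")
    }
  }
  unknown <- setdiff(variables, c(cont, ind_vars))
  if (length(unknown) > 0L) {
    warn(sprintf("variable(s) in no design term: %s",
                 paste(unknown, collapse = ", ")))
  }
  dplyr::bind_rows(out)
}
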