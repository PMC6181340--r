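#' Pixel-level crop shares under the multinomial logit
#'
#' Given a design matrix `W` (one row per pixel, M columns) and the free
#' coefficient matrix `beta` (M rows, one column per non-base crop), the
#' share of pixel i in crop k is
#' `G_ik = exp(W_i b_k) / sum_l exp(W_i b_l)` with the base category's
#' linear index pinned at zero (`b_1 = 0`), which identifies the
#' parameters.  Computed with a row-wise log-sum-exp shift so linear
#' predictors up to |700| are handled without overflow.
#'
#' @param W Numeric design matrix (n x M), or a single M-vector.
#' @param beta Numeric M x (K-1) matrix of free coefficients; a vector is
#'   taken as K = 2.
#' @param crops Optional length-K character vector of crop names (base
#'   first) used for column names.
#'
#' @return An n x K matrix of shares, each row strictly inside (0,1) and
#'   summing to 1; column 1 is the base category.
#' @examples
#' pixel_shares(matrix(1, 1, 1), cbind(log(3)))  # (0.25, 0.75)
#' @export
pixel_shares <- function(W, beta, crops = NULL) {
  if (is.null(dim(W))) W <- matrix(W, nrow = 1L)
  if (is.null(dim(beta))) beta <- matrix(beta, ncol = 1L)
  stopifnot(ncol(W) == nrow(beta))
  eta_free <- W %*% beta                      # n x (K-1)
  if (any(!is.finite(eta_free))) {
    abort("non-finite linear predictor in pixel_shares",
          class = "cropdown_nonfinite_eta")
  }
  eta <- cbind(0, eta_free)                   # base category index = 0
  m <- apply(eta, 1L, max)
  ex <- exp(eta - m)
  G <- ex / rowSums(ex)
  if (!is.null(crops)) colnames(G) <- crops
  G
}

# Area-weighted aggregation core: G (n x K), areas (n), unit factor (n)
# -> J x K matrix of unit shares, rows named by unit level.
agg_shares_matrix <- function(G, areas, unit) {
  stopifnot(nrow(G) == length(areas), length(areas) == length(unit))
  if (any(!(areas > 0))) abort("pixel areas must be positive")
  unit <- as.factor(unit)
  if (any(tabulate(unit, nbins = nlevels(unit)) == 0L)) {
    abort(sprintf("unit(s) without pixels: %s",
                  paste(levels(unit)[tabulate(unit, nlevels(unit)) == 0L],
                        collapse = ", ")),
          class = "cropdown_empty_unit")
  }
  num <- rowsum(G * areas, unit)
  den <- rowsum(areas, unit)
  sweep(num, 1L, den, "/")
}

#' Aggregate pixel shares to administrative units
#'
#' The model's unit-level predicted share is the area-weighted mean of
#' its pixels' shares:
#' `H_jk = sum_i G_ijk A_ij / sum_i A_ij` over the pixels i of unit j.
#' Weighting by pixel area makes the aggregate the fraction of the
#' unit's land, not the mean over equally counted cells.
#'
#' @param grid Long prediction table: columns `pixel_id`, `crop`, a
#'   fraction column (`fraction`, or the first of `scaled_fraction`,
#'   `raw_fraction` present), plus `area_km2` and the unit column (either
#'   carried in `grid` or joined from `pixels`).
#' @param pixels Optional pixel table supplying `area_km2` and unit
#'   columns for pixel ids missing them in `grid`.
#' @param level Unit column to aggregate to: `"unit_l1"` or `"unit_l2"`.
#'
#' @return Tibble `unit`, `crop`, `share`; shares sum to 1 over crops
#'   within each unit when the input fractions do.
#' @export
aggregate_shares <- function(grid, pixels = NULL, level = "unit_l1") {
  stopifnot(is.data.frame(grid), level %in% c("unit_l1", "unit_l2"))
  fcol <- intersect(c("fraction", "scaled_fraction", "raw_fraction"),
                    names(grid))[1]
  if (is.na(fcol)) abort("grid has no fraction column")
  g <- grid
  need <- setdiff(c(level, "area_km2"), names(g))
  if (length(need) > 0L) {
    if (is.null(pixels)) {
      abort(sprintf("grid lacks column(s) %s and no pixel table was given",
                    paste(need, collapse = ", ")))
    }
    g <- dplyr::left_join(g, pixels[, c("pixel_id", need)], by = "pixel_id")
  }
  if (any(is.na(g[[level]]))) {
    abort(sprintf("missing %s for some pixels in the grid", level),
          class = "cropdown_missing_unit")
  }
  g |>
    dplyr::summarise(
      share = sum(.data[[fcol]] * .data$area_km2) / sum(.data$area_km2),
      .by = dplyr::all_of(c(level, "crop"))
    ) |>
    dplyr::rename(unit = dplyr::all_of(level)) |>
    dplyr::arrange(.data$unit, .data$crop)
}

#' Quasi-log-likelihood of observed unit shares
#'
#' The multinomial quasi-log-likelihood `L = sum_j sum_k y_jk log H_jk`
#' comparing observed unit share vectors `y_j` with model aggregates
#' `H_j`.  Maximizing L in the coefficients is consistent whenever the
#' conditional mean (the aggregated logit) is correctly specified,
#' whatever the true distribution of the shares.  Terms with
#' `y_jk = 0` contribute exactly zero.
#'
#' @param y,H Numeric J x K matrices of observed and predicted unit
#'   shares, rows aligned.
#' @return A finite scalar `<= 0`.
#' @export
quasi_loglik <- function(y, H) {
  stopifnot(is.matrix(y), is.matrix(H), all(dim(y) == dim(H)))
  if (any(H <= 0 & y > 0)) {
    abort("predicted share is 0 where the observed share is positive",
          class = "cropdown_zero_share")
  }
  pos <- y > 0
  sum(y[pos] * log(H[pos]))
}

# ---- internal estimation problem ------------------------------------------

# Bundles everything the optimizer needs: the design matrix, per-pixel
# area weights normalized within unit, the observed share matrix with
# the base crop in column 1, and closures for L, the analytic score and
# the per-unit scores.  Parameters are a flat vector, crop-major:
# beta_2 block (M entries) then beta_3 block, etc.
qmle_problem <- function(shares, pixels, spec, base = NULL,
                         share_tol = 1e-9) {
  stopifnot(is.data.frame(shares),
            all(c("unit_l1", "crop", "share") %in% names(shares)),
            is.data.frame(pixels), "unit_l1" %in% names(pixels))
  crops_all <- unique(as.character(shares$crop))
  base <- base %||% (if ("other" %in% crops_all) "other" else crops_all[1L])
  if (!base %in% crops_all) {
    abort(sprintf("base crop '%s' not present in share table", base))
  }
  crops <- c(base, setdiff(crops_all, base))
  K <- length(crops)
  if (K < 2L) abort("need at least two crop categories")

  ywide <- shares |>
    tidyr::pivot_wider(id_cols = "unit_l1", names_from = "crop",
                       values_from = "share")
  if (anyNA(ywide)) {
    bad <- ywide$unit_l1[!stats::complete.cases(ywide)]
    abort(sprintf("missing crop shares for unit(s): %s",
                  paste(bad, collapse = ", ")))
  }
  y <- as.matrix(ywide[, crops, drop = FALSE])
  rownames(y) <- as.character(ywide$unit_l1)
  bad_sum <- abs(rowSums(y) - 1) > share_tol
  if (any(bad_sum)) {
    abort(sprintf(
      "crop shares do not sum to 1 for unit(s): %s (sums: %s)",
      paste(rownames(y)[bad_sum], collapse = ", "),
      paste(format(rowSums(y)[bad_sum], digits = 6), collapse = ", ")
    ), class = "cropdown_bad_share_sum")
  }
  if (any(y < 0 | y > 1)) abort("shares must lie in [0, 1]")

  if ("excluded" %in% names(pixels)) {
    pixels <- apply_exclusions(pixels, quiet = TRUE)
  }
  px <- pixels[as.character(pixels$unit_l1) %in% rownames(y), , drop = FALSE]
  unit <- factor(as.character(px$unit_l1), levels = rownames(y))
  cnt <- tabulate(unit, nbins = nlevels(unit))
  if (any(cnt == 0L)) {
    abort(sprintf("unit(s) in the share table have no pixels: %s",
                  paste(levels(unit)[cnt == 0L], collapse = ", ")),
          class = "cropdown_empty_unit")
  }
  if (!"area_km2" %in% names(px)) {
    if (!"lat" %in% names(px)) {
      abort("pixel table needs an area_km2 or lat column")
    }
    px$area_km2 <- pixel_area(px$lat)
  }
  W <- build_design(px, spec)
  M <- ncol(W)
  qrW <- qr(W)
  if (qrW$rank < M) {
    dropped <- colnames(W)[qrW$pivot[(qrW$rank + 1L):M]]
    abort(sprintf(
      "rank-deficient design matrix: column(s) %s are collinear; coefficients not identified",
      paste(dropped, collapse = ", ")
    ), class = "cropdown_rank_deficient")
  }
  area <- as.numeric(px$area_km2)
  area_tot <- as.numeric(rowsum(area, unit))   # per-unit totals, unit order
  w <- area / area_tot[as.integer(unit)]       # weights summing to 1 per unit

  J <- nrow(y)
  npar <- M * (K - 1L)
  par_names <- as.vector(outer(colnames(W), crops[-1L],
                               function(trm, cr) paste(cr, trm, sep = ":")))

  to_beta <- function(theta) matrix(theta, nrow = M, ncol = K - 1L)

  Hfun <- function(theta) {
    G <- pixel_shares(W, to_beta(theta), crops)
    rowsum(G * w, unit)                       # J x K
  }
  # Optimizer-facing objective: floors H at the smallest normal double
  # so that extreme trial steps in a line search yield a very poor but
  # finite value instead of -Inf; the strict quasi_loglik() contract is
  # unaffected at any interior point.
  llfun <- function(theta) {
    H <- Hfun(theta)
    pos <- y > 0
    sum(y[pos] * log(pmax(H[pos], .Machine$double.xmin)))
  }

  # Score pieces shared by the total and per-unit versions:
  # U[i, k'] = w_i * G_{ik'} * (c_{j(i),k'} - r_i), free crops k' = 2..K,
  # where c_jk = y_jk / H_jk and r_i = sum_k c_{j(i),k} G_ik.
  score_U <- function(theta) {
    G <- pixel_shares(W, to_beta(theta))
    H <- rowsum(G * w, unit)
    C <- y / pmax(H, .Machine$double.xmin)    # J x K
    Ci <- C[as.integer(unit), , drop = FALSE] # n x K
    r <- rowSums(Ci * G)
    U <- w * G[, -1L, drop = FALSE] *
      (Ci[, -1L, drop = FALSE] - r)           # n x (K-1)
    U
  }
  scorefun <- function(theta) as.vector(crossprod(W, score_U(theta)))
  unit_scores <- function(theta) {
    U <- score_U(theta)
    # per-unit score for each free crop block, column-bound crop-major
    do.call(cbind, lapply(seq_len(K - 1L), function(k) {
      rowsum(W * U[, k], unit)                # J x M
    }))                                       # J x M(K-1)
  }

  list(
    y = y, W = W, unit = unit, weights = w, area = area, crops = crops,
    base = base, K = K, M = M, J = J, npar = npar, par_names = par_names,
    pixels = px, to_beta = to_beta, Hfun = Hfun, llfun = llfun,
    scorefun = scorefun, unit_scores = unit_scores
  )
}
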