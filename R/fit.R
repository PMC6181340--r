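#' Fit the aggregated fractional multinomial logit by QMLE
#'
#' Maximizes the quasi-log-likelihood
#' `L(beta) = sum_j sum_k y_jk log H_jk(beta)` where `H_jk` is the
#' area-weighted aggregate over unit j's pixels of the multinomial-logit
#' pixel shares, using BFGS with the analytic score.  The base crop's
#' coefficient vector is pinned at zero; the free parameters are stored
#' flat, crop-major (all of crop 2's coefficients, then crop 3's, ...).
#' Starting values are `beta = 0` (uniform shares) unless `start` is
#' given.  Robust (sandwich) standard errors are attached by default.
#'
#' @param shares Long observed share table: `unit_l1`, `crop`, `share`;
#'   shares must sum to 1 over crops (including the base category)
#'   within each unit.
#' @param pixels Pixel table with `unit_l1`, covariates, and either
#'   `area_km2` or `lat` (areas then computed at 5'); rows flagged
#'   `excluded` are dropped.
#' @param design A [design_spec()].
#' @param base Name of the base ("all other uses") crop; defaults to
#'   `"other"` when present, else the first crop.
#' @param vcov Covariance estimator: `"sandwich"` (default), or
#'   `"none"`.
#' @param tol Convergence: gradient max-norm threshold (default 1e-6);
#'   relative log-likelihood improvement below 1e-10 is also required of
#'   the optimizer.
#' @param max_iter Maximum BFGS iterations.
#' @param start Optional starting parameter vector (length `(K-1)*M`).
#'
#' @return An object of class `qmle_fit`: coefficients, covariance,
#'   standard errors, t-values, log-likelihood and convergence
#'   diagnostics.  Use [tidy()] / [glance()] for tabular summaries and
#'   [predict_pixels()] for pixel predictions.
#' @examples
#' \donttest{
#' cfg <- synthetic_config(J = 40, seed = 1)
#' land <- simulate_landscape(cfg)
#' y <- simulate_shares(land, cfg)
#' fit <- fit_qmle(y, land, cfg$design)
#' tidy(fit)
#' }
#' @export
fit_qmle <- function(shares, pixels, design, base = NULL,
                     vcov = c("sandwich", "none"),
                     tol = 1e-6, max_iter = 500L, start = NULL) {
  vcov <- match.arg(vcov)
  prob <- qmle_problem(shares, pixels, design, base = base)
  theta0 <- if (is.null(start)) rep(0, prob$npar) else {
    stopifnot(length(start) == prob$npar)
    as.numeric(start)
  }

  neg_ll <- function(th) -prob$llfun(th)
  neg_sc <- function(th) -prob$scorefun(th)

  total_iter <- 0L
  theta <- theta0
  opt <- NULL
  for (round in 1:4) {
    opt <- optim(theta, fn = neg_ll, gr = neg_sc, method = "BFGS",
                 control = list(maxit = max_iter, reltol = 1e-14))
    total_iter <- total_iter + opt$counts[["function"]]
    theta <- opt$par
    if (max(abs(theta)) > 1e3) {
      abort(paste("parameter estimates diverged (|beta| > 1000);",
                  "likely separation or an unidentified design"),
            class = "cropdown_separation")
    }
    gnorm <- max(abs(prob$scorefun(theta)))
    if (gnorm < tol) break
  }
  # Newton polish: BFGS stops on relative improvement and can stall with
  # a gradient just above tol; a few damped Newton steps with the FD
  # Hessian of the analytic score push it to the stationary point.
  gnorm <- max(abs(prob$scorefun(theta)))
  newton <- 0L
  while (opt$convergence == 0L && gnorm >= tol * 0.1 && newton < 10L) {
    Hs <- fd_hessian(prob$scorefun, theta)
    step <- tryCatch(solve(Hs, prob$scorefun(theta)), error = function(e) NULL)
    if (is.null(step)) break
    ll_cur <- prob$llfun(theta)
    damp <- 1
    repeat {
      cand <- theta - damp * step
      if (prob$llfun(cand) >= ll_cur - 1e-12 * abs(ll_cur)) break
      damp <- damp / 2
      if (damp < 1e-4) break
    }
    cand <- theta - damp * step
    gn_new <- max(abs(prob$scorefun(cand)))
    if (!is.finite(gn_new) || gn_new >= gnorm) break
    theta <- cand
    gnorm <- gn_new
    newton <- newton + 1L
    total_iter <- total_iter + 1L
  }
  converged <- gnorm < tol
  if (!converged) {
    warn(sprintf(
      "fit_qmle did not converge: gradient max-norm %.3g >= tol %.3g",
      gnorm, tol
    ))
  }
  ll <- prob$llfun(theta)

  fit <- structure(
    list(
      beta_hat = setNames(theta, prob$par_names),
      beta_mat = prob$to_beta(theta),
      crops = prob$crops, base = prob$base,
      terms = colnames(prob$W),
      loglik = ll, loglik0 = prob$llfun(rep(0, prob$npar)),
      converged = converged, iterations = total_iter,
      grad_norm = gnorm, n_units = prob$J, n_pixels = nrow(prob$W),
      design = design, problem = prob,
      options = list(tol = tol, max_iter = max_iter,
                     vcov = vcov, base = prob$base,
                     vcov_convention = "A=(1/J) sum_j H_j, B=(1/J) sum_j s_j s_j', V=A^-1 B A^-1 / J"),
      vcov = NULL, se = rep(NA_real_, prob$npar),
      tvalues = rep(NA_real_, prob$npar)
    ),
    class = "qmle_fit"
  )
  if (vcov == "sandwich") {
    V <- sandwich_cov(fit)
    fit$vcov <- V
    fit$se <- setNames(sqrt(diag(V)), prob$par_names)
    fit$tvalues <- fit$beta_hat / fit$se
  }
  fit
}

# Central finite differences of a gradient function: the Hessian, with
# step 1e-5 * max(1, |theta_m|) per coordinate, symmetrized.
fd_hessian <- function(gradfun, theta) {
  p <- length(theta)
  Hess <- matrix(0, p, p)
  for (m in seq_len(p)) {
    h <- 1e-5 * max(1, abs(theta[m]))
    up <- theta; up[m] <- up[m] + h
    dn <- theta; dn[m] <- dn[m] - h
    Hess[, m] <- (gradfun(up) - gradfun(dn)) / (2 * h)
  }
  (Hess + t(Hess)) / 2
}

#' Sandwich (robust) covariance of the QMLE coefficients
#'
#' The asymptotic covariance `A^-1 B A^-1 / J`, with
#' `A = (1/J) sum_j H_j` the average per-unit Hessian of the
#' quasi-log-likelihood at the estimate (obtained by central finite
#' differences of the analytic score, step `1e-5 * max(1, |beta|)`) and
#' `B = (1/J) sum_j s_j s_j'` the average outer product of the per-unit
#' scores.  The administrative unit is the independent sampling block.
#'
#' @param fit A converged [fit_qmle()] object.
#' @return A symmetric positive semi-definite matrix.
#' @export
sandwich_cov <- function(fit) {
  stopifnot(inherits(fit, "qmle_fit"))
  prob <- fit$problem
  theta <- as.numeric(fit$beta_hat)
  p <- prob$npar

  # Hessian of L by central differences of the analytic score
  Hess <- fd_hessian(prob$scorefun, theta)
  A <- -Hess / prob$J
  if (kappa(A, exact = FALSE) > 1e10) {
    abort(paste("near-singular information matrix (condition number > 1e10);",
                "check the design for collinear columns"),
          class = "cropdown_singular_information")
  }
  S <- prob$unit_scores(theta)                 # J x p
  B <- crossprod(S) / prob$J
  Ainv <- solve(A)
  V <- Ainv %*% B %*% Ainv / prob$J
  V <- (V + t(V)) / 2
  dimnames(V) <- list(prob$par_names, prob$par_names)
  V
}

#' Block-bootstrap covariance of the QMLE coefficients
#'
#' Resamples J administrative units with replacement, carrying *all* of
#' each sampled unit's pixels (so the pixel-to-unit structure is
#' preserved), refits the model on each replicate, and returns the
#' empirical covariance of the replicate coefficient vectors.  Units
#' drawn more than once enter as distinct copies.  Replicates that fail
#' to converge are dropped with a warning; more than 20% dropped is an
#' error.
#'
#' @param fit A converged [fit_qmle()] object.
#' @param B Number of bootstrap replicates (>= 2; >= 50 recommended).
#' @param seed Integer seed making the resampling reproducible.
#' @return A covariance matrix matching [sandwich_cov()] in layout, with
#'   attribute `"n_replicates"` (replicates retained).
#' @export
block_bootstrap_cov <- function(fit, B = 200L, seed = 1L) {
  stopifnot(inherits(fit, "qmle_fit"))
  if (B < 2L) {
    abort("cannot form a bootstrap covariance from fewer than 2 replicates")
  }
  if (B < 50L) warn("fewer than 50 bootstrap replicates; covariance will be noisy")
  prob <- fit$problem
  units <- rownames(prob$y)
  px_by_unit <- split(prob$pixels, as.character(prob$pixels$unit_l1))
  y_by_unit <- split(as.data.frame(prob$y), units)

  draw_fit <- function(idx) {
    picked <- units[idx]
    copies <- stats::ave(seq_along(picked), picked, FUN = seq_along)
    new_id <- paste0(picked, "#", copies)
    px <- purrr::map2_dfr(picked, new_id, function(u, id) {
      d <- px_by_unit[[u]]
      d$unit_l1 <- id
      d
    })
    ymat <- do.call(rbind, y_by_unit[picked])
    ylong <- tibble::tibble(
      unit_l1 = rep(new_id, each = prob$K),
      crop = rep(prob$crops, times = length(new_id)),
      share = as.vector(t(as.matrix(ymat)))
    )
    fit_b <- tryCatch(
      suppressWarnings(fit_qmle(ylong, px, fit$design, base = prob$base,
                                vcov = "none", tol = fit$options$tol,
                                max_iter = fit$options$max_iter,
                                start = as.numeric(fit$beta_hat))),
      error = function(e) NULL
    )
    if (is.null(fit_b) || !fit_b$converged) return(NULL)
    as.numeric(fit_b$beta_hat)
  }

  reps <- withr::with_seed(seed, {
    idx_draws <- replicate(B, sample.int(length(units), replace = TRUE),
                           simplify = FALSE)
    lapply(idx_draws, draw_fit)
  })
  keep <- !vapply(reps, is.null, logical(1))
  if (sum(!keep) > 0L) {
    warn(sprintf("%d of %d bootstrap replicates failed to converge and were dropped",
                 sum(!keep), B))
  }
  if (sum(!keep) > 0.2 * B) {
    abort("more than 20% of bootstrap replicates failed to converge",
          class = "cropdown_bootstrap_failure")
  }
  R <- do.call(rbind, reps[keep])
  V <- stats::cov(R)
  dimnames(V) <- list(prob$par_names, prob$par_names)
  attr(V, "n_replicates") <- sum(keep)
  V
}

#' Build a fitted-model object from a published coefficient table
#'
#' Coefficient estimates from a share model fitted elsewhere can be
#' deployed for prediction, marginal effects and odds ratios without
#' refitting: supply the design and the coefficient table and the
#' result behaves like a [fit_qmle()] object (without likelihood or
#' covariance information unless given).
#'
#' @param coefficients A tibble with columns `term`, `estimate` and
#'   optionally `crop` (required when `K > 2`) and `std_error`.  Terms
#'   must use the design's column labels, in design order within each
#'   crop.
#' @param design The [design_spec()] that produced the terms.
#' @param crops Crop names, base category first.
#' @return A `qmle_fit` object usable with [predict_pixels()],
#'   [marginal_effects()] and [odds_ratios()].
#' @export
qmle_fit_from_coefficients <- function(coefficients, design,
                                       crops = c("other", "crop")) {
  stopifnot(is.data.frame(coefficients),
            all(c("term", "estimate") %in% names(coefficients)),
            length(crops) >= 2L)
  K <- length(crops)
  cf <- coefficients
  if (!"crop" %in% names(cf)) {
    if (K > 2L) abort("coefficient table needs a crop column when K > 2")
    cf$crop <- crops[2L]
  }
  terms <- unique(cf$term)
  M <- length(terms)
  beta <- matrix(NA_real_, M, K - 1L,
                 dimnames = list(terms, crops[-1L]))
  beta[cbind(match(cf$term, terms), match(cf$crop, crops[-1L]))] <-
    cf$estimate
  if (anyNA(beta)) abort("coefficient table is incomplete for some crop")
  se <- rep(NA_real_, M * (K - 1L))
  if ("std_error" %in% names(cf)) {
    semat <- matrix(NA_real_, M, K - 1L)
    semat[cbind(match(cf$term, terms), match(cf$crop, crops[-1L]))] <-
      cf$std_error
    se <- as.numeric(semat)
  }
  theta <- as.numeric(beta)
  par_names <- as.vector(outer(terms, crops[-1L], function(a, b)
    paste(b, a, sep = ":")))
  structure(
    list(beta_hat = setNames(theta, par_names), beta_mat = unname(beta),
         crops = crops, base = crops[1L], terms = terms,
         loglik = NA_real_, loglik0 = NA_real_, converged = NA,
         iterations = NA_integer_, grad_norm = NA_real_,
         n_units = NA_integer_, n_pixels = NA_integer_,
         design = design, problem = list(K = K, pixels = NULL),
         options = list(source = "external coefficient table"),
         vcov = NULL, se = se,
         tvalues = theta / se),
    class = "qmle_fit"
  )
}

# ---- methods ---------------------------------------------------------------

#' @export
print.qmle_fit <- function(x, ...) {
  cat("Aggregated fractional multinomial logit (QMLE)\n")
  cat(sprintf("  crops: %s (base: %s)\n",
              paste(x$crops, collapse = ", "), x$base))
  cat(sprintf("  units: %d   pixels: %d   parameters: %d\n",
              x$n_units, x$n_pixels, length(x$beta_hat)))
  cat(sprintf("  log-quasi-likelihood: %.6f   converged: %s (|grad| = %.2e, %d evals)\n",
              x$loglik, x$converged, x$grad_norm, x$iterations))
  invisible(x)
}

#' @export
coef.qmle_fit <- function(object, ...) object$beta_hat

#' @export
vcov.qmle_fit <- function(object, ...) object$vcov

#' @export
logLik.qmle_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$beta_hat),
            nobs = object$n_units, class = "logLik")
}

#' Tidy the coefficient table of a fitted share model
#'
#' @param x A `qmle_fit` object.
#' @param ... Unused.
#' @return A tibble with columns `crop`, `term`, `estimate`,
#'   `std.error`, `statistic` (the t-value).
#' @method tidy qmle_fit
#' @export
tidy.qmle_fit <- function(x, ...) {
  tibble::tibble(
    crop = rep(x$crops[-1L], each = length(x$terms)),
    term = rep(x$terms, times = length(x$crops) - 1L),
    estimate = as.numeric(x$beta_hat),
    std.error = as.numeric(x$se),
    statistic = as.numeric(x$tvalues)
  )
}

#' One-row model summary
#'
#' @param x A `qmle_fit` object.
#' @param ... Unused.
#' @return A one-row tibble: `logLik`, `logLik_null` (all coefficients
#'   zero), `n_units`, `n_pixels`, `n_parameters`, `converged`,
#'   `iterations`, `grad_norm`.
#' @method glance qmle_fit
#' @export
glance.qmle_fit <- function(x, ...) {
  tibble::tibble(
    logLik = x$loglik, logLik_null = x$loglik0,
    n_units = x$n_units, n_pixels = x$n_pixels,
    n_parameters = length(x$beta_hat),
    converged = x$converged, iterations = x$iterations,
    grad_norm = x$grad_norm
  )
}
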