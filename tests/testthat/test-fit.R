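test_that("noiseless synthetic shares are recovered to high accuracy", {
  s <- noiseless_setup(J = 120, seed = 21)
  fit <- fit_qmle(s$y, s$land, s$cfg$design, vcov = "none")
  expect_true(fit$converged)
  expect_lt(max(abs(as.numeric(fit$beta_hat) - as.numeric(s$cfg$beta_true))),
            1e-3)
  # ascent from the uniform start
  expect_gte(fit$loglik, fit$loglik0)
})

test_that("fit coincides with an independently coded fractional logit", {
  # one pixel per unit, K = 2: the aggregated model collapses to the
  # standard fractional logit, i.e. a quasibinomial GLM
  inst <- tiny_instance(J = 60, max_pix = 1, K = 2, M = 3, seed = 13)
  fit <- fit_qmle(inst$shares, inst$pixels, inst$spec, base = "other",
                  vcov = "none")
  glm_fit <- stats::glm(
    inst$y[, 2] ~ x1 + x2,
    family = stats::quasibinomial(),
    data = inst$pixels[match(rownames(inst$y), inst$pixels$unit_l1), ],
    control = stats::glm.control(epsilon = 1e-12, maxit = 100)
  )
  expect_lt(max(abs(as.numeric(fit$beta_hat) - as.numeric(coef(glm_fit)))) /
              max(abs(coef(glm_fit))), 1e-6)
  # likelihoods agree at the common maximizer
  ll_glm <- sum(inst$y[, 2] * log(fitted(glm_fit)) +
                  inst$y[, 1] * log(1 - fitted(glm_fit)))
  expect_equal(fit$loglik, ll_glm, tolerance = 1e-10)
})

test_that("identical covariates give the pooled logit intercept and flag collinearity", {
  withr::with_seed(99, {
    J <- 30
    px <- tibble::tibble(
      pixel_id = sprintf("p%03d", 1:(3 * J)),
      unit_l1 = rep(sprintf("u%02d", 1:J), each = 3),
      area_km2 = 80,
      x1 = 2.5   # no variation at all
    )
    y2 <- runif(J, 0.05, 0.4)
    shares <- tibble::tibble(
      unit_l1 = rep(sprintf("u%02d", 1:J), 2),
      crop = rep(c("other", "maize"), each = J),
      share = c(1 - y2, y2)
    )
    # intercept-only model: closed form logit of the pooled mean
    fit0 <- fit_qmle(shares, px, design_spec(intercept = TRUE),
                     vcov = "none")
    expect_equal(unname(as.numeric(fit0$beta_hat)), qlogis(mean(y2)),
                 tolerance = 1e-8)
    # adding the constant covariate makes the design rank deficient
    expect_error(
      fit_qmle(shares, px, design_spec(term_linear("x1")), vcov = "none"),
      class = "cropdown_rank_deficient"
    )
  })
})

test_that("rescaling a covariate rescales its coefficient and not the fit", {
  inst <- tiny_instance(J = 40, max_pix = 4, K = 3, M = 3, seed = 17)
  fit1 <- fit_qmle(inst$shares, inst$pixels, inst$spec, base = "other",
                   vcov = "none")
  px2 <- dplyr::mutate(inst$pixels, x1 = x1 * 10)
  fit2 <- fit_qmle(inst$shares, px2, inst$spec, base = "other",
                   vcov = "none")
  b1 <- tidy(fit1); b2 <- tidy(fit2)
  expect_equal(b2$estimate[b2$term == "x1"],
               b1$estimate[b1$term == "x1"] / 10, tolerance = 1e-6)
  expect_equal(fit2$loglik, fit1$loglik, tolerance = 1e-8)
  H1 <- fit1$problem$Hfun(as.numeric(fit1$beta_hat))
  H2 <- fit2$problem$Hfun(as.numeric(fit2$beta_hat))
  expect_equal(H1, H2, tolerance = 1e-8)
})

test_that("iteration exhaustion is flagged, never silent", {
  inst <- tiny_instance(J = 40, max_pix = 4, K = 3, M = 3, seed = 17)
  expect_warning(
    fit <- fit_qmle(inst$shares, inst$pixels, inst$spec, base = "other",
                    vcov = "none", max_iter = 2L),
    "did not converge"
  )
  expect_false(fit$converged)
})

test_that("sandwich covariance is symmetric PSD with matching SEs", {
  inst <- tiny_instance(J = 50, max_pix = 4, K = 2, M = 3, seed = 29)
  fit <- fit_qmle(inst$shares, inst$pixels, inst$spec, base = "other")
  V <- fit$vcov
  expect_equal(V, t(V))
  expect_true(all(eigen(V, symmetric = TRUE, only.values = TRUE)$values >=
                    -1e-10))
  expect_equal(unname(fit$se), unname(sqrt(diag(V))))
  expect_equal(unname(fit$tvalues), unname(fit$beta_hat / fit$se))
})

test_that("score vanishes at the maximizer", {
  inst <- tiny_instance(J = 30, max_pix = 4, K = 3, M = 3, seed = 41)
  fit <- fit_qmle(inst$shares, inst$pixels, inst$spec, base = "other",
                  vcov = "none")
  expect_lt(max(abs(fit$problem$scorefun(as.numeric(fit$beta_hat)))), 1e-6)
})

test_that("block bootstrap is reproducible and rejects degenerate B", {
  inst <- tiny_instance(J = 25, max_pix = 3, K = 2, M = 3, seed = 37)
  fit <- fit_qmle(inst$shares, inst$pixels, inst$spec, base = "other",
                  vcov = "none")
  V1 <- suppressWarnings(block_bootstrap_cov(fit, B = 60, seed = 7))
  V2 <- suppressWarnings(block_bootstrap_cov(fit, B = 60, seed = 7))
  expect_identical(V1, V2)
  V3 <- suppressWarnings(block_bootstrap_cov(fit, B = 60, seed = 8))
  expect_false(identical(V1, V3))
  expect_error(block_bootstrap_cov(fit, B = 1), "fewer than 2")
})

test_that("estimation bias shrinks as the number of units grows", {
  # consistency probe at three sample sizes, Dirichlet noise
  bias <- vapply(c(25, 100, 400), function(J) {
    errs <- vapply(1:30, function(r) {
      cfg <- synthetic_config(J = J, seed = 1000 * J + r,
                              noise = "dirichlet", concentration = 200,
                              exclusion_rate = 0)
      land <- simulate_landscape(cfg)
      y <- simulate_shares(land, cfg)
      f <- fit_qmle(y, land, cfg$design, vcov = "none")
      as.numeric(f$beta_hat) - as.numeric(cfg$beta_true)
    }, numeric(4))
    max(abs(rowMeans(errs)))
  }, numeric(1))
  expect_lt(bias[2], bias[1])
  expect_lt(bias[3], bias[2])
})

test_that("tidy and glance summarise the fit", {
  inst <- tiny_instance(J = 30, max_pix = 3, K = 3, M = 3, seed = 53)
  fit <- fit_qmle(inst$shares, inst$pixels, inst$spec, base = "other")
  td <- tidy(fit)
  expect_equal(nrow(td), 2 * 3)
  expect_named(td, c("crop", "term", "estimate", "std.error", "statistic"))
  expect_setequal(unique(td$crop), c("crop1", "crop2"))
  gl <- glance(fit)
  expect_equal(gl$n_units, 30)
  expect_true(gl$converged)
  expect_lt(gl$grad_norm, 1e-6)
})
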