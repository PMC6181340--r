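# A fitted object with known coefficients, bypassing estimation, so
# effect formulas are tested against exact values.
fake_fit <- function(pixels, spec, beta, crops = c("other", "maize")) {
  W <- build_design(pixels, spec)
  beta <- matrix(beta, nrow = ncol(W))
  prob <- list(pixels = pixels, K = ncol(beta) + 1L)
  structure(
    list(beta_hat = as.numeric(beta), beta_mat = beta, crops = crops,
         base = crops[1], terms = colnames(W), design = spec,
         problem = prob, se = rep(NA_real_, length(beta)),
         tvalues = rep(NA_real_, length(beta))),
    class = "qmle_fit"
  )
}

test_that("zero coefficients give zero marginal effects everywhere", {
  px <- tibble::tibble(pixel_id = c("a", "b"), unit_l1 = "u",
                       area_km2 = 80, x = c(0.2, 1.4), z = c(3, -1))
  spec <- design_spec(term_linear("x"), term_square("x"),
                      term_interaction("x", "z"))
  fit <- fake_fit(px, spec, rep(0, 4))
  me <- marginal_effects(fit, px)
  expect_true(all(me$marginal_effect == 0))
})

test_that("linear-term effect is G(1-G) beta in the two-category model", {
  # G2 = 0.5 at x = 0 with zero intercept; effect on crop 2 = 0.25 * beta
  px <- tibble::tibble(pixel_id = "a", unit_l1 = "u", area_km2 = 80, x = 0)
  spec <- design_spec(term_linear("x"))
  fit <- fake_fit(px, spec, c(0, 1))
  me <- marginal_effects(fit, px)
  expect_equal(me$marginal_effect[me$crop == "maize"], 0.25)
  expect_equal(me$marginal_effect[me$crop == "other"], -0.25)
})

test_that("chain-rule effects match finite differences of pixel shares", {
  withr::with_seed(61, {
    px <- tibble::tibble(
      pixel_id = sprintf("p%02d", 1:20), unit_l1 = "u", area_km2 = 80,
      temp = rnorm(20, 15, 5), precip = rnorm(20, 1, 0.3),
      ph = runif(20, 4.5, 8.5)
    )
    spec <- design_spec(
      term_linear("temp"), term_square("temp"),
      term_interaction("temp", "precip"),
      term_hinge_below("ph", 6.5), term_hinge_above("ph", 6.5)
    )
    beta <- matrix(rnorm(12, sd = 0.3), 6)   # K = 3
    fit <- fake_fit(px, spec, beta, crops = c("other", "maize", "wheat"))
    h <- 1e-6
    for (v in c("temp", "precip")) {
      me <- marginal_effects(fit, px, variables = v, by_pixel = TRUE)
      up <- px; up[[v]] <- up[[v]] + h
      dn <- px; dn[[v]] <- dn[[v]] - h
      fd <- (pixel_shares(build_design(up, spec), beta) -
               pixel_shares(build_design(dn, spec), beta)) / (2 * h)
      expect_lt(max(abs(matrix(me$marginal_effect, ncol = 3) - fd)) /
                  max(abs(fd)), 1e-6)
    }
  })
})

test_that("effects sum to zero across categories at every pixel", {
  inst <- tiny_instance(J = 10, max_pix = 4, K = 4, M = 3, seed = 71)
  fit <- fit_qmle(inst$shares, inst$pixels, inst$spec, base = "other",
                  vcov = "none")
  me <- marginal_effects(fit, by_pixel = TRUE, variables = "x1")
  sums <- tapply(me$marginal_effect, me$pixel_id, sum)
  expect_true(all(abs(sums) < 1e-10))
})

test_that("hinge effects are reported separately and vanish at the pivot", {
  px <- tibble::tibble(pixel_id = c("lo", "at", "hi"), unit_l1 = "u",
                       area_km2 = 80, ph = c(5.0, 6.5, 7.5))
  spec <- design_spec(term_hinge_below("ph", 6.5),
                      term_hinge_above("ph", 6.5))
  fit <- fake_fit(px, spec, c(0, -0.9, -1.6))
  me <- marginal_effects(fit, px, by_pixel = TRUE, variables = "ph")
  m2 <- me[me$crop == "maize", ]
  # below the pivot: d eta/d ph = +0.9 (deviation shrinks); above: -1.6
  G <- pixel_shares(build_design(px, spec), cbind(c(0, -0.9, -1.6)))
  expect_equal(m2$marginal_effect[m2$pixel_id == "lo"],
               G[1, 2] * (1 - G[1, 2]) * 0.9)
  expect_equal(m2$marginal_effect[m2$pixel_id == "at"], 0)  # subgradient 0
  expect_equal(m2$marginal_effect[m2$pixel_id == "hi"],
               G[3, 2] * (1 - G[3, 2]) * -1.6)
})

test_that("odds ratios for linear-entry variables are exp(beta)", {
  px <- tibble::tibble(pixel_id = "a", unit_l1 = "u", area_km2 = 80,
                       soil_carbon = 6, elevation = 0.5)
  spec <- design_spec(term_linear("soil_carbon"), term_linear("elevation"))
  fit <- fake_fit(px, spec, c(-2, 0.157, -0.062))
  orr <- odds_ratios(fit)
  expect_equal(orr$method, rep("exact", 2))
  expect_equal(orr$odds_ratio[orr$variable == "soil_carbon"], exp(0.157))
  expect_equal(orr$odds_ratio[orr$variable == "elevation"], exp(-0.062))
  fit0 <- fake_fit(px, spec, c(-2, 0, 0.3))
  expect_equal(odds_ratios(fit0)$odds_ratio[1], 1)
})

test_that("nonlinear odds ratios average the local log-odds derivative", {
  px <- tibble::tibble(pixel_id = c("a", "b"), unit_l1 = "u",
                       area_km2 = 80, temp = c(10, 20))
  spec <- design_spec(term_linear("temp"), term_square("temp"))
  fit <- fake_fit(px, spec, c(0, 0.5, -0.01))
  orr <- odds_ratios(fit, px)
  expect_equal(orr$method, "average")
  local <- 0.5 + 2 * -0.01 * c(10, 20)
  expect_equal(orr$odds_ratio, mean(exp(local)))
})

test_that("indicator variables get discrete-change effects and exact odds ratios", {
  withr::with_seed(83, {
    px <- tibble::tibble(
      pixel_id = sprintf("p%02d", 1:12), unit_l1 = "u", area_km2 = 80,
      x = rnorm(12), country = rep(c("base", "AR", "US"), 4)
    )
    spec <- design_spec(term_linear("x"),
                        term_indicator("country", base = "base"))
    beta <- c(-1, 0.4, 0.8, -0.5)
    fit <- fake_fit(px, spec, beta)
    me <- marginal_effects(fit, px)
    disc <- me[me$type == "discrete" & me$crop == "maize", ]
    expect_setequal(disc$variable, c("country=AR", "country=US"))
    # oracle: mean share with everyone in AR minus everyone at base
    W <- build_design(px, spec)
    W_ar <- W; W_ar[, "country=AR"] <- 1; W_ar[, "country=US"] <- 0
    W_b <- W; W_b[, "country=AR"] <- 0; W_b[, "country=US"] <- 0
    or_ar <- mean(pixel_shares(W_ar, cbind(beta))[, 2]) -
      mean(pixel_shares(W_b, cbind(beta))[, 2])
    expect_equal(disc$marginal_effect[disc$variable == "country=AR"], or_ar)
    orr <- odds_ratios(fit, px)
    expect_equal(orr$odds_ratio[orr$variable == "country=AR"], exp(0.8))
  })
})

test_that("a variable outside the design yields zero effect with a warning", {
  px <- tibble::tibble(pixel_id = "a", unit_l1 = "u", area_km2 = 80, x = 1,
                       unused = 5)
  fit <- fake_fit(px, design_spec(term_linear("x")), c(0, 1))
  expect_warning(me <- marginal_effects(fit, px, variables = "unused"),
                 "unused")
  expect_true(all(me$marginal_effect == 0))
})
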