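test_that("rmse matches hand computations and is symmetric", {
  p <- tibble::tibble(unit = c("a", "b"), share = c(0.2, 0.5))
  o <- tibble::tibble(unit = c("a", "b"), share = c(0.3, 0.2))
  # errors 0.1 and 0.3 -> sqrt((0.01 + 0.09)/2) = sqrt(0.05)
  expect_equal(share_rmse(p, o)$rmse, sqrt(0.05))
  expect_equal(share_rmse(o, p)$rmse, share_rmse(p, o)$rmse)
  expect_equal(share_rmse(p, p)$rmse, 0)
  # order permutation is irrelevant
  expect_equal(share_rmse(p[2:1, ], o)$rmse, sqrt(0.05))
  # rmse never exceeds the largest absolute error
  expect_lte(share_rmse(p, o)$rmse, 0.3)
})

test_that("rmse errors name the unit-set difference", {
  p <- tibble::tibble(unit = c("a", "b"), share = c(0.2, 0.5))
  o <- tibble::tibble(unit = c("a", "c"), share = c(0.3, 0.2))
  err <- expect_error(share_rmse(p, o), class = "cropdown_unit_mismatch")
  expect_match(conditionMessage(err), "b")
  expect_match(conditionMessage(err), "c")
})

test_that("rmse is computed per crop on multi-crop tables", {
  p <- tidyr::crossing(unit = c("a", "b"), crop = c("maize", "wheat"))
  p$share <- c(0.1, 0.2, 0.3, 0.4)
  o <- p
  o$share <- o$share + c(0.1, 0, 0.1, 0)
  r <- share_rmse(p, o)
  expect_equal(nrow(r), 2)
  expect_equal(r$rmse[r$crop == "maize"], sqrt(0.01))
  expect_equal(r$n_units, c(2, 2))
})

test_that("perfect predictions calibrate to the identity line", {
  x <- c(0.1, 0.2, 0.35, 0.5)
  cal <- calibration(x, x)
  expect_equal(cal$intercept, 0)
  expect_equal(cal$slope, 1)
  expect_equal(cal$r_squared, 1)
  expect_equal(cal$t_intercept_0, 0)
  expect_equal(cal$t_slope_1, 0)
})

test_that("calibration recovers a known linear distortion", {
  x <- c(0.1, 0.2, 0.35, 0.5, 0.6)
  cal <- calibration(x, 2 * x)
  expect_equal(cal$intercept, 0, tolerance = 1e-12)
  expect_equal(cal$slope, 2)
  # slope 2 is significantly different from 1 for an exact fit
  expect_gt(abs(cal$t_slope_1), 2)
})

test_that("r-squared equals the OLS identity slope^2 var(x)/var(y)", {
  withr::with_seed(7, {
    x <- runif(40, 0, 0.5)
    y <- 0.05 + 0.9 * x + rnorm(40, sd = 0.05)
    cal <- calibration(x, y)
    expect_equal(cal$r_squared, cal$slope^2 * var(x) / var(y),
                 tolerance = 1e-12)
    expect_equal(cal$r_squared, cor(x, y)^2)
  })
})

test_that("calibration direction switch and degenerate inputs behave", {
  withr::with_seed(8, {
    x <- runif(20); y <- 0.5 * x + rnorm(20, sd = 0.02)
    c1 <- calibration(x, y)
    c2 <- calibration(x, y, direction = "pred_on_obs")
    expect_false(isTRUE(all.equal(c1$slope, c2$slope)))
    expect_equal(c1$r_squared, c2$r_squared)   # symmetric in direction
    # scaling both series leaves slope and r^2 unchanged
    c3 <- calibration(10 * x, 10 * y)
    expect_equal(c3$slope, c1$slope)
    expect_equal(c3$r_squared, c1$r_squared)
  })
  expect_error(calibration(c(1, 2), c(1, 2)), "at least 3")
  expect_error(calibration(rep(0.3, 5), runif(5)),
               class = "cropdown_zero_variance")
})

test_that("self-consistent truth yields a perfect Level-2 report", {
  cfg <- synthetic_config(J = 25, seed = 311, noise = "none",
                          exclusion_rate = 0)
  land <- simulate_landscape(cfg)
  y1 <- simulate_shares(land, cfg)
  y2 <- simulate_shares(land, cfg, level = "unit_l2")
  fit <- fit_qmle(y1, land, cfg$design, vcov = "none")
  grid <- scale_to_level1(predict_pixels(fit), y1, crops = "maize")
  rep2 <- level2_report(grid, y2[y2$crop == "maize", ])
  expect_equal(rep2$level, 2)
  expect_lt(rep2$rmse, 1e-6)
  expect_equal(rep2$r_squared, 1, tolerance = 1e-6)
  expect_equal(rep2$slope, 1, tolerance = 1e-3)
  expect_equal(rep2$intercept, 0, tolerance = 1e-4)
})

test_that("partial Level-2 coverage restricts the report to observed units", {
  cfg <- synthetic_config(J = 20, seed = 313, noise = "none",
                          exclusion_rate = 0)
  land <- simulate_landscape(cfg)
  y1 <- simulate_shares(land, cfg)
  y2 <- simulate_shares(land, cfg, level = "unit_l2")
  fit <- fit_qmle(y1, land, cfg$design, vcov = "none")
  grid <- scale_to_level1(predict_pixels(fit), y1, crops = "maize")
  l2_units <- unique(y2$unit_l2)
  half <- y2[y2$unit_l2 %in% l2_units[seq_len(floor(length(l2_units) / 2))] &
               y2$crop == "maize", ]
  rep2 <- level2_report(grid, half)
  expect_equal(rep2$n_units, dplyr::n_distinct(half$unit_l2))
  none <- dplyr::mutate(half, unit_l2 = paste0("zz", unit_l2))
  expect_error(level2_report(grid, none), class = "cropdown_unit_mismatch")
})

test_that("in a unit-constant world the naive baseline beats the model", {
  # truth: shares constant within each Level-2 unit, drawn independently
  # of the covariates, so the covariate-driven model cannot match the
  # naive allocation that knows the Level-2 values
  withr::with_seed(101, {
    cfg <- synthetic_config(J = 15, seed = 555, noise = "none",
                            exclusion_rate = 0)
    land <- simulate_landscape(cfg)
    l2 <- unique(land[, c("unit_l1", "unit_l2")])
    truth2 <- tidyr::crossing(l2, crop = "maize")
    truth2$share <- runif(nrow(truth2), 0.05, 0.4)
    truth2 <- dplyr::bind_rows(
      truth2,
      dplyr::mutate(truth2, crop = "other", share = 1 - share)
    )
    # Level-1 observed shares implied by the unit-constant truth
    naive <- naive_allocation(truth2[, c("unit_l2", "crop", "share")], land)
    y1 <- aggregate_shares(naive, level = "unit_l1") |>
      dplyr::rename(unit_l1 = "unit")
    fit <- fit_qmle(y1, land, cfg$design, vcov = "none")
    grid <- scale_to_level1(predict_pixels(fit), y1, crops = "maize")
    obs2 <- truth2[truth2$crop == "maize", c("unit_l2", "crop", "share")]
    r_model <- level2_report(grid, obs2)$rmse
    r_naive <- level2_report(naive, obs2)$rmse
    expect_lt(r_naive, r_model)
    expect_lt(r_naive, 1e-12)
  })
})
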