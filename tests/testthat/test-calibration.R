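test_that("water line recovers an exact line and matches the normal equations", {
  x <- c(-11, -10.2, -9.1, -8.4, -7.9)
  wl <- fit_water_line(x, 8 * x + 10)
  expect_equal(wl$slope, 8)
  expect_equal(wl$intercept, 10)
  expect_equal(wl$r_squared, 1)
  expect_equal(wl$s_yx, 0, tolerance = 1e-10)

  # 3-point instance against the closed-form normal equations
  x3 <- c(0, 1, 2)
  y3 <- c(0, 8, 17)
  wl3 <- fit_water_line(x3, y3)
  beta <- ols_oracle(cbind(1, x3), y3)
  expect_equal(unname(coef(wl3)), unname(beta), tolerance = 1e-12)
  expect_equal(wl3$s_yx, sqrt(sum((y3 - beta[1] - beta[2] * x3)^2) / 1),
               tolerance = 1e-12)
})

test_that("water line recovers generating parameters from noisy farm waters", {
  set.seed(201)
  x <- runif(40, -11.4, -7.8)
  y <- 8.33 * x + 16.3 + rnorm(40, 0, 1.6)
  wl <- fit_water_line(x, y)
  expect_lt(abs(wl$slope - 8.33), 3 * wl$slope_se)
  expect_lt(abs(wl$intercept - 16.3), 3 * wl$intercept_se)
})

test_that("water line rejects degenerate inputs", {
  expect_error(fit_water_line(c(-9, -9, -9), c(-60, -59, -58)), "singular")
  expect_error(fit_water_line(c(-9, -8), c(-60, -52)), "at least 3")
})

test_that("all regression fits agree with a normal-equations oracle", {
  set.seed(202)
  for (rep in 1:10) {
    n <- sample(6:20, 1)
    t <- sort(runif(n, 1, 365))
    y <- rnorm(n, -8, 1)
    # line
    wl <- fit_water_line(t, y)
    bl <- ols_oracle(cbind(1, t), y)
    expect_equal(unname(coef(wl)), unname(bl), tolerance = 1e-8)
    # quartic (descending powers)
    fq <- fit_quartic(t, y)
    expect_equal(unname(coef(fq)), quartic_oracle(t, y), tolerance = 1e-8)
  }
})

test_that("quartic fit interpolates exact quartic data and handles constants", {
  co <- c(2e-9, -1e-6, 3e-4, -1.5e-2, -8)
  t <- c(10, 80, 150, 220, 290, 360)
  y <- co[1] * t^4 + co[2] * t^3 + co[3] * t^2 + co[4] * t + co[5]
  fq <- fit_quartic(t, y)
  expect_equal(unname(coef(fq)), co, tolerance = 1e-6)
  expect_equal(fq$s_yx, 0, tolerance = 1e-8)

  fc <- fit_quartic(seq(10, 360, by = 50), rep(-8.5, 8))
  expect_equal(unname(coef(fc))[1:4], rep(0, 4), tolerance = 1e-12)
  expect_equal(unname(coef(fc))[5], -8.5, tolerance = 1e-9)
})

test_that("quartic fit rejects undersized or rank-deficient designs", {
  expect_error(fit_quartic(c(1, 50, 100, 200, 300), rnorm(5)), "at least 6")
  expect_error(fit_quartic(rep(c(1, 100, 200, 300), 2), rnorm(8)),
               "singular")
  expect_error(fit_quartic(1:10, rnorm(10), shed_id = rep("A", 10),
                           exclude = "A"), "at least 6")
})

test_that("quartic refit stays near the generating seasonal curve", {
  truth <- milk_calibration("milk_d18O")
  tt <- 1:365
  set.seed(203)
  stats <- replicate(50, {
    t20 <- round(seq(5, 362, length.out = 20))
    y20 <- predict(truth, t20)$fit + rnorm(20, 0, 0.92)
    fq <- fit_quartic(t20, y20)
    dev <- abs(predict(fq, tt)$fit - predict(truth, tt)$fit)
    band <- 1.645 * fq$s_yx
    c(all_in = all(dev <= band), frac_in = mean(dev <= band))
  })
  # the truth lies inside the 1.645 s_yx band at nearly every day, and over
  # the whole domain in the large majority of replicates (edge wiggles of a
  # 20-point quartic occasionally escape the band)
  expect_gt(mean(stats["frac_in", ]), 0.95)
  expect_gt(mean(stats["all_in", ]), 0.65)
})

test_that("about 90% of held-out observations fall in the 1.645 s_yx band", {
  truth <- milk_calibration("milk_d18O")
  set.seed(204)
  t <- sample(1:365, 400, replace = TRUE)
  y <- predict(truth, t)$fit + rnorm(400, 0, 0.92)
  fit <- fit_quartic(t[1:200], y[1:200])
  p <- predict(fit, t[201:400])
  coverage <- mean(y[201:400] >= p$lower & y[201:400] <= p$upper)
  # binomial tolerance at n = 200: 0.90 +/- 3 * sqrt(0.9 * 0.1 / 200)
  expect_lt(abs(coverage - 0.90), 3 * sqrt(0.9 * 0.1 / 200))
})

test_that("quartic predictions are exact polynomial evaluations", {
  calib <- milk_calibration("alpha_indoor")
  t <- c(0, 1, 36, 150, 182, 222, 358, 365)
  horner <- predict(calib, t)$fit
  co <- coef(calib)
  naive <- co[1] * t^4 + co[2] * t^3 + co[3] * t^2 + co[4] * t + co[5]
  expect_equal(horner, unname(naive), tolerance = 1e-12)
})

test_that("bundled milk-delta calibration reproduces published predictions", {
  calib <- milk_calibration("milk_d18O")
  expect_equal(round(predict_milk_delta(20)$fit, 2), -8.11)
  expect_equal(round(predict_milk_delta(358)$fit, 2), -8.21)
  expect_identical(predict_milk_delta(0)$fit, -7.91)
  p <- predict_milk_delta(100)
  expect_equal(p$upper - p$fit, 1.645 * calib$s_yx)
  expect_equal(p$fit - p$lower_s, calib$s_yx)
  expect_error(predict_milk_delta(400), "0..365")
  expect_error(predict_milk_delta(20, milk_calibration("alpha_all")),
               "milk_d18O calibration")
})

test_that("bundled alpha calibrations reproduce published predictions", {
  indoor <- milk_calibration("alpha_indoor")
  expect_equal(round(predict_alpha(36, indoor), 6), 1.001058)
  expect_equal(round(predict_alpha(150, indoor), 6), 1.002534)
  expect_identical(predict_alpha(0, indoor), 1.0012)
  expect_identical(predict_alpha(0, milk_calibration("alpha_all")), 1.0012)
})

test_that("alpha prediction uncertainty follows the root-sum formula with shipped overrides", {
  indoor <- milk_calibration("alpha_indoor")
  all_sheds <- milk_calibration("alpha_all")
  expect_equal(alpha_prediction_uncertainty(all_sheds, recompute = TRUE),
               sqrt(0.50^2 + 0.50^2 / 108))
  expect_equal(alpha_prediction_uncertainty(indoor, recompute = TRUE),
               sqrt(0.41^2 + 0.41^2 / 84))
  # shipped constants drive the published thresholds
  expect_identical(alpha_prediction_uncertainty(all_sheds), 0.51)
  expect_identical(alpha_prediction_uncertainty(indoor), 0.42)
  zero <- quartic_calibration(c(0, 0, 0, 0, 1.001), n = 50, s_yx = 0,
                              response = "alpha")
  expect_identical(alpha_prediction_uncertainty(zero), 0)
})

test_that("loess smoother reproduces linear structure and tracks the quartic", {
  t <- seq(5, 360, length.out = 30)
  y <- -8 + 0.004 * t
  lo <- loess_smooth(t, y, span = 0.2)
  expect_equal(lo$fit, y, tolerance = 1e-8)
  lo1 <- loess_smooth(t, y, span = 1)
  expect_equal(lo1$fit, y, tolerance = 1e-8)

  truth <- milk_calibration("milk_d18O")
  set.seed(205)
  t84 <- rep(round(seq(15, 350, length.out = 12)), 7)
  y84 <- predict(truth, t84)$fit + rnorm(84, 0, 0.92)
  refit <- fit_quartic(t84, y84)
  lo2 <- loess_smooth(t84, y84, span = 0.2)
  rms <- sqrt(mean((lo2$fit - predict(refit, lo2$t)$fit)^2))
  expect_lt(rms, refit$s_yx)

  expect_error(loess_smooth(t[1:5], y[1:5]), "at least 10")
  expect_error(loess_smooth(t, y, span = 0.05), "window too small")
})

test_that("calibration files round-trip through text", {
  calib <- milk_calibration("alpha_indoor")
  path <- withr::local_tempfile(fileext = ".txt")
  write_calibration(calib, path)
  back <- read_calibration(path)
  expect_equal(back$coefficients, calib$coefficients)
  expect_identical(back$n, calib$n)
  expect_equal(back$s_yx, calib$s_yx)
  expect_identical(back$u_pred, 0.42)
  expect_identical(back$excluded_sheds, calib$excluded_sheds)
  expect_identical(back$name, "alpha_indoor")
  expect_error(read_calibration(withr::local_tempfile(lines = "x: 1")),
               "not an isomilk calibration")
})
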