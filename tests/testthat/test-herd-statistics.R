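test_that("two-way ANOVA matches a hand-computed sum-of-squares oracle", {
  m <- matrix(c(1, 4, 6,
                2, 5, 7,
                4, 6, 11), nrow = 3, byrow = TRUE)
  av <- two_way_anova(m)
  # brute-force decomposition
  gm <- mean(m)
  ss_row <- ncol(m) * sum((rowMeans(m) - gm)^2)
  ss_col <- nrow(m) * sum((colMeans(m) - gm)^2)
  ss_tot <- sum((m - gm)^2)
  ss_err <- ss_tot - ss_row - ss_col
  expect_equal(av$table$sum_sq, c(ss_row, ss_col, ss_err), tolerance = 1e-12)
  expect_equal(av$s2_row, ss_row / (nrow(m) - 1))
  expect_equal(av$s2_col, ss_col / (ncol(m) - 1))
  expect_equal(av$s2_error, ss_err / ((nrow(m) - 1) * (ncol(m) - 1)))
  # additivity to total SS
  expect_equal(sum(av$table$sum_sq), ss_tot, tolerance = 1e-10)
})

test_that("ANOVA mean squares are invariant to adding a constant", {
  set.seed(301)
  m <- matrix(rnorm(48), nrow = 12)
  a1 <- two_way_anova(m)
  a2 <- two_way_anova(m + 5)
  expect_equal(a1$table$mean_sq, a2$table$mean_sq, tolerance = 1e-10)
})

test_that("ANOVA degenerate and invalid designs are handled", {
  ident <- matrix(rep(c(1, 2, 3), each = 4), nrow = 4)
  expect_equal(two_way_anova(ident)$s2_row, 0)
  bad <- matrix(c(1, NA, 3, 4), nrow = 2)
  expect_error(two_way_anova(bad), "incomplete design")
  expect_error(two_way_anova(matrix(1:3, nrow = 3)), "at least 2")
})

test_that("seasonal signal dominates the ANOVA of synthetic herd alpha values", {
  sim <- simulate_herd_year(herd_config(seed = 1))
  # records are ordered shed-fastest: rows = months, columns = sheds
  m <- matrix(compute_alpha(sim$d18O_M, sim$d18O_W), nrow = 12, byrow = TRUE)
  av <- two_way_anova(m)
  expect_gt(av$s2_row, av$s2_col)
  expect_gt(av$s2_col, av$s2_error)
})

test_that("alpha-temperature regression is exact on linear data", {
  temp <- seq(0, 25, length.out = 12)
  rec <- data.frame(alpha = 7e-5 * temp + 1.0005, temp_2wk = temp)
  ft <- fit_alpha_vs_temperature(rec)
  expect_equal(ft$slope, 7e-5, tolerance = 1e-12)
  expect_equal(ft$intercept, 1.0005, tolerance = 1e-10)
  expect_equal(ft$r, 1)
})

test_that("alpha-temperature slope is recovered from a synthetic indoor shed", {
  cfg <- indoor_config(n_sheds = 1, water_d18O_means = -9.5,
                       alpha_temp_slope_range = c(6.9e-5, 6.9e-5), seed = 11)
  sim <- simulate_herd_year(cfg)
  ft <- fit_alpha_vs_temperature(sim)
  expect_lt(abs(ft$slope - 6.9e-5), 2 * ft$slope_se)
  expect_equal(ft$n, 12L)
})

test_that("outdoor grazing inflates the fitted temperature slope", {
  cfg <- herd_config(n_sheds = 2, water_d18O_means = c(-9.5, -9.5),
                     alpha_temp_slope_range = c(7e-5, 7e-5),
                     outdoor_sheds = "S2", seed = 12)
  sim <- simulate_herd_year(cfg)
  indoor <- fit_alpha_vs_temperature(sim[sim$shed_id == "S1", ])
  outdoor <- fit_alpha_vs_temperature(sim[sim$shed_id == "S2", ])
  expect_gt(outdoor$slope, indoor$slope)
})

test_that("alpha-temperature regression skips and reports missing temperatures", {
  temp <- c(NA, seq(2, 22, length.out = 11))
  rec <- data.frame(alpha = 7e-5 * ifelse(is.na(temp), 0, temp) + 1.0005,
                    temp_2wk = temp)
  ft <- fit_alpha_vs_temperature(rec)
  expect_identical(ft$n_skipped, 1L)
  expect_identical(ft$n, 11L)
  rec$temp_2wk <- NA_real_
  expect_error(fit_alpha_vs_temperature(rec), "insufficient data")
  expect_error(
    fit_alpha_vs_temperature(data.frame(shed_id = c("A", "B"),
                                        alpha = c(1, 1),
                                        temp_2wk = c(1, 2))),
    "single shed")
})

test_that("deuterium-excess difference tracks temperature under metabolic enrichment", {
  sim <- simulate_herd_year(herd_config(seed = 1))
  expect_gt(dex_temperature_correlation(sim), 0.7)
  # null: temperature-independent enrichment
  null_cfg <- herd_config(alpha_temp_slope_range = c(0, 0),
                          alpha_intercept_mean = 1.0012,
                          dex_temp_slope = 0,
                          outdoor_sheds = character(), seed = 2)
  null_sim <- simulate_herd_year(null_cfg)
  expect_lt(abs(dex_temperature_correlation(null_sim)), 0.3)
})

test_that("deuterium-excess correlation degenerates gracefully", {
  rec <- data.frame(d2H_W = c(-60, -61, -59), d18O_W = c(-9, -9.1, -8.9),
                    d2H_M = c(-50, -51, -49), d18O_M = c(-7, -7.1, -6.9),
                    temp_2wk = c(10, 10, 10))
  expect_warning(r <- dex_temperature_correlation(rec), "not computable")
  expect_true(is.na(r))
  expect_error(dex_temperature_correlation(rec[1:2, ]), "insufficient data")
  expect_error(dex_temperature_correlation(rec[, -1]), "missing column")
})

test_that("cold/warm regressions find parallel lines with a summer intercept shift", {
  set.seed(302)
  sheds <- sprintf("S%d", 1:8)
  w <- seq(-11, -8, length.out = 8)
  base <- 0.8 * w - 1.0
  cold <- data.frame(shed_id = sheds, month = 1L, d18O_W = w,
                     d18O_M = base + rnorm(8, 0, 0.05))
  warm <- data.frame(shed_id = sheds, month = 7L, d18O_W = w,
                     d18O_M = base + 1.4 + rnorm(8, 0, 0.05))
  pf <- periodic_regressions(rbind(cold, warm))
  expect_gt(pf$p_same_slope, 0.05)
  expect_equal(pf$intercept_diff, 1.4, tolerance = 0.35)

  # identical data in both periods: slopes identical, p in the ~1 region
  same <- rbind(cold, transform(cold, month = 7L))
  pf2 <- periodic_regressions(same)
  expect_equal(pf2$warm$slope, pf2$cold$slope)
  expect_equal(pf2$p_same_slope, 1)
})

test_that("cold/warm regression slope test detects truly different slopes", {
  set.seed(303)
  sheds <- sprintf("S%d", 1:10)
  w <- seq(-11, -8, length.out = 10)
  cold <- data.frame(shed_id = sheds, month = 12L, d18O_W = w,
                     d18O_M = 0.5 * w - 2 + rnorm(10, 0, 0.02))
  warm <- data.frame(shed_id = sheds, month = 6L, d18O_W = w,
                     d18O_M = 1.0 * w + 1 + rnorm(10, 0, 0.02))
  pf <- periodic_regressions(rbind(cold, warm))
  expect_lt(pf$p_same_slope, 0.01)
})

test_that("periodic regressions demand enough sheds and a time column", {
  rec <- data.frame(shed_id = c("A", "B"), month = c(1L, 7L),
                    d18O_W = c(-9, -9), d18O_M = c(-8, -7))
  expect_error(periodic_regressions(rec), "fewer than 3 sheds")
  expect_error(periodic_regressions(data.frame(shed_id = "A", d18O_W = -9,
                                               d18O_M = -8)),
               "`month`, `t` or `date`")
})
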