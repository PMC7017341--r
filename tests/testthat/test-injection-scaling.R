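test_that("power-law fit is exact on noiseless 1/L data", {
  d <- data.frame(length_um = c(2, 5, 10, 25),
                  injection_rate_au_s = 100 / c(2, 5, 10, 25))
  fit <- fit_power_law(d)
  expect_equal(fit$slope, -1, tolerance = 1e-12)
  expect_equal(fit$intercept, 2, tolerance = 1e-12)
  expect_false(fit$constrained)
  expect_equal(predict(fit, data.frame(length_um = 4)), 25, tolerance = 1e-10)

  # constrained fit through a single point
  one <- data.frame(length_um = 8, injection_rate_au_s = 12.5)
  fc <- fit_power_law(one, fix_slope = -1)
  expect_identical(fc$slope, -1)
  expect_equal(predict(fc, one), 12.5, tolerance = 1e-12)

  expect_error(fit_power_law(one), "at least 2")
  expect_error(
    fit_power_law(data.frame(length_um = c(1, -2),
                             injection_rate_au_s = c(1, 2))),
    "rows"
  )
})

test_that("free-slope estimate lands near -1 under lognormal scatter", {
  set.seed(50)
  slopes <- replicate(10, {
    L <- runif(50, 3, 25)
    d <- data.frame(length_um = L,
                    injection_rate_au_s = 80 / L * 10^rnorm(50, 0, 0.1))
    fit_power_law(d)$slope
  })
  expect_true(all(abs(slopes + 1) < 0.15))
})

test_that("mean log deviation measures the fold offset from the trend", {
  set.seed(60)
  L <- runif(40, 4, 20)
  wt <- data.frame(length_um = L,
                   injection_rate_au_s = 60 / L * 10^rnorm(40, 0, 0.12))
  fit <- fit_power_law(wt)
  # OLS residuals average to zero on the training strain
  expect_equal(mean_log_deviation(wt, fit)$mean, 0, tolerance = 1e-12)

  # data constructed at exactly 1.7x the trend
  up <- wt
  up$injection_rate_au_s <- 1.7 * predict(fit, wt)
  expect_equal(mean_log_deviation(up, fit)$mean, log10(1.7),
               tolerance = 1e-12)

  # noisy mutant: mean deviation within 2 SE of the planted log fold
  Lm <- runif(30, 12, 24)
  mut <- data.frame(length_um = Lm,
                    injection_rate_au_s = 1.7 * 60 / Lm * 10^rnorm(30, 0, 0.14))
  dv <- mean_log_deviation(mut, fit_power_law(wt, fix_slope = -1))
  expect_lt(abs(dv$mean - log10(1.7)), 2 * dv$sd / sqrt(dv$n))
})

test_that("deviation-to-fold conversion reproduces printed pairings", {
  expect_equal(fold_from_deviation(0), 1)
  # each printed deviation maps to its printed fold at one-decimal rounding
  devs <- c(0.24, 0.25, 0.18, 0.19, 0.22, 0.23)
  folds <- c(1.7, 1.8, 1.5, 1.5, 1.7, 1.7)
  expect_equal(round_half_away(fold_from_deviation(devs), 1), folds)
})

test_that("free and constrained deviations agree when the free slope is -1", {
  d <- data.frame(length_um = c(2, 4, 8, 16),
                  injection_rate_au_s = 100 / c(2, 4, 8, 16))
  target <- data.frame(length_um = c(5, 9),
                       injection_rate_au_s = c(31, 19))
  f_free <- fit_power_law(d)
  f_m1 <- fit_power_law(d, fix_slope = -1)
  expect_equal(mean_log_deviation(target, f_free)$mean,
               mean_log_deviation(target, f_m1)$mean, tolerance = 1e-10)
})

test_that("strain summaries compare every strain to the wild-type trends", {
  set.seed(70)
  L <- runif(30, 5, 15)
  wt <- data.frame(strain = "wt", length_um = L,
                   injection_rate_au_s = 50 / L * 10^rnorm(30, 0, 0.1))
  clone <- wt
  clone$strain <- "mutX"
  su <- build_strain_summaries(rbind(wt, clone))
  row <- su[su$strain == "mutX", ]
  expect_equal(row$fold_change_length, 1)
  expect_equal(row$fold_injection_bestfit, 1, tolerance = 1e-10)
  expect_equal(row$fold_injection_slope1,
               fold_from_deviation(row$dev_slope1_mean))
  expect_equal(row$predicted_fold_length_bestfit, 1, tolerance = 1e-10)

  expect_error(build_strain_summaries(wt, wt_label = "absent"), "wild-type")
})

test_that("printed per-strain statistics reproduce both summary tables", {
  su <- summaries_from_printed(printed_strain_stats(), d_over_a = 8)
  t_inj <- format_injection_table(su)
  t_pred <- format_prediction_table(su)

  i <- match(c("lf1", "lf2-1", "lf4"), t_inj$strain)
  expect_equal(t_inj$fold_change_length[i], c(1.8, 1.7, 2.0))
  expect_equal(t_inj$fold_injection_bestfit[i], c(1.7, 1.5, 1.7))
  expect_equal(t_inj$fold_injection_slope1[i], c(1.8, 1.5, 1.7))

  j <- match(c("lf1", "lf2-1", "lf4"), t_pred$strain)
  expect_equal(t_pred$predicted_fold_length_bestfit[j], c(1.5, 1.4, 1.5))
  expect_equal(t_pred$predicted_fold_length_slope1[j], c(1.5, 1.4, 1.5))
})
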