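test_that("binomial null model reproduces the worked occupancy examples", {
  # each particle half-occupied: train occupancy 50%, 75%, 15/16 at N = 1, 2, 4
  expect_equal(occupancy_probability(0.5, 1), 0.5)
  expect_equal(occupancy_probability(0.5, 2), 0.75)
  expect_equal(occupancy_probability(0.5, 4), 15 / 16)
  expect_equal(p_empty(0, c(0, 3, 10)), c(1, 1, 1))
  expect_equal(p_empty(1, 2), 0)
  expect_error(p_empty(1.2, 1), "p_bound")
  expect_error(p_empty(0.5, -1), "N")
})

test_that("emptiness probabilities multiply over sub-trains", {
  set.seed(31)
  for (i in 1:20) {
    p <- runif(1)
    n1 <- runif(1, 0, 12)
    n2 <- runif(1, 0, 12)
    expect_equal(p_empty(p, n1 + n2), p_empty(p, n1) * p_empty(p, n2),
                 tolerance = 1e-12)
  }
})

test_that("log10 emptiness is exactly linear in train size", {
  for (p in c(0.2, 0.5, 0.8)) {
    N <- seq(0.5, 15, by = 0.5)
    expect_lt(max(abs(log10(p_empty(p, N)) - N * log10(1 - p))), 1e-12)
  }
})

test_that("train-size map evaluates and inverts the log-linear fit", {
  expect_equal(train_size_from_length(1), 16)
  expect_equal(train_size_from_length(10), 16 - 9.96)
  # round trip over the valid range
  N <- c(1, 4, 9, 15)
  expect_equal(train_size_from_length(length_from_train_size(N)), N,
               tolerance = 1e-12)
  # out of range: error states the valid lengths
  expect_error(train_size_from_length(45), "valid lengths")
})

test_that("predicted occupancy declines with length", {
  L <- seq(2, 30, length.out = 40)
  cur <- predict_occupancy_curve(0.3, L)
  expect_true(all(diff(cur$predicted_occupancy) < 0))
  expect_equal(predict_occupancy_curve(1, L)$predicted_occupancy,
               rep(1, length(L)))
  expect_equal(predict_occupancy_curve(0.5, 1)$predicted_occupancy,
               1 - 0.5^16)
})

test_that("binding probability is recovered from occupancy observations", {
  # noiseless construction inverts exactly
  L <- seq(3, 30, length.out = 15)
  N <- train_size_from_length(L)
  obs <- data.frame(length_um = L,
                    fraction_occupied = 1 - (1 - 0.5)^N)
  est <- estimate_p_bound(obs)
  expect_equal(est$p_bound, 0.5, tolerance = 1e-10)
  expect_lt(max(abs(est$residuals)), 1e-10)

  # saturated rows are excluded with a warning and counted
  obs2 <- rbind(obs, data.frame(length_um = 2, fraction_occupied = 1))
  expect_warning(est2 <- estimate_p_bound(obs2), "excluded")
  expect_equal(est2$n_excluded_full, 1)
  expect_equal(est2$n_used, nrow(obs))

  # free-intercept variant reports the diagnostic intercept
  est3 <- estimate_p_bound(obs, zero_intercept = FALSE)
  expect_equal(est3$intercept_log10, 0, tolerance = 1e-8)
})

test_that("binomial sampling noise leaves the estimate within +/- 0.05", {
  errs <- vapply(1:20, function(s) {
    d <- make_occupancy_dataset(0.4, trains_per_length = 50, seed = 300 + s)
    suppressWarnings(abs(estimate_p_bound(d$data)$p_bound - 0.4))
  }, numeric(1))
  expect_true(all(is.finite(errs)))
  expect_lt(stats::median(errs), 0.05)
})
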