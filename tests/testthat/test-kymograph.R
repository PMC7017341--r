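test_that("angle/speed conversion is an exact unit conversion", {
  # 1 px/frame at 0.1 um/px, 0.05 s/frame = 2 um/s (45 degrees)
  expect_equal(speed_from_angle(45, 0.1, 0.05), 2)
  # 90 degrees = stationary
  expect_equal(speed_from_angle(90, 0.1, 0.05), 0)
  expect_error(speed_from_angle(0, 0.1, 0.05))
  # inverse round trip across the anterograde range
  for (sp in c(0.5, 1.5, 2, 3.7)) {
    expect_equal(
      speed_from_angle(angle_from_speed(sp, 0.1, 0.05), 0.1, 0.05), sp,
      tolerance = 1e-12
    )
  }
  expect_equal(angle_from_speed(0, 0.1, 0.05), 90)
})

test_that("projection-contrast search recovers the generating angle", {
  sk <- make_kymograph(n_trains = 8, speed_um_s = 2, noise_sd = 0,
                       departures = "uniform", seed = 1)
  bp <- best_projection_angle(sk$kymograph)
  expect_lt(abs(bp$angle_deg - angle_from_speed(2, 0.1, 0.05)), 0.25)

  # a stationary streak (same position in every frame) selects 90 degrees
  m <- matrix(0, 40, 40)
  m[18:20, ] <- 10
  bp90 <- best_projection_angle(m, angle_grid = c(30, 60, 90), refine = FALSE)
  expect_equal(bp90$angle_deg, 90)

  # featureless image: no contrast at any angle
  expect_error(best_projection_angle(matrix(5, 20, 20)), "no traces")
})

test_that("selected angle maximises contrast over the whole grid", {
  sk <- make_kymograph(n_trains = 6, speed_um_s = 1.7, noise_sd = 1,
                       departures = "uniform", seed = 4)
  grid <- seq(20, 90, by = 1)
  bp <- best_projection_angle(sk$kymograph, angle_grid = grid)
  others <- vapply(grid, function(a) {
    best_projection_angle(sk$kymograph, angle_grid = a, refine = FALSE)$contrast
  }, numeric(1))
  expect_true(all(bp$contrast >= others - 1e-8))
})

test_that("peak detection recovers separated peak areas", {
  x <- seq_len(200)
  prof <- 10 / sqrt(2 * pi * 9) * exp(-(x - 60)^2 / 18) +
    20 / sqrt(2 * pi * 9) * exp(-(x - 140)^2 / 18)
  pk <- detect_trains(prof)
  expect_equal(nrow(pk), 2)
  expect_equal(pk$area, c(10, 20), tolerance = 0.05)

  expect_equal(nrow(detect_trains(rep(1, 50))), 0)

  # 12 traces at 10% relative noise are all found
  sk <- make_kymograph(n_trains = 12, speed_um_s = 2, noise_sd = 1,
                       duration_s = 18, departures = "uniform", seed = 2)
  res <- analyze_kymograph(sk$kymograph)
  expect_equal(res$n_trains, 12)
})

test_that("kymograph statistics match their definitions on exact spacing", {
  # 11 trains spaced over a 10 s departure window: frequency 1/s
  sp <- 2
  sk <- make_kymograph(n_trains = 11, speed_um_s = sp, train_intensity_cv = 0,
                       noise_sd = 0.5, duration_s = 10 + 10 / sp,
                       departures = "uniform", seed = 3)
  res <- analyze_kymograph(sk$kymograph)
  expect_equal(res$n_trains, 11)
  expect_equal(res$frequency_per_s, 1, tolerance = 0.02)
  expect_equal(res$speed_um_s, sp, tolerance = 0.02)
  expect_equal(res$mean_magnitude_au, mean(sk$truth$magnitudes_au),
               tolerance = 0.05)
  # definitional identity
  expect_identical(res$injection_rate_au_s,
                   res$frequency_per_s * res$mean_magnitude_au)
})

test_that("a single train yields a speed but an undefined frequency", {
  sk <- make_kymograph(n_trains = 1, speed_um_s = 2, noise_sd = 0.5,
                       departures = "uniform", seed = 5)
  expect_warning(res <- analyze_kymograph(sk$kymograph), "undefined")
  expect_false(res$frequency_defined)
  expect_true(is.na(res$frequency_per_s))
  expect_equal(res$speed_um_s, 2, tolerance = 0.05)
})

test_that("analysis is equivariant under intensity rescaling", {
  sk <- make_kymograph(n_trains = 7, speed_um_s = 2.2, noise_sd = 1,
                       departures = "uniform", seed = 6)
  k1 <- sk$kymograph
  k2 <- kymograph(3 * k1$intensity, k1$pixel_size_um, k1$frame_interval_s)
  r1 <- analyze_kymograph(k1)
  r2 <- analyze_kymograph(k2)
  expect_equal(r2$projection_angle_deg, r1$projection_angle_deg)
  expect_equal(r2$frequency_per_s, r1$frequency_per_s)
  expect_equal(r2$magnitudes_au, 3 * r1$magnitudes_au, tolerance = 1e-8)
  expect_equal(r2$injection_rate_au_s, 3 * r1$injection_rate_au_s,
               tolerance = 1e-8)
})

test_that("kymograph container validates its inputs", {
  expect_error(kymograph(matrix(1, 4, 4), 0.1, 0.05), "8 x 8")
  expect_error(kymograph(matrix(-1, 10, 10), 0.1, 0.05), "non-negative")
  expect_error(kymograph(matrix(1, 10, 10), 0, 0.05), "pixel_size_um")
})
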