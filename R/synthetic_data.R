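#' Generate a synthetic IFT kymograph with known ground truth
#'
#' Renders idealised anterograde IFT traces -- straight lines of constant
#' speed with a Gaussian cross-section -- over additive Gaussian noise, in
#' the row = space (row 1 = flagellar base), column = time convention used
#' by [kymograph()]. No optical point-spread or TIRF physics is simulated.
#' Each train departs the base at a recorded time, travels at the common
#' speed and disappears at the flagellar tip; its rendered integrated
#' intensity (before noise) is recorded as the ground-truth magnitude.
#'
#' @param n_trains Number of trains (default 11).
#' @param speed_um_s Anterograde speed, um/s (default 2, typical of
#'   kinesin-2-driven IFT).
#' @param train_intensity_mean Mean peak amplitude per train, a.u.
#'   (default 10).
#' @param train_intensity_cv Coefficient of variation of train amplitude
#'   (default 0.2).
#' @param trace_width_px Gaussian cross-section SD, px (default 1.5).
#' @param noise_sd Additive Gaussian noise SD, a.u. (default 1; amplitude /
#'   noise_sd is the SNR). Negative pixels are clipped to zero.
#' @param background_au Uniform background level (camera offset plus
#'   out-of-focus fluorescence), a.u. (default 5). Keeps the noise floor
#'   clear of the zero-clipping boundary, as in a real detector.
#' @param duration_s Movie duration, s (default 17; leaves a 12 s departure
#'   window after the 5 s tip transit at the defaults).
#' @param flagellum_length_um Flagellar length, um (default 10).
#' @param pixel_size_um Spatial calibration (default 0.1 um/px).
#' @param frame_interval_s Temporal calibration (default 0.05 s/frame).
#' @param departures `"poisson"` (default; departure times uniform over the
#'   feasible window, i.e. a conditioned homogeneous Poisson process) or
#'   `"uniform"` (evenly spaced, for exact-frequency tests).
#' @param seed Optional integer; fixes the output bit-exactly.
#' @return List with `kymograph` (a [kymograph()]) and `truth`: list with
#'   `departures_s`, `amplitudes_au`, `magnitudes_au` (rendered integrated
#'   intensity per train), `speed_um_s`, `frequency_per_s` (empirical,
#'   (n-1)/departure span), `n_trains`, `seed`.
#' @export
make_kymograph <- function(n_trains = 11, speed_um_s = 2,
                           train_intensity_mean = 10,
                           train_intensity_cv = 0.2,
                           trace_width_px = 1.5, noise_sd = 1,
                           background_au = 5,
                           duration_s = 17, flagellum_length_um = 10,
                           pixel_size_um = 0.1, frame_interval_s = 0.05,
                           departures = c("poisson", "uniform"),
                           seed = NULL) {
  departures <- match.arg(departures)
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n_trains >= 0, speed_um_s > 0, train_intensity_mean > 0,
            train_intensity_cv >= 0, trace_width_px > 0, noise_sd >= 0,
            background_au >= 0, duration_s > 0, flagellum_length_um > 0,
            pixel_size_um > 0, frame_interval_s > 0)
  nr <- round(flagellum_length_um / pixel_size_um)
  if (nr < 2) {
    stop("flagellum shorter than 2 pixels at this calibration", call. = FALSE)
  }
  nc <- round(duration_s / frame_interval_s)
  transit_s <- flagellum_length_um / speed_um_s
  window_s <- duration_s - transit_s
  if (n_trains > 0 && window_s <= 0) {
    stop(sprintf(
      "duration (%g s) must exceed the tip transit time (%g s) so trains fit in the movie",
      duration_s, transit_s), call. = FALSE)
  }

  t0 <- if (n_trains == 0) numeric(0) else switch(departures,
    uniform = if (n_trains == 1) window_s / 2 else
      seq(0, window_s, length.out = n_trains),
    poisson = sort(stats::runif(n_trains, 0, window_s))
  )
  amps <- train_intensity_mean *
    pmax(0.05, 1 + train_intensity_cv * stats::rnorm(n_trains))

  x_px <- seq_len(nr)                      # base at row 1
  t_s <- (seq_len(nc) - 1) * frame_interval_s
  sigma_px <- trace_width_px
  img <- matrix(0, nr, nc)
  mags <- numeric(n_trains)
  for (i in seq_len(n_trains)) {
    centre_px <- 1 + speed_um_s * (t_s - t0[i]) / pixel_size_um
    active <- which(t_s >= t0[i] & centre_px <= nr + 3 * sigma_px)
    if (!length(active)) next
    contrib <- amps[i] * exp(-outer(x_px, centre_px[active], "-")^2 /
                               (2 * sigma_px^2))
    mags[i] <- sum(contrib)
    img[, active] <- img[, active] + contrib
  }
  img <- img + background_au
  if (noise_sd > 0) {
    img <- img + stats::rnorm(length(img), 0, noise_sd)
  }
  img <- pmax(img, 0)
  freq <- if (n_trains >= 2 && diff(range(t0)) > 0) {
    (n_trains - 1) / diff(range(t0))
  } else {
    NA_real_
  }
  list(
    kymograph = kymograph(img, pixel_size_um, frame_interval_s),
    truth = list(departures_s = t0, amplitudes_au = amps,
                 magnitudes_au = mags, speed_um_s = speed_um_s,
                 frequency_per_s = freq, n_trains = n_trains, seed = seed)
  )
}

#' Default strain specification for synthetic injection-scaling data
#'
#' Mirrors the measured strain statistics: wild-type flagella 9.9 +/- 2.9
#' um with injection on the 1/L trend; lf1 (17.9 +/- 2.5 um, injection fold
#' 1.7), lf2-1 (16.7 +/- 4.3 um, fold 1.5) and lf4 (19.9 +/- 8.4 um, fold
#' 1.7). Log10 scatter SDs are the per-strain SDs of the deviations from
#' the 1/L trend line (0.16, 0.14, 0.11, 0.17).
#'
#' @param n_per_strain Flagella per strain (default 30).
#' @return Data frame with columns `strain`, `n`, `length_mean_um`,
#'   `length_sd_um`, `fold`, `scatter_sd_log10`.
#' @export
default_scaling_spec <- function(n_per_strain = 30) {
  data.frame(
    strain = c("wt", "lf1", "lf2-1", "lf4"),
    n = n_per_strain,
    length_mean_um = c(9.9, 17.9, 16.7, 19.9),
    length_sd_um = c(2.9, 2.5, 4.3, 8.4),
    fold = c(1, 1.7, 1.5, 1.7),
    scatter_sd_log10 = c(0.16, 0.14, 0.11, 0.17)
  )
}

#' Generate a synthetic injection-scaling dataset
#'
#' Per-flagellum lengths are drawn from truncated normals per strain, and
#' injection rates follow the 1/L law with a strain-specific fold and
#' lognormal scatter: `rate = fold * c / L * 10^e`, e ~ N(0, scatter SD).
#'
#' @param spec Data frame as from [default_scaling_spec()].
#' @param trend_constant Wild-type trend constant c, a.u. um / s (default
#'   50, giving ~5 a.u./s at 10 um).
#' @param min_length_um Lower truncation for drawn lengths (default 1).
#' @param seed Optional integer seed.
#' @return List with `data` (data frame `strain`, `length_um`,
#'   `injection_rate_au_s`) and `truth` (planted folds, trend constant,
#'   spec, seed).
#' @export
make_scaling_dataset <- function(spec = default_scaling_spec(),
                                 trend_constant = 50, min_length_um = 1,
                                 seed = NULL) {
  stopifnot(is.data.frame(spec),
            all(c("strain", "n", "length_mean_um", "length_sd_um", "fold",
                  "scatter_sd_log10") %in% names(spec)))
  if (any(spec$fold <= 0)) stop("folds must be > 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(seq_len(nrow(spec)), function(i) {
    s <- spec[i, ]
    L <- stats::rnorm(s$n, s$length_mean_um, s$length_sd_um)
    while (any(L <= min_length_um)) {
      bad <- L <= min_length_um
      L[bad] <- stats::rnorm(sum(bad), s$length_mean_um, s$length_sd_um)
    }
    eps <- stats::rnorm(s$n, 0, s$scatter_sd_log10)
    data.frame(
      strain = s$strain,
      length_um = L,
      injection_rate_au_s = s$fold * trend_constant / L * 10^eps
    )
  })
  list(
    data = do.call(rbind, rows),
    truth = list(folds = stats::setNames(spec$fold, spec$strain),
                 trend_constant = trend_constant, spec = spec, seed = seed)
  )
}

#' Generate a synthetic cargo-occupancy dataset
#'
#' For each flagellar length, the train size is the (integer-rounded,
#' clamped at `min_n`) prediction of the train-size model; each of
#' `trains_per_length` trains is then scored cargo-positive with
#' probability `1 - (1 - p_bound)^N`, and the occupied fraction recorded.
#'
#' @param p_bound Per-particle binding probability in \[0, 1\].
#' @param lengths Flagellar lengths, um. Default: 20 log-spaced lengths
#'   from 2 to 28 um, spanning train sizes ~13 down to ~2.
#' @param trains_per_length Trains scored per length (default 50).
#' @param model A [train_size_model()].
#' @param min_n Minimum integer train size after rounding (default 1).
#' @param seed Optional integer seed.
#' @return List with `data` (data frame `length_um`, `fraction_occupied`,
#'   `n_trains`) and `truth` (`p_bound`, integer train sizes, seed).
#' @export
make_occupancy_dataset <- function(p_bound,
                                   lengths = 10^seq(log10(2), log10(28),
                                                    length.out = 20),
                                   trains_per_length = 50,
                                   model = train_size_model(),
                                   min_n = 1, seed = NULL) {
  .check_scalar(p_bound, "p_bound", lower = 0, upper = 1)
  stopifnot(trains_per_length >= 1, min_n >= 1)
  if (!is.null(seed)) set.seed(seed)
  N_int <- pmax(min_n, round(train_size_from_length(lengths, model)))
  occ_p <- occupancy_probability(p_bound, N_int)
  k <- stats::rbinom(length(lengths), trains_per_length, occ_p)
  list(
    data = data.frame(length_um = lengths,
                      fraction_occupied = k / trains_per_length,
                      n_trains = trains_per_length),
    truth = list(p_bound = p_bound, train_sizes = N_int, seed = seed)
  )
}
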