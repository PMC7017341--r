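#' Read balance-point model parameters from a file
#'
#' YAML or JSON with numeric keys `A` (um/min), `P` (um length-equivalents)
#' and `D` (um/min).
#'
#' @param path File path; format chosen by extension (`.yaml`/`.yml` or
#'   `.json`).
#' @return A [model_params()] object.
#' @export
read_model_params <- function(path) {
  ext <- tolower(tools::file_ext(path))
  vals <- switch(ext,
    yaml = ,
    yml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    stop("unsupported parameter-file extension: ", ext, call. = FALSE)
  )
  for (k in c("A", "P", "D")) {
    if (is.null(vals[[k]])) {
      stop(sprintf("parameter file is missing key '%s'", k), call. = FALSE)
    }
  }
  model_params(A = as.numeric(vals$A), P = as.numeric(vals$P),
               D = as.numeric(vals$D))
}

#' Write a length trajectory as CSV
#'
#' Columns `time_min,length_um`, no row names.
#'
#' @param trajectory A `length_trajectory` (from [simulate_regeneration()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(trajectory, path) {
  stopifnot(is.data.frame(trajectory),
            all(c("time_min", "length_um") %in% names(trajectory)))
  utils::write.csv(trajectory[, c("time_min", "length_um")], path,
                   row.names = FALSE)
  invisible(path)
}

#' Read per-flagellum injection measurements
#'
#' CSV with columns `strain,length_um,injection_rate_au_s`.
#'
#' @param path CSV path.
#' @return Validated data frame.
#' @export
read_injection_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("strain", "length_um", "injection_rate_au_s")
  if (!all(need %in% names(d))) {
    stop("expected columns ", paste(need, collapse = ", "), " in ", path,
         call. = FALSE)
  }
  .check_scaling_data(d)
  d
}

#' Read cargo-occupancy observations
#'
#' CSV with columns `length_um,fraction_occupied` and optionally
#' `n_trains`.
#'
#' @param path CSV path.
#' @return Validated data frame.
#' @export
read_occupancy_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("length_um", "fraction_occupied") %in% names(d))) {
    stop("expected columns length_um, fraction_occupied in ", path,
         call. = FALSE)
  }
  if (any(d$fraction_occupied < 0 | d$fraction_occupied > 1)) {
    stop("fraction_occupied outside [0, 1] in ", path, call. = FALSE)
  }
  d
}

#' Printed per-strain statistics shipped with the package
#'
#' Mean flagellar lengths and mean log10 deviations from the wild-type
#' trend lines for wild type and the three long-flagella mutants, as used
#' by the strain-comparison tables.
#'
#' @return Data frame (see [summaries_from_printed()] for the columns).
#' @export
printed_strain_stats <- function() {
  utils::read.csv(
    system.file("extdata", "printed_strain_stats.csv",
                package = "flagbalance"),
    stringsAsFactors = FALSE, check.names = TRUE
  )
}

#' Pipeline configuration
#'
#' Bundles the calibration and model constants shared across pipeline
#' stages, with validation.
#'
#' @param pixel_size_um um per pixel (default 0.1).
#' @param frame_interval_s s per frame (default 0.05).
#' @param d_over_a Wild-type D/A for length predictions (default 8).
#' @param n_intercept,n_slope_per_log10um Train-size model coefficients
#'   (defaults 16 and -9.96).
#' @param min_prominence_frac,min_separation_px Peak-detection thresholds
#'   (defaults 0.2 and 3).
#' @param angle_min_deg Smallest projection angle searched, degrees
#'   (default 15; smaller angles mean faster traces).
#' @param frequency_denominator `"peak_span"` or `"duration"`, see
#'   [analyze_kymograph()].
#' @param seed Optional integer seed recorded in outputs.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(pixel_size_um = 0.1, frame_interval_s = 0.05,
                            d_over_a = 8, n_intercept = 16,
                            n_slope_per_log10um = -9.96,
                            min_prominence_frac = 0.2, min_separation_px = 3,
                            angle_min_deg = 15,
                            frequency_denominator = "peak_span",
                            seed = NULL) {
  .check_scalar(pixel_size_um, "pixel_size_um", lower = 0, strict_lower = TRUE)
  .check_scalar(frame_interval_s, "frame_interval_s", lower = 0,
                strict_lower = TRUE)
  .check_scalar(d_over_a, "d_over_a", lower = 0)
  .check_scalar(n_intercept, "n_intercept")
  .check_scalar(n_slope_per_log10um, "n_slope_per_log10um")
  .check_scalar(min_prominence_frac, "min_prominence_frac", lower = 0, upper = 1)
  .check_scalar(min_separation_px, "min_separation_px", lower = 1)
  .check_scalar(angle_min_deg, "angle_min_deg", lower = 0, upper = 90,
                strict_lower = TRUE)
  stopifnot(frequency_denominator %in% c("peak_span", "duration"))
  structure(list(
    pixel_size_um = pixel_size_um, frame_interval_s = frame_interval_s,
    d_over_a = d_over_a,
    train_size = train_size_model(n_intercept, n_slope_per_log10um),
    min_prominence_frac = min_prominence_frac,
    min_separation_px = min_separation_px,
    angle_min_deg = angle_min_deg,
    frequency_denominator = frequency_denominator,
    seed = seed
  ), class = "pipeline_config")
}

#' Run the end-to-end analysis pipeline
#'
#' Ties the stages together: kymographs (if given) are quantified into
#' per-flagellum injection measurements; measurements are summarised per
#' strain against the wild-type trend lines and mapped to predicted length
#' fold changes through the balance-point model; occupancy observations
#' (if given) are fitted with the binomial null model. Deterministic given
#' inputs and config.
#'
#' @param measurements Data frame (`strain`, `length_um`,
#'   `injection_rate_au_s`) or path to such a CSV. Ignored when
#'   `kymographs` is supplied.
#' @param kymographs Optional named list; each element a list with fields
#'   `kymograph` (a [kymograph()]), `strain`, and `length_um`.
#' @param occupancy Optional data frame (`length_um`, `fraction_occupied`)
#'   or CSV path.
#' @param config A [pipeline_config()].
#' @param wt_label Wild-type strain label (default `"wt"`).
#' @param out_dir Optional output directory; written files:
#'   `measurements.csv`, `strain_summaries.csv`, `table_injection.csv`,
#'   `table_predictions.csv`, and `occupancy_estimate.json` +
#'   `occupancy_curve.csv` when occupancy data are given.
#' @return List with `measurements`, `summaries`, `table_injection`,
#'   `table_predictions`, and (if occupancy data were given)
#'   `binding_estimate` and `occupancy_curve`.
#' @export
run_pipeline <- function(measurements = NULL, kymographs = NULL,
                         occupancy = NULL, config = pipeline_config(),
                         wt_label = "wt", out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(kymographs)) {
    rows <- lapply(kymographs, function(k) {
      res <- analyze_kymograph(
        k$kymograph,
        min_prominence_frac = config$min_prominence_frac,
        min_separation = config$min_separation_px,
        angle_grid = seq(config$angle_min_deg, 90, by = 0.25),
        frequency_denominator = config$frequency_denominator
      )
      data.frame(strain = k$strain, length_um = k$length_um,
                 injection_rate_au_s = res$injection_rate_au_s,
                 speed_um_s = res$speed_um_s,
                 frequency_per_s = res$frequency_per_s,
                 mean_magnitude_au = res$mean_magnitude_au,
                 n_trains = res$n_trains)
    })
    measurements <- do.call(rbind, rows)
    if (any(!is.finite(measurements$injection_rate_au_s))) {
      stop("some kymographs yielded undefined injection rates ",
           "(fewer than two trains); cannot build strain summaries",
           call. = FALSE)
    }
  } else if (is.character(measurements)) {
    measurements <- read_injection_csv(measurements)
  }
  if (is.null(measurements) || nrow(measurements) == 0) {
    stop("no injection measurements supplied", call. = FALSE)
  }

  summaries <- build_strain_summaries(measurements, wt_label = wt_label,
                                      d_over_a = config$d_over_a)
  out <- list(
    measurements = measurements,
    summaries = summaries,
    table_injection = format_injection_table(summaries),
    table_predictions = format_prediction_table(summaries)
  )

  if (!is.null(occupancy)) {
    if (is.character(occupancy)) occupancy <- read_occupancy_csv(occupancy)
    est <- estimate_p_bound(occupancy, model = config$train_size)
    lr <- range(occupancy$length_um)
    curve <- predict_occupancy_curve(
      est$p_bound, seq(lr[1], lr[2], length.out = 100), config$train_size)
    out$binding_estimate <- est
    out$occupancy_curve <- curve
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(out$measurements, file.path(out_dir, "measurements.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(out$summaries),
                     file.path(out_dir, "strain_summaries.csv"),
                     row.names = FALSE)
    utils::write.csv(out$table_injection,
                     file.path(out_dir, "table_injection.csv"),
                     row.names = FALSE)
    utils::write.csv(out$table_predictions,
                     file.path(out_dir, "table_predictions.csv"),
                     row.names = FALSE)
    if (!is.null(out$binding_estimate)) {
      est <- out$binding_estimate
      jsonlite::write_json(
        list(p_bound = est$p_bound,
             slope_log10_p_empty = est$slope_log10_p_empty,
             zero_intercept = est$zero_intercept,
             n_used = est$n_used, n_excluded_full = est$n_excluded_full,
             r_squared = est$r_squared),
        file.path(out_dir, "occupancy_estimate.json"),
        auto_unbox = TRUE, digits = NA
      )
      utils::write.csv(
        out$occupancy_curve[, c("length_um", "predicted_occupancy")],
        file.path(out_dir, "occupancy_curve.csv"), row.names = FALSE)
    }
  }
  out
}
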