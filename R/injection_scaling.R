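#' Fit a power law to injection rate vs length
#'
#' Ordinary least squares on log10-transformed axes: log10(rate) =
#' intercept + slope * log10(length). IFT injection rate in wild-type cells
#' scales approximately as 1/L, i.e. slope -1 on these axes; `fix_slope =
#' -1` constrains the slope and fits only the intercept (the mean of
#' log10(rate) - slope * log10(length)).
#'
#' @param data Data frame with columns `length_um` and
#'   `injection_rate_au_s`, one row per flagellum; both strictly positive.
#' @param fix_slope Optional fixed slope (e.g. -1). `NULL` (default) fits
#'   the slope freely.
#' @return Object of class `power_law_fit`: list with `slope`, `intercept`
#'   (log10 a.u./s at L = 1 um), `constrained`, `n`.
#' @export
#' @examples
#' d <- data.frame(length_um = c(5, 10, 20),
#'                 injection_rate_au_s = 100 / c(5, 10, 20))
#' fit_power_law(d)  # slope -1, intercept 2
fit_power_law <- function(data, fix_slope = NULL) {
  .check_scaling_data(data)
  min_n <- if (is.null(fix_slope)) 2L else 1L
  if (nrow(data) < min_n) {
    stop(sprintf("need at least %d observations for this fit", min_n),
         call. = FALSE)
  }
  x <- log10(data$length_um)
  y <- log10(data$injection_rate_au_s)
  if (is.null(fix_slope)) {
    fit <- stats::lm(y ~ x)
    slope <- unname(stats::coef(fit)[2])
    intercept <- unname(stats::coef(fit)[1])
    constrained <- FALSE
  } else {
    .check_scalar(fix_slope, "fix_slope")
    slope <- fix_slope
    intercept <- mean(y - slope * x)
    constrained <- TRUE
  }
  structure(list(slope = slope, intercept = intercept,
                 constrained = constrained, n = nrow(data)),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf(
    "Power-law fit (n = %d%s): log10(rate) = %.4g %+.4g * log10(L)\n",
    x$n, if (x$constrained) ", slope constrained" else "",
    x$intercept, x$slope
  ))
  invisible(x)
}

#' Predicted injection rate from a power-law fit
#'
#' @param object A `power_law_fit`.
#' @param newdata Data frame with a `length_um` column, or a numeric vector
#'   of lengths (um).
#' @param ... Unused.
#' @return Predicted injection rates, a.u./s.
#' @export
predict.power_law_fit <- function(object, newdata, ...) {
  L <- if (is.data.frame(newdata)) newdata$length_um else newdata
  10^(object$intercept + object$slope * log10(L))
}

#' Mean log deviation from a trend line
#'
#' Average (over flagella) of log10(rate) minus the trend-line prediction
#' at that flagellum's length. On log-log axes this is the log of the fold
#' change in injection rate relative to the reference strain the line was
#' fitted to.
#'
#' @inheritParams fit_power_law
#' @param fit A `power_law_fit`, typically fitted to wild-type data.
#' @return List with `mean` (log10 units), `sd` and `n`.
#' @export
mean_log_deviation <- function(data, fit) {
  .check_scaling_data(data)
  stopifnot(inherits(fit, "power_law_fit"))
  dev <- log10(data$injection_rate_au_s) -
    (fit$intercept + fit$slope * log10(data$length_um))
  list(mean = mean(dev), sd = stats::sd(dev), n = length(dev))
}

#' Fold change from a log10 deviation
#'
#' Converts a mean log10 deviation from a trend line into a fold change in
#' injection rate: `10^deviation`.
#'
#' @param deviation Log10 deviation(s); finite.
#' @return Fold change(s), dimensionless.
#' @export
#' @examples
#' fold_from_deviation(0.24)  # ~1.74, rounds to 1.7
fold_from_deviation <- function(deviation) {
  if (!is.numeric(deviation) || any(!is.finite(deviation))) {
    stop("`deviation` must be finite", call. = FALSE)
  }
  10^deviation
}

#' Per-strain injection and length summaries
#'
#' Reproduces the strain-comparison analysis: the wild-type
#' injection-vs-length trend is fitted twice (free slope and slope
#' constrained to -1); every strain's flagella are then scored by their
#' mean log10 deviation from each wild-type line, deviations are converted
#' to injection fold changes (10^deviation, used unrounded downstream), and
#' each injection fold change is mapped to a predicted length fold change
#' through the balance-point model ([predict_mutant_length_ratio()]).
#'
#' @param data Data frame with columns `strain`, `length_um`,
#'   `injection_rate_au_s` (one row per flagellum).
#' @param wt_label Strain label identifying wild type (default `"wt"`).
#' @param d_over_a Wild-type D/A ratio fed to the length prediction
#'   (default 8, the high end of the 6--8 wild-type estimate).
#' @return Data frame of class `strain_summary`, one row per strain (wild
#'   type first): mean and SD of length, length fold change vs wild type,
#'   mean and SD of the log deviation from each wild-type fit, the
#'   corresponding injection fold changes, and the predicted length fold
#'   changes. Wild-type rows carry NA for the fold-change columns.
#' @export
build_strain_summaries <- function(data, wt_label = "wt", d_over_a = 8) {
  if (!is.data.frame(data) || !all(c("strain", "length_um",
                                     "injection_rate_au_s") %in% names(data))) {
    stop("`data` needs columns strain, length_um, injection_rate_au_s",
         call. = FALSE)
  }
  .check_scaling_data(data)
  .check_scalar(d_over_a, "d_over_a", lower = 0)
  if (!wt_label %in% data$strain) {
    stop(sprintf("wild-type strain '%s' not present in the data", wt_label),
         call. = FALSE)
  }
  wt <- data[data$strain == wt_label, ]
  fit_free <- fit_power_law(wt)
  fit_m1 <- fit_power_law(wt, fix_slope = -1)
  wt_mean_length <- mean(wt$length_um)

  strains <- c(wt_label, setdiff(unique(data$strain), wt_label))
  rows <- lapply(strains, function(s) {
    d <- data[data$strain == s, ]
    dev_free <- mean_log_deviation(d, fit_free)
    dev_m1 <- mean_log_deviation(d, fit_m1)
    is_wt <- identical(s, wt_label)
    fold_free <- fold_from_deviation(dev_free$mean)
    fold_m1 <- fold_from_deviation(dev_m1$mean)
    data.frame(
      strain = s,
      n = nrow(d),
      length_um_mean = mean(d$length_um),
      length_um_sd = stats::sd(d$length_um),
      fold_change_length = if (is_wt) NA_real_ else mean(d$length_um) / wt_mean_length,
      dev_bestfit_mean = dev_free$mean,
      dev_bestfit_sd = dev_free$sd,
      fold_injection_bestfit = if (is_wt) NA_real_ else fold_free,
      dev_slope1_mean = dev_m1$mean,
      dev_slope1_sd = dev_m1$sd,
      fold_injection_slope1 = if (is_wt) NA_real_ else fold_m1,
      predicted_fold_length_bestfit = if (is_wt) NA_real_ else
        predict_mutant_length_ratio(d_over_a, fold_free),
      predicted_fold_length_slope1 = if (is_wt) NA_real_ else
        predict_mutant_length_ratio(d_over_a, fold_m1)
    )
  })
  out <- do.call(rbind, rows)
  attr(out, "wt_fit_free") <- fit_free
  attr(out, "wt_fit_slope1") <- fit_m1
  attr(out, "d_over_a") <- d_over_a
  class(out) <- c("strain_summary", "data.frame")
  out
}

#' Strain summaries from printed per-strain statistics
#'
#' Builds the same summary as [build_strain_summaries()] but starting from
#' already-aggregated per-strain statistics (mean lengths and mean log
#' deviations from the wild-type trend lines) instead of per-flagellum
#' measurements. Fold changes are computed from the unrounded 10^deviation
#' and lengths; rounding is applied only by the formatting helpers.
#'
#' @param printed Data frame with columns `strain`, `length_um_mean`,
#'   `length_um_sd`, `dev_bestfit_mean`, `dev_bestfit_sd`,
#'   `dev_slope1_mean`, `dev_slope1_sd` (see
#'   `system.file("extdata", "printed_strain_stats.csv", package =
#'   "flagbalance")`).
#' @inheritParams build_strain_summaries
#' @return A `strain_summary` data frame (see [build_strain_summaries()]).
#' @export
summaries_from_printed <- function(printed, wt_label = "wt", d_over_a = 8) {
  need <- c("strain", "length_um_mean", "length_um_sd", "dev_bestfit_mean",
            "dev_bestfit_sd", "dev_slope1_mean", "dev_slope1_sd")
  if (!is.data.frame(printed) || !all(need %in% names(printed))) {
    stop("`printed` needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (!wt_label %in% printed$strain) {
    stop(sprintf("wild-type strain '%s' not present", wt_label), call. = FALSE)
  }
  .check_scalar(d_over_a, "d_over_a", lower = 0)
  wt_len <- printed$length_um_mean[printed$strain == wt_label][1]
  ord <- c(which(printed$strain == wt_label),
           which(printed$strain != wt_label))
  printed <- printed[ord, ]
  is_wt <- printed$strain == wt_label
  fold_free <- fold_from_deviation(printed$dev_bestfit_mean)
  fold_m1 <- fold_from_deviation(printed$dev_slope1_mean)
  out <- data.frame(
    strain = printed$strain,
    n = NA_integer_,
    length_um_mean = printed$length_um_mean,
    length_um_sd = printed$length_um_sd,
    fold_change_length = ifelse(is_wt, NA_real_,
                                printed$length_um_mean / wt_len),
    dev_bestfit_mean = printed$dev_bestfit_mean,
    dev_bestfit_sd = printed$dev_bestfit_sd,
    fold_injection_bestfit = ifelse(is_wt, NA_real_, fold_free),
    dev_slope1_mean = printed$dev_slope1_mean,
    dev_slope1_sd = printed$dev_slope1_sd,
    fold_injection_slope1 = ifelse(is_wt, NA_real_, fold_m1),
    predicted_fold_length_bestfit = ifelse(
      is_wt, NA_real_, predict_mutant_length_ratio(d_over_a, fold_free)),
    predicted_fold_length_slope1 = ifelse(
      is_wt, NA_real_, predict_mutant_length_ratio(d_over_a, fold_m1))
  )
  attr(out, "d_over_a") <- d_over_a
  class(out) <- c("strain_summary", "data.frame")
  out
}

#' Format strain summaries as the injection-change table
#'
#' One-decimal presentation (half away from zero) of lengths, length fold
#' changes and injection fold changes; deviations keep two decimals.
#'
#' @param summaries A `strain_summary` data frame.
#' @return Data frame with character `length` ("mean +/- sd") and rounded
#'   numeric columns.
#' @export
format_injection_table <- function(summaries) {
  stopifnot(inherits(summaries, "strain_summary"))
  data.frame(
    strain = summaries$strain,
    length = sprintf("%.1f ± %.1f",
                     round_half_away(summaries$length_um_mean, 1),
                     round_half_away(summaries$length_um_sd, 1)),
    fold_change_length = round_half_away(summaries$fold_change_length, 1),
    dev_bestfit = sprintf("%.2f ± %.2f",
                          round_half_away(summaries$dev_bestfit_mean, 2),
                          round_half_away(summaries$dev_bestfit_sd, 2)),
    fold_injection_bestfit = round_half_away(summaries$fold_injection_bestfit, 1),
    dev_slope1 = sprintf("%.2f ± %.2f",
                         round_half_away(summaries$dev_slope1_mean, 2),
                         round_half_away(summaries$dev_slope1_sd, 2)),
    fold_injection_slope1 = round_half_away(summaries$fold_injection_slope1, 1)
  )
}

#' Format strain summaries as the length-prediction table
#'
#' Observed versus balance-point-predicted length fold changes, one decimal
#' (half away from zero). Wild type is omitted (it is the reference).
#'
#' @inheritParams format_injection_table
#' @return Data frame with one row per mutant strain.
#' @export
format_prediction_table <- function(summaries) {
  stopifnot(inherits(summaries, "strain_summary"))
  mut <- summaries[!is.na(summaries$fold_change_length), ]
  data.frame(
    strain = mut$strain,
    length = sprintf("%.1f ± %.1f",
                     round_half_away(mut$length_um_mean, 1),
                     round_half_away(mut$length_um_sd, 1)),
    fold_change_length = round_half_away(mut$fold_change_length, 1),
    predicted_fold_length_bestfit =
      round_half_away(mut$predicted_fold_length_bestfit, 1),
    predicted_fold_length_slope1 =
      round_half_away(mut$predicted_fold_length_slope1, 1)
  )
}

# Internal: validate positive length/rate columns, listing offending rows
.check_scaling_data <- function(data) {
  if (!is.data.frame(data) ||
      !all(c("length_um", "injection_rate_au_s") %in% names(data))) {
    stop("`data` needs columns length_um and injection_rate_au_s",
         call. = FALSE)
  }
  bad <- which(!is.finite(data$length_um) | data$length_um <= 0 |
               !is.finite(data$injection_rate_au_s) |
               data$injection_rate_au_s <= 0)
  if (length(bad)) {
    stop("non-positive or non-finite length/injection values in rows: ",
         paste(utils::head(bad, 10), collapse = ", "),
         if (length(bad) > 10) " ..." else "", call. = FALSE)
  }
  invisible(data)
}
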