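#' Probability that an IFT train appears empty
#'
#' Binomial null model for cargo occupancy: an IFT train of N particles,
#' each independently carrying cargo (tubulin) with probability `p_bound`,
#' shows no cargo signal with probability
#'
#' \deqn{P_{empty} = (1 - P_{bound})^N.}
#'
#' Occupancy (the fraction of trains with a cargo signal) is
#' `1 - p_empty()`. N may be real-valued: the train-size-vs-length fit
#' predicts non-integer mean train sizes.
#'
#' @param p_bound Per-particle cargo binding probability, in \[0, 1\].
#' @param N Particles per train, >= 0 (real-valued allowed). Vectorised.
#' @return Probability that the train shows no cargo signal.
#' @export
#' @examples
#' 1 - p_empty(0.5, c(1, 2, 4))  # occupancy 0.5, 0.75, 15/16
p_empty <- function(p_bound, N) {
  .check_scalar(p_bound, "p_bound", lower = 0, upper = 1)
  if (!is.numeric(N) || any(!is.finite(N)) || any(N < 0)) {
    stop("`N` must be finite and >= 0", call. = FALSE)
  }
  (1 - p_bound)^N
}

#' Train occupancy under the binomial null model
#'
#' Convenience wrapper: `1 - p_empty(p_bound, N)`.
#'
#' @inheritParams p_empty
#' @return Probability that the train shows a cargo signal.
#' @export
occupancy_probability <- function(p_bound, N) {
  1 - p_empty(p_bound, N)
}

#' Train-size-vs-length model
#'
#' IFT trains contain fewer particles in longer flagella. The mean train
#' size is modelled as linear in the log of flagellar length,
#' `N = intercept + slope * log10(L)`; the default coefficients are the
#' best-fit line N = 16 - 9.96 log10(L) from quantitative TIRF /
#' photobleaching measurements of train size. With the defaults N stays
#' positive for lengths below ~40.5 um; the model errors outside the range
#' where it predicts N > 0.
#'
#' @param intercept Particles per train at L = 1 um (default 16).
#' @param slope Particles per log10(um) (default -9.96).
#' @return Object of class `train_size_model`.
#' @export
train_size_model <- function(intercept = 16, slope = -9.96) {
  .check_scalar(intercept, "intercept")
  .check_scalar(slope, "slope")
  structure(list(intercept = intercept, slope = slope),
            class = "train_size_model")
}

#' @export
print.train_size_model <- function(x, ...) {
  cat(sprintf("Train-size model: N = %g %+g * log10(L um)\n",
              x$intercept, x$slope))
  if (x$slope < 0) {
    cat(sprintf("  valid for L < %.3g um (N > 0)\n",
                10^(-x$intercept / x$slope)))
  }
  invisible(x)
}

#' Predicted particles per train at a given flagellar length
#'
#' @param L Flagellar length, um (> 0). Vectorised.
#' @param model A [train_size_model()].
#' @return Mean particles per train (real-valued).
#' @export
#' @examples
#' train_size_from_length(c(1, 10))  # 16, 6.04
train_size_from_length <- function(L, model = train_size_model()) {
  stopifnot(inherits(model, "train_size_model"))
  if (!is.numeric(L) || any(!is.finite(L)) || any(L <= 0)) {
    stop("`L` must be positive and finite", call. = FALSE)
  }
  N <- model$intercept + model$slope * log10(L)
  if (any(N <= 0)) {
    lim <- if (model$slope < 0) {
      sprintf("valid lengths: 0 < L < %.4g um", 10^(-model$intercept / model$slope))
    } else {
      sprintf("valid lengths: L > %.4g um", 10^(-model$intercept / model$slope))
    }
    stop("train-size model predicts N <= 0 at some requested lengths; ", lim,
         call. = FALSE)
  }
  N
}

#' Flagellar length at which a train size is predicted
#'
#' Inverse of [train_size_from_length()]: `L = 10^((N - intercept)/slope)`.
#'
#' @param N Particles per train (> 0). Vectorised.
#' @param model A [train_size_model()].
#' @return Length, um.
#' @export
length_from_train_size <- function(N, model = train_size_model()) {
  stopifnot(inherits(model, "train_size_model"))
  if (!is.numeric(N) || any(!is.finite(N)) || any(N <= 0)) {
    stop("`N` must be positive and finite", call. = FALSE)
  }
  if (model$slope == 0) stop("slope 0: length is not identified", call. = FALSE)
  10^((N - model$intercept) / model$slope)
}

#' Predicted occupancy as a function of flagellar length
#'
#' Composition of the train-size map and the binomial null model: the
#' expected fraction of trains showing a cargo signal if per-particle
#' binding is length-independent. Because trains shrink with length, the
#' predicted occupancy decreases with length even at constant `p_bound` --
#' apparent length dependence of cargo loading can arise purely from train
#' organisation.
#'
#' @inheritParams p_empty
#' @param lengths Flagellar lengths, um; must lie in the model's valid
#'   range (N > 0).
#' @param model A [train_size_model()].
#' @return Data frame with columns `length_um`, `train_size`,
#'   `predicted_occupancy`.
#' @export
predict_occupancy_curve <- function(p_bound, lengths,
                                    model = train_size_model()) {
  N <- train_size_from_length(lengths, model)
  data.frame(
    length_um = lengths,
    train_size = N,
    predicted_occupancy = occupancy_probability(p_bound, N)
  )
}

#' Estimate the per-particle binding probability from occupancy data
#'
#' Under the null model, log10 P_empty = N log10(1 - P_bound) is linear in
#' train size N with zero intercept. Observed occupancy fractions are
#' converted to log10(1 - fraction_occupied), train sizes are predicted
#' from each observation's flagellar length, and the slope is estimated by
#' least squares -- through the origin by default (the null model has no
#' intercept); `zero_intercept = FALSE` adds a free intercept as a
#' diagnostic for deviations from the null model. The binding probability
#' is recovered as `p_bound = 1 - 10^slope`.
#'
#' Observations with `fraction_occupied = 1` have log10 P_empty = -Inf and
#' are excluded with a warning (their count is reported in the result).
#'
#' @param observations Data frame with columns `length_um` and
#'   `fraction_occupied` (in \[0, 1\]); optionally `n_trains`.
#' @param model A [train_size_model()] mapping length to train size.
#' @param zero_intercept Force the regression through the origin (default
#'   TRUE, the null-model form).
#' @return Object of class `binding_estimate`: list with `p_bound`,
#'   `slope_log10_p_empty` (per particle), `intercept_log10` (0 if
#'   constrained), `n_used`, `n_excluded_full`, `r_squared` and
#'   `residuals` (linearity diagnostics).
#' @export
estimate_p_bound <- function(observations, model = train_size_model(),
                             zero_intercept = TRUE) {
  if (!is.data.frame(observations) ||
      !all(c("length_um", "fraction_occupied") %in% names(observations))) {
    stop("`observations` needs columns length_um and fraction_occupied",
         call. = FALSE)
  }
  f <- observations$fraction_occupied
  if (any(!is.finite(f)) || any(f < 0) || any(f > 1)) {
    stop("`fraction_occupied` must lie in [0, 1]", call. = FALSE)
  }
  full <- f >= 1
  n_excluded <- sum(full)
  if (n_excluded > 0) {
    warning(sprintf(
      "%d observation(s) with fraction_occupied = 1 excluded (log P_empty infinite)",
      n_excluded), call. = FALSE)
  }
  obs <- observations[!full, , drop = FALSE]
  if (nrow(obs) < 2) {
    stop("need at least 2 observations with fraction_occupied < 1",
         call. = FALSE)
  }
  N <- train_size_from_length(obs$length_um, model)
  y <- log10(1 - obs$fraction_occupied)
  fit <- if (zero_intercept) stats::lm(y ~ 0 + N) else stats::lm(y ~ N)
  co <- stats::coef(fit)
  slope <- unname(co[["N"]])
  intercept <- if (zero_intercept) 0 else unname(co[[1]])
  if (slope > 0) {
    warning("fitted slope is positive; occupancy increases with train size ",
            "are inconsistent with the null model (p_bound set to 0)",
            call. = FALSE)
  }
  structure(list(
    p_bound = max(0, 1 - 10^slope),
    slope_log10_p_empty = slope,
    intercept_log10 = intercept,
    zero_intercept = zero_intercept,
    n_used = nrow(obs),
    n_excluded_full = n_excluded,
    r_squared = summary(fit)$r.squared,
    residuals = unname(stats::residuals(fit))
  ), class = "binding_estimate")
}

#' @export
print.binding_estimate <- function(x, ...) {
  cat("Binomial cargo-occupancy fit\n")
  cat(sprintf("  p_bound:  %.4g (per-particle binding probability)\n", x$p_bound))
  cat(sprintf("  slope:    %.4g log10 P_empty per particle%s\n",
              x$slope_log10_p_empty,
              if (x$zero_intercept) " (zero intercept)" else ""))
  cat(sprintf("  n used:   %d (%d excluded at occupancy 1)\n",
              x$n_used, x$n_excluded_full))
  cat(sprintf("  R^2:      %.3f\n", x$r_squared))
  invisible(x)
}
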