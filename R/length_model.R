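#' Balance-point model parameters
#'
#' Parameters of the balance-point model of flagellar length dynamics,
#'
#' \deqn{dL/dt = A (P - 2L)/L - D,}
#'
#' in which length-dependent assembly (IFT injection scales as 1/L, and the
#' free precursor pool is the total pool minus the material already in the
#' two flagella of a biflagellate cell) is balanced against length-independent
#' disassembly.
#'
#' @param A Injection coefficient, um/min. Lumped constant combining the
#'   1/L injection scaling, the length increment per delivered cargo, and
#'   cargo binding to IFT particles. Must be > 0.
#' @param P Total precursor (tubulin) pool of the cell, expressed in um of
#'   flagellar length it could build ("length equivalents"). Must be > 0.
#' @param D Length-independent disassembly rate, um/min. Must be >= 0.
#' @return An object of class `model_params`.
#' @export
#' @examples
#' p <- model_params(A = 0.25, P = 120, D = 2)
#' steady_state_length(p)
model_params <- function(A, P, D) {
  .check_scalar(A, "A", lower = 0, strict_lower = TRUE)
  .check_scalar(P, "P", lower = 0, strict_lower = TRUE)
  .check_scalar(D, "D", lower = 0)
  structure(list(A = A, P = P, D = D), class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("Balance-point model parameters\n")
  cat(sprintf("  A (injection coefficient): %g um/min\n", x$A))
  cat(sprintf("  P (precursor pool):        %g um length-equivalents\n", x$P))
  cat(sprintf("  D (disassembly rate):      %g um/min\n", x$D))
  cat(sprintf("  steady-state length L*:    %g um\n", steady_state_length(x)))
  invisible(x)
}

#' Illustrative default model parameters
#'
#' D/A = 8 (the high end of the 6--8 range estimated for wild-type cells)
#' with A and P chosen so that the steady state sits at 12 um and
#' regeneration completes on the hour scale typical of Chlamydomonas.
#' Absolute values of A, P and D are not individually constrained by IFT
#' measurements; these defaults are illustrative, not fitted.
#'
#' @return A `model_params` object with A = 0.25, P = 120, D = 2.
#' @export
default_model_params <- function() {
  model_params(A = 0.25, P = 120, D = 2)
}

#' Rate of flagellar length change
#'
#' Evaluates dL/dt = A (P - 2L)/L - D, the difference between the
#' length-dependent assembly term and the constant disassembly rate.
#'
#' @param L Flagellar length, um. Vectorised; every element must be > 0
#'   (the assembly term is singular at L = 0).
#' @param params A [model_params()] object.
#' @return Rate of length change, um/min (same length as `L`).
#' @export
#' @examples
#' p <- model_params(A = 2, P = 30, D = 8)
#' length_rate(2, p)  # 2 * 26 / 2 - 8 = 18
length_rate <- function(L, params) {
  stopifnot(inherits(params, "model_params"))
  if (!is.numeric(L) || any(!is.finite(L)) || any(L <= 0)) {
    stop("`L` must be positive and finite: the model is singular at L = 0",
         call. = FALSE)
  }
  params$A * (params$P - 2 * L) / L - params$D
}

#' Steady-state flagellar length
#'
#' The unique balance point L* = P / (2 + D/A) at which assembly equals
#' disassembly. The steady state is stable: dL/dt > 0 below L* and
#' dL/dt < 0 between L* and P/2.
#'
#' @inheritParams length_rate
#' @return Steady-state length, um.
#' @export
steady_state_length <- function(params) {
  stopifnot(inherits(params, "model_params"))
  params$P / (2 + params$D / params$A)
}

#' Predicted mutant/wild-type length ratio
#'
#' For a mutation that multiplies the injection coefficient A by `fold_A`
#' while leaving P and D unchanged, the steady-state lengths satisfy
#'
#' \deqn{L_M / L_{wt} = (2 + D/A_{wt}) / (2 + (D/A_{wt})/fold_A).}
#'
#' Because of the constant 2 in numerator and denominator the length fold
#' change is always smaller than the injection fold change (for
#' `fold_A` > 1), approaching it only when D/A >> 2.
#'
#' @param d_over_a_wt Wild-type ratio D/A (dimensionless, >= 0). The
#'   wild-type estimate from flagellar-number variation is 6--8; 8 is used
#'   as the default elsewhere in the package.
#' @param fold_a Fold change in the injection coefficient, A_M / A_wt (> 0).
#'   Vectorised.
#' @return Predicted length ratio L_M / L_wt (same length as `fold_a`).
#' @export
#' @examples
#' predict_mutant_length_ratio(8, 10^0.24)  # ~1.51, rounds to 1.5
predict_mutant_length_ratio <- function(d_over_a_wt, fold_a) {
  .check_scalar(d_over_a_wt, "d_over_a_wt", lower = 0)
  if (!is.numeric(fold_a) || any(!is.finite(fold_a)) || any(fold_a <= 0)) {
    stop("`fold_a` must be positive and finite", call. = FALSE)
  }
  (2 + d_over_a_wt) / (2 + d_over_a_wt / fold_a)
}

#' Simulate flagellar regeneration
#'
#' Integrates the balance-point equation from an initial length `L0`
#' (e.g. a stump after deflagellation) to `t_end`. Uses adaptive-step ODE
#' integration (deSolve, lsoda); `dt` sets the reporting grid only, not the
#' internal step, so trajectories are insensitive to it.
#'
#' @inheritParams length_rate
#' @param L0 Initial length, um; must satisfy 0 < L0 < P/2.
#' @param t_end Final time, min.
#' @param dt Output time step, min (default 0.5).
#' @return A data frame of class `length_trajectory` with columns
#'   `time_min` and `length_um`.
#' @export
#' @examples
#' traj <- simulate_regeneration(default_model_params(), L0 = 1, t_end = 300)
#' tail(traj, 1)  # close to the 12 um steady state
simulate_regeneration <- function(params, L0, t_end, dt = 0.5) {
  stopifnot(inherits(params, "model_params"))
  .check_scalar(L0, "L0", lower = 0, upper = params$P / 2,
                strict_lower = TRUE, strict_upper = TRUE)
  .check_scalar(t_end, "t_end", lower = 0, strict_lower = TRUE)
  .check_scalar(dt, "dt", lower = 0, strict_lower = TRUE)

  times <- seq(0, t_end, by = dt)
  if (times[length(times)] < t_end) times <- c(times, t_end)
  l_min <- 1e-3
  # the RHS clamps internal trial steps at the length floor so the adaptive
  # integrator never evaluates the singular L <= 0 region; trajectories that
  # actually reach the floor are rejected below
  rhs <- function(t, y, parms) {
    L <- max(y[[1]], l_min)
    list(params$A * (params$P - 2 * L) / L - params$D)
  }
  sol <- deSolve::ode(y = c(L = L0), times = times, func = rhs, parms = NULL)
  lengths <- as.numeric(sol[, "L"])
  if (any(!is.finite(lengths)) || any(lengths <= l_min)) {
    stop(sprintf(
      "integration drove the length to <= %g um (first at t = %g min); the model is singular at L = 0",
      l_min, times[which(!is.finite(lengths) | lengths <= l_min)[1]]
    ), call. = FALSE)
  }
  if (any(lengths >= params$P / 2)) {
    stop(sprintf(
      "integration drove the length to >= P/2 = %g um (pool exhausted); check parameters",
      params$P / 2
    ), call. = FALSE)
  }
  out <- data.frame(time_min = as.numeric(sol[, "time"]), length_um = lengths)
  class(out) <- c("length_trajectory", "data.frame")
  out
}

#' Assembly and disassembly rate curves
#'
#' Evaluates the length-dependent assembly rate A (P - 2L)/L and the
#' constant disassembly rate D over a grid of lengths. Their unique
#' crossing is the steady-state length.
#'
#' @inheritParams length_rate
#' @param L_grid Lengths at which to evaluate, um; all > 0.
#' @return Data frame with columns `length_um`, `assembly_um_min`,
#'   `disassembly_um_min`.
#' @export
assembly_disassembly_curves <- function(params, L_grid) {
  stopifnot(inherits(params, "model_params"))
  if (!is.numeric(L_grid) || any(!is.finite(L_grid)) || any(L_grid <= 0)) {
    stop("`L_grid` must be positive and finite", call. = FALSE)
  }
  data.frame(
    length_um = L_grid,
    assembly_um_min = params$A * (params$P - 2 * L_grid) / L_grid,
    disassembly_um_min = rep(params$D, length(L_grid))
  )
}
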