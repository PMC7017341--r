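test_that("length rate follows the assembly-minus-disassembly form", {
  # direct arithmetic oracle: A*(P - 2L)/L - D = 2*26/2 - 8
  expect_equal(length_rate(2, model_params(A = 2, P = 30, D = 8)), 18)
  # pool exhausted at L = P/2 with no disassembly: rate zero
  expect_equal(length_rate(5, model_params(A = 1, P = 10, D = 0)), 0)
  # zero by definition at the steady state
  p <- model_params(A = 0.7, P = 55, D = 3.1)
  expect_equal(length_rate(steady_state_length(p), p), 0, tolerance = 1e-12)

  expect_error(length_rate(0, p), "singular")
  expect_error(length_rate(-1, p), "singular")
  expect_error(model_params(A = 0, P = 10, D = 1), "A")
  expect_error(model_params(A = 1, P = 10, D = -1), "D")
})

test_that("steady-state length equals P / (2 + D/A)", {
  expect_equal(steady_state_length(model_params(A = 1, P = 10, D = 8)), 1)
  expect_equal(steady_state_length(model_params(A = 1, P = 80, D = 6)), 10)
  # zero-disassembly limit: half the pool
  expect_equal(steady_state_length(model_params(A = 3, P = 24, D = 0)), 12)
})

test_that("steady state is unique and stable: rate sign flips at L*", {
  set.seed(11)
  for (i in 1:25) {
    p <- model_params(A = runif(1, 0.1, 5), P = runif(1, 20, 200),
                      D = runif(1, 0, 20))
    ls <- steady_state_length(p)
    expect_lt(abs(length_rate(ls, p)), 1e-10)
    below <- seq(ls * 0.01, ls * 0.99, length.out = 20)
    above <- seq(ls * 1.01, p$P / 2 * 0.999, length.out = 20)
    expect_true(all(length_rate(below, p) > 0))
    expect_true(all(length_rate(above, p) < 0))
  }
})

test_that("mutant length ratio follows (2 + D/A) / (2 + (D/A)/fold)", {
  # identity when injection is unchanged
  expect_equal(predict_mutant_length_ratio(8, 1), 1)
  expect_equal(predict_mutant_length_ratio(0, 7), 1)
  # printed one-decimal predictions from the unrounded injection folds
  expect_equal(round_half_away(predict_mutant_length_ratio(8, 10^0.24), 1), 1.5)
  expect_equal(round_half_away(predict_mutant_length_ratio(8, 10^0.18), 1), 1.4)
  expect_error(predict_mutant_length_ratio(8, 0), "fold_a")
  expect_error(predict_mutant_length_ratio(-1, 2), "d_over_a_wt")
})

test_that("length fold change is bounded by the injection fold change", {
  set.seed(21)
  for (i in 1:50) {
    x <- runif(1, 0, 50)
    f <- runif(1, 1 + 1e-6, 20)
    expect_lt(predict_mutant_length_ratio(x, f), f)
  }
  # limit: ratio approaches the fold when D/A >> 2
  f <- 1.8
  expect_lt(abs(predict_mutant_length_ratio(1e4, f) - f), 0.01 * f)
})

test_that("regeneration trajectories relax monotonically to the steady state", {
  p <- default_model_params()
  ls <- steady_state_length(p)

  # starting at the steady state: constant
  tr0 <- simulate_regeneration(p, L0 = ls, t_end = 60, dt = 1)
  expect_equal(tr0$length_um, rep(ls, nrow(tr0)), tolerance = 1e-6)

  # regrowth from a stump: monotone increase, limit L*
  tr1 <- simulate_regeneration(p, L0 = 0.1 * ls, t_end = 600, dt = 0.5)
  expect_true(all(diff(tr1$length_um) > -1e-9))
  expect_lt(abs(tail(tr1$length_um, 1) - ls) / ls, 0.01)

  # overlong flagellum shrinks back (sign of dL/dt above L*)
  tr2 <- simulate_regeneration(p, L0 = 1.5 * ls, t_end = 600, dt = 0.5)
  expect_true(all(diff(tr2$length_um) < 1e-9))
  expect_lt(abs(tail(tr2$length_um, 1) - ls) / ls, 0.01)

  # reporting-grid refinement does not move the solution
  tr3 <- simulate_regeneration(p, L0 = 0.1 * ls, t_end = 600, dt = 0.25)
  expect_lt(abs(tail(tr3$length_um, 1) - tail(tr1$length_um, 1)) /
              tail(tr1$length_um, 1), 0.001)

  expect_error(simulate_regeneration(p, L0 = 0, t_end = 10), "L0")
  expect_error(simulate_regeneration(p, L0 = p$P / 2, t_end = 10), "L0")
})

test_that("assembly and disassembly curves cross exactly at the steady state", {
  p <- model_params(A = 0.4, P = 90, D = 3)
  ls <- steady_state_length(p)
  cr <- assembly_disassembly_curves(p, c(seq(1, 40, by = 0.5), ls))
  at_ls <- cr[cr$length_um == ls, ]
  expect_equal(at_ls$assembly_um_min, at_ls$disassembly_um_min)
  # assembly strictly decreasing in L
  ord <- cr[order(cr$length_um), ]
  expect_true(all(diff(ord$assembly_um_min) < 0))
  # doubling A doubles assembly everywhere and moves the crossing right
  p2 <- model_params(A = 2 * p$A, P = p$P, D = p$D)
  cr2 <- assembly_disassembly_curves(p2, cr$length_um)
  expect_equal(cr2$assembly_um_min, 2 * cr$assembly_um_min)
  expect_gt(steady_state_length(p2), ls)
})

test_that("injection and disassembly rates are recoverable from a trajectory", {
  p_true <- model_params(A = 0.25, P = 120, D = 2)
  traj <- simulate_regeneration(p_true, L0 = 2, t_end = 240, dt = 2)
  sse <- function(theta) {
    if (theta[1] <= 0 || theta[2] < 0) return(1e12)
    tryCatch({
      cand <- simulate_regeneration(model_params(theta[1], 120, theta[2]),
                                    L0 = 2, t_end = 240, dt = 2)
      sum((cand$length_um - traj$length_um)^2)
    }, error = function(e) 1e12)
  }
  fit <- stats::optim(c(0.4, 1), sse, control = list(reltol = 1e-12))
  expect_lt(abs(fit$par[1] - 0.25) / 0.25, 0.01)
  expect_lt(abs(fit$par[2] - 2) / 2, 0.01)
})
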