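sec_gov <- canonical_lq(m = 1.5, C = 1, k = 1)  # security/government, c = 1

test_that("constant-control value matches the independent quadrature oracle", {
  # zero effort leaves only the discounted reputation term
  expect_equal(constant_control_value(sec_gov, 0, 1), 1, tolerance = 1e-14)
  # frozen values computed by high-accuracy quadrature of the discounted
  # flow along x(t) = 25 - 24 exp(-0.1 t) (F = 2.5) and its F = 2 analogue
  expect_equal(constant_control_value(sec_gov, 2.5, 1), 4.472222,
               tolerance = 1e-6)
  expect_equal(constant_control_value(sec_gov, 2.0, 1), 4.333333,
               tolerance = 1e-6)
  # live cross-check of the closed form against numerical integration
  for (F in c(0.5, 2, 2.5, 4)) {
    expect_equal(constant_control_value(sec_gov, F, 1),
                 quadrature_constant_value(1.5, 1, 1, 0.9, 0.1, 1, F, 1),
                 tolerance = 1e-8)
  }
})

test_that("brute-force search over constant controls recovers the optimum", {
  bf <- brute_force_best_constant(sec_gov, x0 = 1,
                                  F_grid = seq(0, 5, by = 0.01))
  expect_lt(abs(bf$F_grid_best - 2.5), 0.01 + 1e-12)
  expect_equal(bf$value_best, 1 + 6.25 / 1.8, tolerance = 1e-6)

  # grid capped below the optimum maximises at the boundary
  bf2 <- brute_force_best_constant(sec_gov, x0 = 1,
                                   F_grid = seq(0, 1, by = 0.01),
                                   refine = FALSE)
  expect_equal(bf2$F_grid_best, 1)

  # strict concavity: values along the grid are unimodal
  g <- seq(0, 5, by = 0.05)
  v <- constant_control_value(sec_gov, g, 1)
  expect_identical(sum(diff(sign(diff(v))) != 0), 1L)
})

test_that("every constant control is weakly dominated by the equilibrium value", {
  set.seed(99)
  for (sc in sample_scenarios(seed = 31, n = 10)) {
    for (mode in mh_modes()) for (actor in mh_actors()) {
      lq <- reduce_to_canonical(mode, actor, sc)
      eq <- solve_closed_form(lq, x0 = 1)
      Fs <- runif(20, 0, 3 * max(1, abs(eq$F_star)))
      expect_true(all(constant_control_value(lq, Fs, 1) <=
                        eq$V_at_x0 + 1e-10))
    }
  }
})

test_that("HJB residual certifies the closed form and detects perturbations", {
  sc <- baseline_scenario()
  for (mode in mh_modes()) for (actor in mh_actors()) {
    lq <- reduce_to_canonical(mode, actor, sc)
    eq <- solve_closed_form(lq)
    expect_lt(hjb_residual(lq, eq, x_values = c(0, 1, 10)), 1e-12)
  }

  lq <- sec_gov
  eq <- solve_closed_form(lq)
  # perturbing the shadow price makes the residual linear in x with slope
  # (rho + delta) * dA
  eqA <- eq; eqA$A <- eq$A + 0.1
  res <- residuals(eqA, x = c(0, 1, 5))
  expect_gt(hjb_residual(lq, eqA, x_values = c(0, 1, 5)), 0.1)
  expect_equal(unname(diff(res)) / c(1, 4), rep((lq$rho + lq$delta) * 0.1, 2),
               tolerance = 1e-10)

  # perturbing the premium shifts the residual uniformly by rho * dB
  eqB <- eq; eqB$premium <- eq$premium + 1
  expect_equal(hjb_residual(lq, eqB, x_values = c(-3, 0, 2)), lq$rho,
               tolerance = 1e-12)
})

test_that("trajectory integration matches the analytic constant-control path", {
  tr <- simulate_trajectory(sec_gov, F = 2.5, x0 = 1, T = 10, step = 0.5)
  expect_s3_class(tr, "mh_trajectory")
  expect_equal(tr$x[tr$t == 10], 25 - 24 * exp(-1), tolerance = 1e-7)

  # steady state k F / delta = 25
  tr_long <- simulate_trajectory(sec_gov, F = 2.5, x0 = 1, T = 120, step = 1)
  expect_equal(tail(tr_long$x, 1), 25, tolerance = 1e-4)

  # pure decay at zero effort
  tr0 <- simulate_trajectory(sec_gov, F = 0, x0 = 1, T = 60, step = 1)
  expect_equal(tr0$x, exp(-0.1 * tr0$t), tolerance = 1e-8)

  # state-feedback policies are integrated too
  trf <- simulate_trajectory(sec_gov, F = function(x) 2.5, x0 = 1,
                             T = 10, step = 0.5)
  expect_equal(trf$x, tr$x, tolerance = 1e-7)

  expect_error(simulate_trajectory(sec_gov, F = Inf, x0 = 1), "finite")
  expect_error(simulate_trajectory(sec_gov, F = 1, x0 = 1, T = -1), "T")
})

test_that("discounted quadrature reproduces the closed-form value with a certified tail", {
  tr <- simulate_trajectory(sec_gov, F = 2.5, x0 = 1, T = 60, step = 0.1)
  dp <- discounted_payoff_numeric(tr, tail_tolerance = 1e-4)
  expect_equal(dp$value, 1 + 6.25 / 1.8, tolerance = 1e-4)
  expect_lt(dp$tail_bound, 1e-4)

  # all-zero flow integrates to zero
  lq0 <- canonical_lq(m = 0, C = 1, k = 0, l = 0)
  tr0 <- simulate_trajectory(lq0, F = 0, x0 = 0, T = 60, step = 1)
  dp0 <- discounted_payoff_numeric(tr0, lq = lq0)
  expect_equal(dp0$value, 0)
  expect_equal(dp0$tail_bound, 0)

  # too-short horizons fail loudly and name the horizon needed
  tr5 <- simulate_trajectory(sec_gov, F = 2.5, x0 = 1, T = 5, step = 0.1)
  expect_error(discounted_payoff_numeric(tr5, tail_tolerance = 1e-6),
               "need T >=")
  expect_gte(quadrature_horizon(sec_gov, 2.5, 1), 40)
})

test_that("equilibrium simulate method runs the fitted policy", {
  eq <- mh_equilibrium("security", "government")
  tr <- simulate(eq, T = 60, step = 0.1)
  expect_equal(tr$F[1], 2.5, tolerance = 1e-12)
  dp <- discounted_payoff_numeric(tr)
  expect_equal(dp$value, eq$V_at_x0, tolerance = 1e-5)
  # trajectories export as plain CSV
  p <- file.path(tempdir(), "traj.csv")
  write_trajectory(tr, p)
  back <- utils::read.csv(p)
  expect_identical(names(back), c("t", "x", "F", "flow", "discounted_cum"))
})
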