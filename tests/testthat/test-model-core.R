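test_that("shadow price is l/(rho + delta) and rejects degenerate rates", {
  expect_equal(shadow_price(baseline_scenario()), 1)
  expect_equal(shadow_price(list(l = 2, rho = 0.5, delta = 0.5)), 2)
  expect_error(shadow_price(list(l = 1, rho = 0, delta = 0.1)), "rho")
  expect_error(shadow_price(list(l = 1, rho = 0.9, delta = 0)), "delta")
})

test_that("canonical reductions match the flow/dynamics coefficients of all six problems", {
  sc <- baseline_scenario()  # beta = 1, c = 1
  cases <- list(
    list("screening", "government", m = 0.6, C = log(exp(1) + 2), k = -0.2),
    list("screening", "union",      m = 1.0, C = 1, k = 0.1),
    list("security",  "government", m = 1.5, C = 1, k = 1),
    list("security",  "union",      m = 0.5, C = 1, k = 1),
    list("training",  "government", m = 4.5, C = 1, k = -1),
    list("training",  "union",      m = 2.0, C = 1, k = -1)
  )
  for (cs in cases) {
    lq <- reduce_to_canonical(cs[[1]], cs[[2]], sc)
    expect_equal(lq$m, cs$m, tolerance = 1e-12,
                 info = paste(cs[[1]], cs[[2]]))
    expect_equal(lq$C, cs$C, tolerance = 1e-12)
    expect_equal(lq$k, cs$k, tolerance = 1e-12)
  }
  expect_error(reduce_to_canonical("bribery", "government", sc))
  expect_error(reduce_to_canonical("security", "employer", sc))
})

test_that("closed-form solution reproduces hand-derived equilibria", {
  # security / government: F* = (1.5 + 1)/1 = 2.5, premium = 2.5^2/1.8
  eq <- solve_closed_form(canonical_lq(m = 1.5, C = 1, k = 1), x0 = 1)
  expect_equal(eq$F_star, 2.5, tolerance = 1e-12)
  expect_equal(eq$premium, 6.25 / 1.8, tolerance = 1e-12)
  expect_equal(round(eq$premium, 2), 3.47)  # the reported coefficient
  expect_equal(eq$V_at_x0, 1 + 6.25 / 1.8, tolerance = 1e-12)
  expect_true(eq$interior)

  # security / union: premium exactly 1.25
  equ <- solve_closed_form(canonical_lq(m = 0.5, C = 1, k = 1), x0 = 1)
  expect_equal(equ$premium, 1.25, tolerance = 1e-14)

  # screening / government: inflated cost, F* = 0.4/log(e+2)
  eqs <- mh_equilibrium("screening", "government")
  expect_equal(eqs$F_star, 0.4 / log(exp(1) + 2), tolerance = 1e-12)
  expect_equal(eqs$premium, 0.16 / (1.8 * log(exp(1) + 2)), tolerance = 1e-12)
  expect_equal(eqs$F_star, 0.257824, tolerance = 1e-5)
  expect_equal(eqs$premium, 0.057294, tolerance = 1e-5)

  # degenerate problem: zero gain and drift
  eq0 <- solve_closed_form(canonical_lq(m = 0, C = 1, k = 0), x0 = 3)
  expect_equal(eq0$F_star, 0)
  expect_equal(eq0$premium, 0)
  expect_equal(eq0$V_at_x0, eq0$A * 3)
  expect_false(eq0$interior)

  expect_error(canonical_lq(m = 1, C = 0, k = 1), "C")
  expect_error(canonical_lq(m = 1, C = 1, k = 1, rho = 0), "rho")
})

test_that("scenario-level equilibrium composes reduction and closed form", {
  sc <- baseline_scenario()
  for (mode in mh_modes()) for (actor in mh_actors()) {
    direct <- mh_equilibrium(mode, actor, sc)
    manual <- solve_closed_form(reduce_to_canonical(mode, actor, sc), x0 = 1)
    expect_equal(coef(direct), coef(manual), tolerance = 1e-14)
  }
  # hand-checked premiums for the remaining problems
  expect_equal(mh_equilibrium("training", "government")$premium, 12.25 / 1.8,
               tolerance = 1e-12)
  expect_equal(mh_equilibrium("training", "union")$premium, 1 / 1.8,
               tolerance = 1e-12)
  expect_equal(mh_equilibrium("screening", "union")$premium, 1.21 / 1.8,
               tolerance = 1e-12)
  expect_error(mh_equilibrium("security", "government", delta = 0), "delta")
})

test_that("value function is affine in initial reputation with slope A", {
  for (sc in sample_scenarios(seed = 11, n = 10)) {
    eq <- mh_equilibrium("training", "union", sc)
    x <- c(-5, 0, 1, 7.5)
    v <- predict(eq, x0 = x)
    expect_equal(diff(v) / diff(x), rep(eq$A, 3), tolerance = 1e-12)
    # premium does not depend on where the state starts
    eq2 <- mh_equilibrium("training", "union", sc, x0 = 42)
    expect_equal(eq2$premium, eq$premium, tolerance = 1e-14)
  }
})

test_that("premium is non-negative and zero only at a vanishing canonical gain", {
  for (sc in sample_scenarios(seed = 5, n = 25)) {
    for (mode in mh_modes()) for (actor in mh_actors()) {
      eq <- mh_equilibrium(mode, actor, sc)
      expect_gte(eq$premium, 0)
      if (eq$premium == 0) expect_equal(eq$lq$m + eq$A * eq$lq$k, 0)
    }
  }
})

test_that("equilibrium methods print, summarise and plot without error", {
  eq <- mh_equilibrium("security", "government")
  expect_output(print(eq), "effort F\\*")
  expect_output(print(summary(eq)), "HJB residual")
  expect_lt(max(abs(residuals(eq))), 1e-10)
  tmp <- file.path(tempdir(), "eqplot.png")
  grDevices::png(tmp); plot(eq); grDevices::dev.off()
  expect_true(file.exists(tmp))
})
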