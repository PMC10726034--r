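test_that("benefit coefficients match hand-derived values and are cost-free", {
  expect_equal(as.numeric(benefit_coefficient("security", "government",
                                              baseline_scenario())),
               6.25 / 1.8, tolerance = 1e-12)          # reported as 3.47
  expect_equal(as.numeric(benefit_coefficient("security", "union",
                                              baseline_scenario())),
               1.25, tolerance = 1e-14)                 # reported as 1.25
  expect_equal(as.numeric(benefit_coefficient("training", "government",
                                              baseline_scenario(beta_gov = 2))),
               20.25 / 1.8, tolerance = 1e-12)          # 11.25
  # independent of the cost coefficient
  for (cc in c(0.5, 1, 3)) {
    expect_equal(
      as.numeric(benefit_coefficient("screening", "union",
                                     baseline_scenario(c = cc))),
      1.21 / 1.8, tolerance = 1e-12)
  }
  # non-interior configurations are flagged
  expect_warning(
    bc <- benefit_coefficient("security", "union",
                              scenario_update(baseline_scenario(), b_G2 = 3.5)),
    "non-interior")
  expect_false(attr(bc, "interior"))
})

test_that("benefit curves follow V = A x0 + coefficient / c and agree with the solver", {
  sc <- baseline_scenario()
  cv <- benefit_curve("security", "government", sc, c_grid = c(1, 2, 4))
  expect_equal(cv$V, c(1 + 3.4722222, 1 + 1.7361111, 1 + 0.8680556),
               tolerance = 1e-6)
  for (i in seq_len(nrow(cv))) {
    eq <- mh_equilibrium("security", "government", sc, c = cv$c[i])
    expect_equal(cv$V[i], eq$V_at_x0, tolerance = 1e-12)
    expect_equal(cv$F_star[i], eq$F_star, tolerance = 1e-12)
  }
  # values approach the pure reputation term A x0 as the cost diverges
  far <- benefit_curve("training", "government", sc, c_grid = c(1e5, 1e6))
  expect_equal(far$V, rep(1, 2), tolerance = 1e-4)
  expect_error(benefit_curve("security", "union", sc, c_grid = c(-1, 2)),
               "costs")
})

test_that("mode orderings reproduce the comparative study", {
  expect_identical(mode_ordering("government", baseline_scenario())$mode,
                   c("training", "security", "screening"))
  expect_identical(mode_ordering("union", baseline_scenario(beta_union = 2))$mode,
                   c("security", "training", "screening"))
  # at low union beta the derived order has screening strictly between
  # security and training, with no tie between screening and security
  ord <- mode_ordering("union", baseline_scenario())
  expect_identical(ord$mode, c("security", "screening", "training"))
  expect_false(any(ord$tied_with_next, na.rm = TRUE))
  expect_equal(ord$premium, c(1.25, 1.21 / 1.8, 1 / 1.8), tolerance = 1e-12)
  # ordering is invariant to the initial reputation (A x0 is mode-free)
  ord2 <- mode_ordering("union", baseline_scenario(), x0 = -7)
  expect_identical(ord2$mode, ord$mode)
})

test_that("closed-form comparative statics carry the expected signs and values", {
  sc <- baseline_scenario()
  cs_p <- comparative_static("screening", "government", sc, "p_gov")
  expect_equal(cs_p$derivative, (1.5 + 1 * 1) / log(exp(1) + 2),
               tolerance = 1e-12)  # (a1 + A beta1)/C > 0
  expect_identical(cs_p$sign, 1)

  cs_d <- comparative_static("training", "union", sc, "d")
  expect_equal(cs_d$derivative, -1, tolerance = 1e-12)  # -A/c
  expect_identical(cs_d$sign, -1)

  cs_f <- comparative_static("screening", "union", sc, "f_union")
  expect_identical(cs_f$sign, -1)

  cs_b <- comparative_static("security", "union", sc, "b_G2")
  expect_identical(cs_b$sign, -1)

  # b_T1 does not enter the government security problem
  cs0 <- comparative_static("security", "government", sc, "b_T1")
  expect_equal(cs0$derivative, 0)
  expect_false(cs0$applicable)
  expect_match(cs0$note, "does not enter")

  expect_error(comparative_static("security", "government", sc, "zeta"),
               "unknown")
})

test_that("closed-form derivatives agree with finite differences on random scenarios", {
  fields <- c("p_gov", "p_union", "f_gov", "f_union", "d", "b_G2", "b_T1",
              "a_gov", "a_union", "c", "I_S", "l", "rho", "delta",
              "beta_gov", "beta_union")
  for (sc in sample_scenarios(seed = 13, n = 5, require_interior = TRUE)) {
    for (mode in mh_modes()) for (actor in mh_actors()) {
      for (f in fields) {
        cs <- comparative_static(mode, actor, sc, f)
        denom <- max(abs(cs$derivative), 1e-8)
        expect_lt(abs(cs$derivative - cs$fd) / denom, 1e-6)
      }
    }
  }
})

test_that("the coefficient audit flags exactly the reported values that disagree", {
  audit <- coefficient_audit()
  expect_identical(nrow(audit), 12L)
  expect_equal(audit$derived, expected_coefficients$derived, tolerance = 1e-10)
  # only the two security-mode low/matching rows agree at 2 d.p.
  expect_identical(audit$match,
                   c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE,
                     FALSE, TRUE, FALSE, FALSE, FALSE, FALSE))
  # the mismatch of the high-beta government security row also violates
  # monotonicity: the reported 2.92 is below the low-beta 3.47 although the
  # premium is strictly increasing in beta
  expect_gt(audit$derived[5], audit$derived[2])
  expect_lt(audit$reported[5], audit$reported[2])
})

test_that("conclusion checks pass where derivable and report the rest as findings", {
  rep <- check_conclusions()
  st <- setNames(rep$conclusions$status, rep$conclusions$id)
  expect_identical(st[["C1"]], "pass")
  expect_identical(st[["C2"]], "not-derivable")
  expect_identical(st[["C3"]], "pass")
  expect_identical(st[["C4"]], "pass")
  expect_identical(st[["C5"]], "not-derivable")
  expect_identical(st[["C6"]], "pass")
  expect_match(rep$conclusions$evidence[rep$conclusions$id == "C5"],
               "screening 0.6722")

  # pairwise government gaps scale exactly as 1/c: (6.8056 - 0.0573)/c
  g1 <- rep$gaps[rep$gaps$actor == "government" & rep$gaps$beta == 1, ]
  expect_equal(g1$max_gap * g1$c, rep((12.25 - 0.16 / log(exp(1) + 2)) / 1.8,
                                      nrow(g1)), tolerance = 1e-9)
  expect_true(all(diff(g1$max_gap) < 0))
  expect_output(print(rep), "C4 \\[pass\\]")
})
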