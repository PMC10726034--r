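# Hand-derived closed-form quantities at the baseline parameters
# (rho = 0.9, delta = 0.1, l = 1 => shadow price A = 1).
#
# coefficient = (m + A k)^2 / (2 rho g), g = log(e + I_S) for government
# screening and 1 otherwise; all arithmetic below is independent of the
# package's own reduction code.

.e_g <- log(exp(1) + 2)  # government screening cost inflation, ~1.551446

# (actor, mode, beta) -> benefit coefficient, presentation order
expected_coefficients <- data.frame(
  actor = rep(c("government", "union"), each = 6),
  mode = rep(c("screening", "security", "training"), 4),
  beta = rep(rep(c(1, 2), each = 3), 2),
  derived = c(
    (1.5 * 0.4 + (0.4 * 1 - 0.6))^2 / (1.8 * .e_g),  # 0.0573
    (1.5 + 1)^2 / 1.8,                               # 3.4722
    (1.5 + 3 + (1 - 2))^2 / 1.8,                     # 6.8056
    (1.5 * 0.4 + (0.4 * 2 - 0.6))^2 / (1.8 * .e_g),  # 0.2292
    (1.5 + 2)^2 / 1.8,                               # 6.8056
    (1.5 + 3 + (2 - 2))^2 / 1.8,                     # 11.25
    (2 * 0.5 + (0.5 * 1 - 0.4))^2 / 1.8,             # 0.6722
    (2 - 1.5 + 1)^2 / 1.8,                           # 1.25
    (2 + (1 - 2))^2 / 1.8,                           # 0.5556
    (2 * 0.5 + (0.5 * 2 - 0.4))^2 / 1.8,             # 1.4222
    (2 - 1.5 + 2)^2 / 1.8,                           # 3.4722
    (2 + (2 - 2))^2 / 1.8                            # 2.2222
  )
)

# independent quadrature of the constant-control payoff: integrate the
# discounted flow along the analytic reputation path
quadrature_constant_value <- function(m, C, k, rho, delta, l, F, x0,
                                      upper = 200) {
  xfun <- function(t) x0 * exp(-delta * t) + (k * F / delta) * (1 - exp(-delta * t))
  stats::integrate(function(t)
    exp(-rho * t) * (m * F - C * F^2 / 2 + l * xfun(t)),
    lower = 0, upper = upper, rel.tol = 1e-12)$value
}

# six-problem canonical reductions recomputed by plain arithmetic from a
# scenario record (test-side oracle for reduce_to_canonical)
oracle_reduction <- function(sc, mode, actor) {
  if (mode == "screening" && actor == "government")
    list(m = sc$a_gov * sc$p_gov, C = sc$c * log(exp(1) + sc$I_S),
         k = sc$p_gov * sc$beta_gov - sc$f_gov)
  else if (mode == "screening")
    list(m = sc$a_union * sc$p_union, C = sc$c,
         k = sc$p_union * sc$beta_union - sc$f_union)
  else if (mode == "security" && actor == "government")
    list(m = sc$a_gov, C = sc$c, k = sc$beta_gov)
  else if (mode == "security")
    list(m = sc$a_union - sc$b_G2, C = sc$c, k = sc$beta_union)
  else if (actor == "government")
    list(m = sc$a_gov + sc$b_T1, C = sc$c, k = sc$beta_gov - sc$d)
  else
    list(m = sc$a_union, C = sc$c, k = sc$beta_union - sc$d)
}
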