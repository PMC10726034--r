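---
title: "Methods: differential games of mental-health protection policy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential games of mental-health protection policy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mhgame)
```

## The model and its assumptions

Two actors — a government and a labor union — each choose a continuous,
non-negative effort level $F_i(t)$ to protect young employees' mental
health under one of three policy modes: psychological screening, social
security provision, or strengthened training. Each actor's organisational
reputation $x_i(t)$ follows Nerlove–Arrow goodwill dynamics: effort builds
reputation at a mode-specific net rate, and reputation decays at rate
$\delta$. The actor maximises the discounted integral of a flow payoff
that is linear in reputation (weight $l$), linear in the beneficial part
of effort, and quadratic in its cost.

Three structural assumptions matter for everything downstream:

1. **Payoff decoupling.** Neither actor's flow payoff or dynamics contain
   the other's effort. The "game" equilibrium of each mode is therefore
   the pair of independent single-agent optima. This is documented model
   structure, not an approximation, and it is why the package solves six
   scalar problems rather than one coupled system.
2. **Linear-quadratic structure.** The flow payoff is linear in the state
   and quadratic (strictly concave) in the control, and the dynamics are
   linear. The HJB equation
   $\rho V = \max_F \{ mF - \tfrac{C}{2}F^2 + lx + V'(x)(kF - \delta x)\}$
   then admits an *exactly* affine value function $V(x) = A x + B$:
   matching the coefficient of $x$ gives the shadow price
   $A = l/(\rho+\delta)$, and matching constants gives
   $B = (m + Ak)^2 / (2\rho C)$ with equilibrium effort
   $F^* = (m + Ak)/C$. The affine ansatz is not a truncation; the
   residual of the HJB equation is identically zero, which the test suite
   certifies numerically to $10^{-9}$ over $x \in [-10, 10]$.
3. **Infinite horizon, stationary parameters.** Mental-health protection
   is modelled as a permanent activity, so the equilibrium effort is a
   constant and every trajectory converges to the steady state
   $x_\infty = kF^*/\delta$.

### The six canonical reductions

| problem | $m$ | $C$ | $k$ |
|---|---|---|---|
| screening / government | $a_1 p_1$ | $c\,\ln(e + I_S)$ | $p_1\beta_1 - f_1$ |
| screening / union | $a_2 p_2$ | $c$ | $p_2\beta_2 - f_2$ |
| security / government | $a_1$ | $c$ | $\beta_1$ |
| security / union | $a_2 - b_{G2}$ | $c$ | $\beta_2$ |
| training / government | $a_1 + b_{T1}$ | $c$ | $\beta_1 - d$ |
| training / union | $a_2$ | $c$ | $\beta_2 - d$ |

The government's screening cost is inflated by $\ln(e + I_S) \ge 1$,
read as "log of (Euler's $e$ plus the information difficulty $I_S$)": the
government finds it harder than the union to obtain information about
employees, and the factor is 1 when $I_S \to 0$. The alternative reading
$\ln(e) + I_S$ was rejected because it would triple the baseline cost and
reproduces neither the reported screening coefficient nor the narrative
that the inflation is a mild friction.

## Parameters, units and defaults

All parameters are rates or gains per unit of (dimensionless) effort or
time. The baseline scenario (`baseline_scenario()`) is the configuration
of the original numerical study: $\rho = 0.9$, $\delta = 0.1$, $l = 1$,
$a_1 = 1.5$, $a_2 = 2$, $f_1 = 0.6$, $f_2 = 0.4$, $p_1 = 0.4$,
$p_2 = 0.5$, $I_S = 2$, $d = 2$, $b_{T1} = 3$, $b_{G2} = 1.5$,
$x_0 = 1$ for both actors. The reputation gains $\beta_1, \beta_2$ and
the cost coefficient $c$ have no single study value — the study sweeps
$\beta \in \{1, 2\}$ and plots benefits against $c$ — so they are
call-time arguments with defaults $\beta = 1$, $c = 1$.

Two deliberate tightenings of the parameter domain:

* **$\rho > 0$ strictly.** The original symbol table allows $\rho = 0$,
  but every value function carries a $1/\rho$ factor, so the undiscounted
  limit is undefined; validation rejects it.
* **Single $a$ and $c$ per actor.** The original subscripting ($a_{Y i}$,
  $c_{Y i}$) permits mode-specific gains and costs, but the numerical
  study uses one value per actor across all modes. The scenario record
  therefore stores one value per actor; mode-specific variants are
  expressed through per-call overrides (`scenario_update()`, or `...` in
  `mh_equilibrium()`), which keeps the serialized scenario flat and
  unambiguous.

### Non-interior problems

Nothing guarantees $m + Ak > 0$: screening with $f_1 > p_1\beta_1$ and a
large shadow price, or security with $b_{G2} > a_2 + A\beta_2$, makes the
interior first-order effort negative. The closed form is still returned,
flagged `interior = FALSE`; the feasible optimum is then the boundary
policy $F = 0$, whose value $l x_0/(\rho+\delta)$ is available through
`constant_control_value(lq, 0, x0)`, and the CLI warns and reports both.
The reputation state itself is unconstrained in sign (screening with
$f_1 > p_1\beta_1$ drives it negative in steady state); no floor is
imposed because none exists in the model.

## The scenario sampler

`sample_scenarios()` is the package's synthetic-data stage: it draws each
parameter independently and uniformly within per-field ranges, in a fixed
documented field order, so a `(seed, n, ranges)` triple is bit-for-bit
reproducible. The default ranges bracket the baseline values —
$\rho \in [0.1, 1]$, $\delta \in (0, 1]$, $l \in (0, 3]$, gains and cost
in $(0, 5]$, probabilities in $(0, 1]$, remaining positive parameters and
initial reputations in $(0, 4]$ — because the study itself prescribes no
sampling distribution and these spans cover every configuration it
exercises with room on both sides. `require_interior = TRUE` applies
rejection sampling until all six problems have strictly positive
equilibrium effort, which is the regime the study's conclusions concern.

What the sampler emulates is parameter uncertainty around a stylised
policy model; what it does **not** emulate is real data of any kind. There
is no noise process, no measurement error, no empirical calibration
against survey or registry statistics, and no behavioural heterogeneity.
Passing tests therefore certify the mathematics of the model and the
internal consistency of the published analysis — they say nothing about
whether the model describes actual governments, unions or employees.

## Numerical choices

* **Verification oracles are independent of the closed form.** The
  constant-control value is derived by direct integration of the flow
  along the analytic state path (and re-checked in the test suite against
  `stats::integrate`); the brute-force grid search maximises that value
  over an effort grid whose upper end, $4\max(1, F_{\mathrm{unc}})$, is
  computed from the stationary point of the constant-control quadratic,
  not from the HJB solution. For this problem class the best constant
  control coincides with the feedback optimum, so the grid winner must
  approach $(F^*, V(x_0))$ — the oracle-equivalence property the
  acceptance checks exercise on 50 random interior scenarios with grid
  step $10^{-3}$.
* **Grid refinement.** A step-$h$ grid bounds the value error only by
  $\tfrac{C}{2\rho}(h/2)^2$, which for large $C$ or small $\rho$ can
  exceed the $10^{-6}$ agreement the oracle check demands. The search
  therefore reports both the raw grid winner (used for the effort check,
  within one step) and a golden-section refinement *of the same
  independent constant-control objective* within one grid step (used for
  the value check). The refinement never touches the closed form.
* **ODE integration** uses `deSolve::lsoda` with relative tolerance
  $10^{-9}$, integrating the discounted payoff as an auxiliary state so
  the quadrature inherits the integrator's accuracy instead of a
  trapezoid rule on the output grid. Constant-control paths are always
  cross-checked against the analytic solution and an error is raised on
  disagreement.
* **Quadrature horizon.** The truncation error of the payoff integral is
  certified by $e^{-\rho T} S/\rho$ with
  $S = |m F| + \tfrac{C}{2}F^2 + l\max(|x_0|, |kF/\delta|)$ an explicit
  flow bound; the default horizon is $\max(40, \ln(S/(\rho\,\mathrm{tol}))/\rho)$
  at tolerance $10^{-6}$, and a too-short horizon fails loudly with the
  minimal adequate $T$ rather than returning a silently biased value.
* **Comparative statics** are exact chain-rule derivatives through the
  canonical reduction and the shadow price, cross-validated against a
  centered finite difference of the full reduce-then-solve pipeline with
  relative step $10^{-6}$; agreement to relative $10^{-6}$ holds on
  sampled interior scenarios. Fields that do not enter a problem return
  derivative 0 with an explicit "inapplicable" note instead of being an
  error, because one published conclusion turns on exactly such a field.
* **Ties** in mode orderings are declared at relative $10^{-9}$ —
  tight enough that only exact coincidences (e.g. training at
  $\beta = d$, where $k = 0$ in two modes) register as ties, while the
  0.58-sized gap behind the published "equal benefits" claim does not.
* **Problem sizes.** The shipped checks use 50 sampled scenarios for the
  oracle sweep, 100-point cost grids on $[0.25, 10]$ for orderings and
  convergence, and a horizon of 60 time units at step 0.1 for the worked
  trajectory; these sizes were chosen as comfortably sufficient for the
  stated tolerances.

## The coefficient audit

At the baseline parameters, the study's own propositions give the twelve
benefit coefficients (premium × cost) as 0.0573 / 3.4722 / 6.8056 at
$\beta_1 = 1$, 0.2292 / 6.8056 / 11.25 at $\beta_1 = 2$ (government
screening / security / training), and 0.6722 / 1.25 / 0.5556,
1.4222 / 3.4722 / 2.2222 for the union. The originally reported numbers
agree for exactly two of the twelve (security mode: 3.47 and 1.25) and
disagree for the other ten — one of them (the high-$\beta$ government
security value, reported 2.92 < 3.47) even violating the monotonicity of
the premium in $\beta_1$ that the closed form implies. The package treats
the derived closed forms as canonical — they satisfy the HJB equations to
round-off, which the reported coefficients cannot all do — and ships the
reported values purely as audit data (`reported_benefit_coefficients()`,
`coefficient_audit()`), with an optional dotted overlay on the figures
for visual comparison. Similarly, two published qualitative conclusions
are not derivable from the propositions: the claimed dependence of
government security effort on the training contribution $b_{T1}$ (the
parameter does not enter that problem; the plausibly intended statement
about the union's sabotage loss $b_{G2}$ is evaluated alongside, flagged
as interpretation) and the claimed equality of union screening and
security benefits at low $\beta_2$ (0.6722 vs 1.25). `check_conclusions()`
reports both as `not-derivable` findings with the evidence numbers —
stating derivations and mismatches without reinterpreting intent.

## Known limitations

* No strategic coupling: cross terms, leader–follower timing and
  cooperative solutions are out of scope by construction.
* Deterministic dynamics only; no stochastic reputation shocks.
* The audit is arithmetic, not forensic: it demonstrates that the
  reported coefficients are inconsistent with the propositions at the
  stated parameters, but cannot recover which alternative parameter
  values (if any) produced them.
* Effort is unconstrained above zero; capacity limits or budget
  constraints would bound $F^*$ and break the clean $1/c$ scaling of the
  benefit curves.
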