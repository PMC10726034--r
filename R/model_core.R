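# Canonical scalar LQ reduction and closed-form HJB solution.
#
# Every (mode, actor) problem is the discounted infinite-horizon control
# problem
#
#   max_F  integral_0^inf e^{-rho t} [ m F - (C/2) F^2 + l x ] dt
#   s.t.   dx/dt = k F - delta x,   x(0) = x0,
#
# whose HJB equation rho V = max_F { m F - (C/2) F^2 + l x + V'(x)(kF - delta x) }
# admits the affine value function V(x) = A x + B with
#   A = l / (rho + delta)          (shadow price of reputation)
#   F* = (m + A k) / C             (constant feedback equilibrium effort)
#   B = (m + A k)^2 / (2 rho C)    (value premium above the reputation term).

#' Policy modes of the game
#'
#' The three mental-health protection modes: psychological `screening`,
#' social `security` provision, and strengthened `training`.
#' @return Character vector of the three mode names.
#' @export
mh_modes <- function() c("screening", "security", "training")

#' Actors of the game
#' @return Character vector `c("government", "union")`.
#' @export
mh_actors <- function() c("government", "union")

.match_mode <- function(mode) match.arg(mode, mh_modes())
.match_actor <- function(actor) match.arg(actor, mh_actors())

#' Shadow price of reputation
#'
#' The marginal value of one unit of reputation, `l / (rho + delta)`.  It
#' is identical across all six (mode, actor) problems because reputation
#' enters every flow payoff linearly with weight `l` and decays at the
#' common rate `delta`.
#'
#' @param params an `mh_scenario`, or any list with numeric `l`, `rho`,
#'   `delta`.
#' @return The scalar shadow price.
#' @export
#' @examples
#' shadow_price(baseline_scenario())  # 1
shadow_price <- function(params) {
  if (params$rho <= 0) stop("rho must be > 0 (value functions carry a 1/rho factor)",
                            call. = FALSE)
  if (params$delta <= 0) stop("delta must be > 0", call. = FALSE)
  if (params$l <= 0) stop("l must be > 0", call. = FALSE)
  params$l / (params$rho + params$delta)
}

#' Reduce a (mode, actor) problem to canonical scalar LQ form
#'
#' Maps each of the six problems onto the triple `(m, C, k)`:
#' \describe{
#'   \item{m}{net linear flow gain per unit effort,}
#'   \item{C}{quadratic effort-cost coefficient (> 0),}
#'   \item{k}{net reputation drift per unit effort (any sign).}
#' }
#' The reductions are:
#' \tabular{llll}{
#'   problem \tab m \tab C \tab k \cr
#'   screening / government \tab `a_gov * p_gov` \tab `c * log(e + I_S)` \tab `p_gov*beta_gov - f_gov` \cr
#'   screening / union \tab `a_union * p_union` \tab `c` \tab `p_union*beta_union - f_union` \cr
#'   security / government \tab `a_gov` \tab `c` \tab `beta_gov` \cr
#'   security / union \tab `a_union - b_G2` \tab `c` \tab `beta_union` \cr
#'   training / government \tab `a_gov + b_T1` \tab `c` \tab `beta_gov - d` \cr
#'   training / union \tab `a_union` \tab `c` \tab `beta_union - d`
#' }
#' where `e` is Euler's number: the factor `log(e + I_S) >= 1` inflates the
#' government's screening cost by its information-acquisition difficulty.
#'
#' @param mode one of `"screening"`, `"security"`, `"training"`.
#' @param actor `"government"` or `"union"`.
#' @param params an `mh_scenario`.
#' @return An object of class `mh_canonical`: list with `m`, `C`, `k`,
#'   `rho`, `delta`, `l`, `mode`, `actor`.
#' @export
#' @examples
#' lq <- reduce_to_canonical("security", "government", baseline_scenario())
#' c(lq$m, lq$C, lq$k)  # 1.5 1 1
reduce_to_canonical <- function(mode, actor, params) {
  mode <- .match_mode(mode)
  actor <- .match_actor(actor)
  stopifnot(inherits(params, "mh_scenario"))
  p <- params
  gov <- identical(actor, "government")
  red <- switch(mode,
    screening = if (gov)
      list(m = p$a_gov * p$p_gov, C = p$c * log(exp(1) + p$I_S),
           k = p$p_gov * p$beta_gov - p$f_gov)
    else
      list(m = p$a_union * p$p_union, C = p$c,
           k = p$p_union * p$beta_union - p$f_union),
    security = if (gov)
      list(m = p$a_gov, C = p$c, k = p$beta_gov)
    else
      list(m = p$a_union - p$b_G2, C = p$c, k = p$beta_union),
    training = if (gov)
      list(m = p$a_gov + p$b_T1, C = p$c, k = p$beta_gov - p$d)
    else
      list(m = p$a_union, C = p$c, k = p$beta_union - p$d)
  )
  if (red$C <= 0) stop("canonical cost coefficient must be > 0", call. = FALSE)
  structure(c(red, list(rho = p$rho, delta = p$delta, l = p$l,
                        mode = mode, actor = actor)),
            class = "mh_canonical")
}

#' Construct a canonical LQ problem directly
#'
#' Mostly useful for tests and for exploring the scalar problem without a
#' full scenario.
#'
#' @param m linear flow gain per unit effort.
#' @param C quadratic effort-cost coefficient, > 0.
#' @param k reputation drift per unit effort.
#' @param rho discount rate, > 0.
#' @param delta reputation decay rate, > 0.
#' @param l reputation weight in the flow payoff.
#' @param mode,actor optional labels.
#' @return An `mh_canonical` object.
#' @export
canonical_lq <- function(m, C, k, rho = 0.9, delta = 0.1, l = 1,
                         mode = NA_character_, actor = NA_character_) {
  if (C <= 0) stop("C must be > 0", call. = FALSE)
  if (rho <= 0) stop("rho must be > 0", call. = FALSE)
  if (delta <= 0) stop("delta must be > 0", call. = FALSE)
  structure(list(m = m, C = C, k = k, rho = rho, delta = delta, l = l,
                 mode = mode, actor = actor),
            class = "mh_canonical")
}

#' @export
print.mh_canonical <- function(x, ...) {
  lab <- if (!is.na(x$mode)) paste0(" (", x$mode, " / ", x$actor, ")") else ""
  cat("Canonical LQ problem", lab, "\n", sep = "")
  cat(sprintf("  m = %.6g, C = %.6g, k = %.6g\n", x$m, x$C, x$k))
  cat(sprintf("  rho = %.6g, delta = %.6g, l = %.6g\n", x$rho, x$delta, x$l))
  invisible(x)
}

#' Solve the HJB equation of a canonical problem in closed form
#'
#' The unique affine-value-function solution: shadow price
#' `A = l/(rho + delta)`, equilibrium effort `F* = (m + A k)/C`, value
#' premium `B = (m + A k)^2 / (2 rho C)` and value `V(x0) = A x0 + B`.
#' When `m + A k <= 0` the interior first-order condition gives a
#' non-positive effort; the closed form is still returned with
#' `interior = FALSE`, and the feasible boundary policy is zero effort
#' (its value is `constant_control_value(lq, 0, x0)`).
#'
#' @param lq an `mh_canonical` problem.
#' @param x0 initial reputation.
#' @return An object of class `mh_equilibrium` with fields `F_star`, `A`,
#'   `premium`, `V_at_x0`, `interior`, plus the problem `lq` and `x0`.
#' @seealso [mh_equilibrium()] for the scenario-level interface,
#'   [hjb_residual()] for numerical certification.
#' @export
#' @examples
#' lq <- canonical_lq(m = 1.5, C = 1, k = 1)
#' eq <- solve_closed_form(lq, x0 = 1)
#' eq$F_star   # 2.5
#' eq$premium  # 3.4722...
solve_closed_form <- function(lq, x0 = 1) {
  stopifnot(inherits(lq, "mh_canonical"))
  if (lq$C <= 0) stop("C must be > 0", call. = FALSE)
  if (lq$rho <= 0) stop("rho must be > 0", call. = FALSE)
  A <- lq$l / (lq$rho + lq$delta)
  gain <- lq$m + A * lq$k
  F_star <- gain / lq$C
  premium <- gain^2 / (2 * lq$rho * lq$C)
  structure(list(
    F_star = F_star,
    A = A,
    premium = premium,
    V_at_x0 = A * x0 + premium,
    interior = gain > 0,
    lq = lq,
    x0 = x0
  ), class = "mh_equilibrium")
}

#' Closed-form equilibrium for a (mode, actor) problem
#'
#' The main entry point: reduces the scenario to canonical form and solves
#' the HJB equation.  Additional named arguments override scenario fields
#' for this call (e.g. `c = 2`, `beta_gov = 2`), which is how the
#' mode-comparison study sweeps the cost and the reputation gain.
#'
#' @param mode one of `"screening"`, `"security"`, `"training"`.
#' @param actor `"government"` or `"union"`.
#' @param params an `mh_scenario` (default: [baseline_scenario()]).
#' @param x0 initial reputation; defaults to the actor's `x0_*` field.
#' @param ... scenario field overrides, passed to [scenario_update()].
#' @return An `mh_equilibrium` object.
#' @export
#' @examples
#' eq <- mh_equilibrium("security", "government")
#' coef(eq)
#' predict(eq, x0 = c(0, 1, 2))
mh_equilibrium <- function(mode, actor, params = baseline_scenario(),
                           x0 = NULL, ...) {
  mode <- .match_mode(mode)
  actor <- .match_actor(actor)
  params <- scenario_update(params, ...)
  viol <- validate_scenario(params)
  if (any(viol$severity == "violation")) {
    v <- viol[viol$severity == "violation", ]
    stop("invalid scenario: ",
         paste(sprintf("%s (%s)", v$field, v$constraint), collapse = "; "),
         call. = FALSE)
  }
  if (is.null(x0))
    x0 <- if (actor == "government") params$x0_gov else params$x0_union
  solve_closed_form(reduce_to_canonical(mode, actor, params), x0 = x0)
}

#' @export
print.mh_equilibrium <- function(x, digits = 6, ...) {
  lab <- if (!is.na(x$lq$mode)) paste0(x$lq$mode, " / ", x$lq$actor) else "canonical problem"
  cat("Feedback equilibrium:", lab, "\n")
  cat(sprintf("  effort F*        = %.*g%s\n", digits, x$F_star,
              if (x$interior) "" else "  [non-interior: feasible optimum is F = 0]"))
  cat(sprintf("  shadow price A   = %.*g\n", digits, x$A))
  cat(sprintf("  value premium    = %.*g\n", digits, x$premium))
  cat(sprintf("  V(x0 = %g)       = %.*g\n", x$x0, digits, x$V_at_x0))
  invisible(x)
}

#' @export
coef.mh_equilibrium <- function(object, ...) {
  c(F_star = object$F_star, A = object$A,
    premium = object$premium, V_at_x0 = object$V_at_x0)
}

#' Equilibrium value at alternative initial reputations
#'
#' The value function is affine in the state, `V(x) = A x + premium`, so
#' prediction is exact for any reputation level.
#'
#' @param object an `mh_equilibrium`.
#' @param x0 numeric vector of reputation levels (default: the fitted `x0`).
#' @param ... unused.
#' @return Numeric vector `A * x0 + premium`.
#' @export
predict.mh_equilibrium <- function(object, x0 = object$x0, ...) {
  object$A * x0 + object$premium
}

#' HJB residuals of a fitted equilibrium
#'
#' Evaluates the HJB residual of the closed-form value function on a grid
#' of reputation values; all residuals are zero to round-off for a correct
#' solution.  See [hjb_residual()] for the definition.
#'
#' @param object an `mh_equilibrium`.
#' @param x reputation grid.
#' @param ... unused.
#' @return Named numeric vector of residuals.
#' @export
residuals.mh_equilibrium <- function(object, x = seq(-10, 10, length.out = 21), ...) {
  r <- vapply(x, function(xx)
    .hjb_residual_at(object$lq, object$A, object$premium, xx), numeric(1))
  names(r) <- format(x)
  r
}

#' @export
summary.mh_equilibrium <- function(object, ...) {
  res <- residuals(object)
  structure(list(eq = object, max_resid = max(abs(res))),
            class = "summary.mh_equilibrium")
}

#' @export
print.summary.mh_equilibrium <- function(x, ...) {
  print(x$eq)
  lq <- x$eq$lq
  cat(sprintf("  canonical (m, C, k) = (%.6g, %.6g, %.6g)\n", lq$m, lq$C, lq$k))
  cat(sprintf("  steady-state reputation under F*: %.6g\n",
              lq$k * max(x$eq$F_star, 0) / lq$delta))
  cat(sprintf("  max |HJB residual| on x in [-10, 10]: %.3g\n", x$max_resid))
  invisible(x)
}

#' Simulate the reputation trajectory under the equilibrium policy
#'
#' Integrates the reputation dynamics under the (constant) equilibrium
#' effort and accumulates the discounted payoff; a thin wrapper around
#' [simulate_trajectory()].  Non-interior equilibria are simulated at the
#' boundary policy F = 0.
#'
#' @param object an `mh_equilibrium`.
#' @param nsim unused (the model is deterministic); must be 1.
#' @param seed unused.
#' @param T horizon.
#' @param step output grid step.
#' @param ... unused.
#' @return An `mh_trajectory` data frame.
#' @export
simulate.mh_equilibrium <- function(object, nsim = 1, seed = NULL,
                                    T = 40, step = 0.05, ...) {
  stopifnot(nsim == 1)
  F_use <- if (object$interior) object$F_star else 0
  simulate_trajectory(object$lq, F = F_use, x0 = object$x0,
                      T = T, step = step)
}

#' Constant-control value curve of an equilibrium problem
#'
#' Plots the exact discounted payoff of holding each constant effort level
#' forever, with the closed-form optimum marked: a direct visual check
#' that the equilibrium effort sits at the peak of a strictly concave
#' value curve.
#'
#' @param x an `mh_equilibrium`.
#' @param F_range effort range; defaults to `[0, 2.5 * max(1, F*)]`.
#' @param n number of curve points.
#' @param ... passed to [graphics::plot()].
#' @export
plot.mh_equilibrium <- function(x, F_range = NULL, n = 201, ...) {
  if (is.null(F_range)) F_range <- c(0, 2.5 * max(1, x$F_star))
  Fg <- seq(F_range[1], F_range[2], length.out = n)
  vals <- constant_control_value(x$lq, Fg, x$x0)
  graphics::plot(Fg, vals, type = "l", xlab = "constant effort F",
                 ylab = "discounted payoff", ...)
  graphics::abline(v = x$F_star, lty = 2, col = "grey40")
  graphics::points(x$F_star, x$V_at_x0, pch = 19, col = "red3")
  invisible(x)
}
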