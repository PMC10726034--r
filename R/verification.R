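# Independent numerical verification of the closed-form equilibria:
# analytic constant-control values, brute-force search, HJB residuals,
# and ODE trajectory simulation with discounted-payoff quadrature.

#' Exact discounted payoff of a constant effort policy
#'
#' Holding effort `F` forever from initial reputation `x0`, the reputation
#' path is `x(t) = x0 e^{-delta t} + (k F / delta)(1 - e^{-delta t})` and
#' the discounted payoff integrates in closed form to
#' \deqn{(m F - C F^2/2)/\rho + l x_0/(\rho+\delta) + l k F/(\rho(\rho+\delta)).}
#' Maximising this expression over `F` recovers the feedback optimum
#' `F* = (m + A k)/C` — for this problem class the best constant control
#' and the best feedback control coincide, which is what makes the
#' brute-force grid search a valid oracle for the HJB solution.
#'
#' @param lq an `mh_canonical` problem.
#' @param F effort level(s); vectorised.
#' @param x0 initial reputation.
#' @return Numeric vector of discounted payoffs.
#' @export
#' @examples
#' lq <- canonical_lq(m = 1.5, C = 1, k = 1)
#' constant_control_value(lq, F = 0, x0 = 1)    # 1
#' constant_control_value(lq, F = 2.5, x0 = 1)  # 4.4722...
constant_control_value <- function(lq, F, x0) {
  stopifnot(inherits(lq, "mh_canonical"))
  if (lq$rho <= 0) stop("rho must be > 0", call. = FALSE)
  if (lq$delta <= 0) stop("delta must be > 0", call. = FALSE)
  (lq$m * F - lq$C * F^2 / 2) / lq$rho +
    lq$l * x0 / (lq$rho + lq$delta) +
    lq$l * lq$k * F / (lq$rho * (lq$rho + lq$delta))
}

#' Brute-force search over constant controls
#'
#' Exhaustive oracle for the closed-form equilibrium: evaluates
#' [constant_control_value()] on an effort grid and returns the best grid
#' point.  With `refine = TRUE` the grid optimum is polished by a
#' golden-section search within one grid step, so the returned value is
#' accurate to far better than the grid's quadratic value error while the
#' reported `F_grid_best` remains the raw grid winner.
#'
#' The grid is evaluated in chunks so that very fine grids do not allocate
#' large vectors at once.
#'
#' @param lq an `mh_canonical` problem.
#' @param x0 initial reputation.
#' @param F_grid sorted effort grid; default `seq(0, 4*max(1, F_unc), length.out
#'   = 4001)` where `F_unc` is the unconstrained stationary point of the
#'   constant-control value (computed without reference to the HJB
#'   solution).
#' @param refine polish the optimum within one grid step.
#' @return List with `F_best` (refined if requested), `value_best`,
#'   `F_grid_best`, `value_grid_best`, and `step` (max grid spacing).
#' @export
brute_force_best_constant <- function(lq, x0, F_grid = NULL, refine = TRUE) {
  stopifnot(inherits(lq, "mh_canonical"))
  if (is.null(F_grid)) {
    # stationary point of the analytic constant-control value, derived by
    # differentiating the quadratic in F (independent of the HJB route)
    F_unc <- (lq$m + lq$l * lq$k / (lq$rho + lq$delta)) / lq$C
    F_grid <- seq(0, 4 * max(1, F_unc), length.out = 4001)
  }
  if (length(F_grid) < 1L || is.unsorted(F_grid))
    stop("F_grid must be non-empty and sorted", call. = FALSE)
  chunk <- 1e6
  best_v <- -Inf
  best_i <- NA_integer_
  nF <- length(F_grid)
  for (start in seq(1L, nF, by = chunk)) {
    idx <- start:min(start + chunk - 1L, nF)
    v <- constant_control_value(lq, F_grid[idx], x0)
    j <- which.max(v)
    if (v[j] > best_v) { best_v <- v[j]; best_i <- idx[j] }
  }
  step <- if (nF > 1L) max(diff(F_grid)) else 0
  F_best <- F_grid[best_i]
  value_best <- best_v
  if (refine && nF > 1L) {
    lo <- if (best_i > 1L) F_grid[best_i - 1L] else F_grid[1L]
    hi <- if (best_i < nF) F_grid[best_i + 1L] else F_grid[nF]
    opt <- stats::optimize(function(f) constant_control_value(lq, f, x0),
                           interval = c(lo, hi), maximum = TRUE,
                           tol = 1e-10)
    F_best <- opt$maximum
    value_best <- opt$objective
  }
  list(F_best = F_best, value_best = value_best,
       F_grid_best = F_grid[best_i], value_grid_best = best_v,
       step = step)
}

# Residual of the HJB equation at one state value, for a candidate affine
# value function V(x) = A x + B.  The inner maximisation over effort is a
# concave quadratic, maximised exactly at F = (m + A k)/C.
.hjb_residual_at <- function(lq, A, B, x) {
  inner <- (lq$m + A * lq$k)^2 / (2 * lq$C) + lq$l * x - A * lq$delta * x
  lq$rho * (A * x + B) - inner
}

#' Maximum HJB residual of a candidate solution
#'
#' Evaluates `rho V(x) - max_F { m F - (C/2) F^2 + l x + V'(x)(k F - delta x) }`
#' on a grid of reputation values using the candidate affine value function
#' `V(x) = A x + premium` carried by `eq`, and returns the largest absolute
#' residual.  The closed-form solution yields residuals at round-off level;
#' perturbing `A` makes the residual linear in `x`, perturbing the premium
#' by `dB` shifts it uniformly by `rho * dB`.
#'
#' @param lq an `mh_canonical` problem.
#' @param eq an `mh_equilibrium` (possibly perturbed) supplying `A` and
#'   `premium`.
#' @param x_values reputation grid (default `seq(-10, 10, length.out = 81)`).
#' @return Maximum absolute residual over the grid.
#' @export
#' @examples
#' lq <- canonical_lq(m = 1.5, C = 1, k = 1)
#' hjb_residual(lq, solve_closed_form(lq))  # ~ 0
hjb_residual <- function(lq, eq, x_values = seq(-10, 10, length.out = 81)) {
  stopifnot(inherits(lq, "mh_canonical"))
  res <- vapply(x_values, function(x)
    .hjb_residual_at(lq, eq$A, eq$premium, x), numeric(1))
  max(abs(res))
}

#' Simulate a reputation trajectory
#'
#' Integrates `dx/dt = k F - delta x` from `x0` under a constant effort or
#' a feedback policy `F(x)`, jointly with the discounted payoff
#' `dP/dt = e^{-rho t} (m F - (C/2) F^2 + l x)`, using an adaptive
#' integrator (`deSolve::lsoda`, relative tolerance 1e-9).  For a constant
#' effort the integrator output is cross-checked against the analytic path
#' `x(t) = x0 e^{-delta t} + (k F/delta)(1 - e^{-delta t})` and an error is
#' raised if they disagree beyond tolerance.
#'
#' @param lq an `mh_canonical` problem.
#' @param F a single effort level, or a function of reputation `F(x)`.
#' @param x0 initial reputation.
#' @param T horizon (> 0).
#' @param step output grid spacing (> 0).
#' @param rtol,atol integrator tolerances.
#' @return An object of classes `mh_trajectory` and `data.frame` with
#'   columns `t`, `x`, `F`, `flow` and `discounted_cum` (discounted
#'   cumulative payoff up to `t`).
#' @export
#' @examples
#' lq <- canonical_lq(m = 1.5, C = 1, k = 1)
#' tr <- simulate_trajectory(lq, F = 2.5, x0 = 1, T = 10, step = 0.5)
#' tail(tr$x, 1)  # 25 - 24*exp(-1) = 16.17...
simulate_trajectory <- function(lq, F, x0, T = 40, step = 0.05,
                                rtol = 1e-9, atol = 1e-12) {
  stopifnot(inherits(lq, "mh_canonical"))
  if (!is.finite(x0) || !is.finite(T) || !is.finite(step))
    stop("non-finite arguments", call. = FALSE)
  if (T <= 0 || step <= 0) stop("T and step must be > 0", call. = FALSE)
  constantF <- is.numeric(F)
  if (constantF && (length(F) != 1L || !is.finite(F)))
    stop("constant effort F must be a single finite number", call. = FALSE)
  policy <- if (constantF) function(x) F else F
  times <- seq(0, T, by = step)
  if (times[length(times)] < T) times <- c(times, T)
  deriv <- function(t, y, parms) {
    f <- policy(y[1])
    flow <- lq$m * f - lq$C * f^2 / 2 + lq$l * y[1]
    list(c(lq$k * f - lq$delta * y[1], exp(-lq$rho * t) * flow))
  }
  sol <- deSolve::lsoda(c(x = x0, P = 0), times, deriv, parms = NULL,
                        rtol = rtol, atol = atol)
  x <- sol[, "x"]
  if (constantF) {
    xan <- x0 * exp(-lq$delta * times) +
      (lq$k * F / lq$delta) * (1 - exp(-lq$delta * times))
    if (max(abs(x - xan)) > 1e-6 * max(1, max(abs(xan))))
      stop("integrator disagrees with the analytic constant-control path",
           call. = FALSE)
  }
  Fpath <- vapply(x, policy, numeric(1))
  flow <- lq$m * Fpath - lq$C * Fpath^2 / 2 + lq$l * x
  out <- data.frame(t = times, x = x, F = Fpath, flow = flow,
                    discounted_cum = sol[, "P"])
  attr(out, "lq") <- lq
  class(out) <- c("mh_trajectory", "data.frame")
  out
}

#' Discounted payoff of a trajectory, with a certified tail bound
#'
#' Takes the discounted cumulative payoff accumulated along the trajectory
#' (integrated jointly with the state, not re-quadratured from the output
#' grid) and certifies the truncation error of the infinite-horizon
#' integral via the bound `e^{-rho T} * sup|flow| / rho`, where `sup|flow|`
#' is bounded using `|m F - C F^2/2| + l * max(|x0|, |k F / delta|)` over
#' the realised effort path.  If the bound exceeds `tail_tolerance` the
#' function stops and reports the minimal adequate horizon.
#'
#' @param traj an `mh_trajectory`.
#' @param lq the `mh_canonical` problem the trajectory was simulated under
#'   (default: taken from the trajectory).
#' @param tail_tolerance maximum admissible truncation error.
#' @return List with `value` (quadrature over `[0, T]`) and `tail_bound`.
#' @export
discounted_payoff_numeric <- function(traj, lq = attr(traj, "lq"),
                                      tail_tolerance = 1e-6) {
  stopifnot(inherits(traj, "mh_trajectory"), inherits(lq, "mh_canonical"))
  T <- max(traj$t)
  Fmax <- max(abs(traj$F))
  x0 <- traj$x[1]
  xbound <- max(abs(x0), abs(lq$k) * Fmax / lq$delta)
  S <- abs(lq$m) * Fmax + lq$C * Fmax^2 / 2 + abs(lq$l) * xbound
  tail_bound <- exp(-lq$rho * T) * S / lq$rho
  if (tail_bound > tail_tolerance) {
    T_needed <- log(S / (lq$rho * tail_tolerance)) / lq$rho
    stop(sprintf(
      "horizon T = %.4g too short for tail tolerance %.3g; need T >= %.4g",
      T, tail_tolerance, T_needed), call. = FALSE)
  }
  list(value = traj$discounted_cum[nrow(traj)], tail_bound = tail_bound)
}

#' Default quadrature horizon for a given tail tolerance
#'
#' `max(40, log(S/(rho*tol))/rho)` with `S` the flow bound used by
#' [discounted_payoff_numeric()].
#'
#' @param lq an `mh_canonical` problem.
#' @param F constant effort level.
#' @param x0 initial reputation.
#' @param tol tail tolerance.
#' @return Horizon length.
#' @export
quadrature_horizon <- function(lq, F, x0, tol = 1e-6) {
  xbound <- max(abs(x0), abs(lq$k) * abs(F) / lq$delta)
  S <- abs(lq$m) * abs(F) + lq$C * F^2 / 2 + abs(lq$l) * xbound
  max(40, log(max(S, .Machine$double.eps) / (lq$rho * tol)) / lq$rho)
}

#' Write a trajectory to CSV
#'
#' Columns `t, x, F, flow, discounted_cum`.
#'
#' @param traj an `mh_trajectory`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "mh_trajectory"))
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}
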