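# Parameter scenarios: construction, validation, sampling, (de)serialization.

# Fixed field order used everywhere (printing, sampling, serialization).
.scenario_fields <- c(
  "rho", "delta", "l", "a_gov", "a_union", "c",
  "p_gov", "p_union", "beta_gov", "beta_union",
  "f_gov", "f_union", "d", "b_T1", "b_G2", "I_S",
  "x0_gov", "x0_union"
)

#' Construct a parameter scenario
#'
#' A scenario is the full parameter record of the three-mode differential
#' game: discounting and reputation decay, per-actor gains from improved
#' mental health, effort-cost coefficient, screening success probabilities,
#' reputation gained per unit effort, screening dissatisfaction, training
#' resistance, the training-mode societal contribution, the security-mode
#' sabotage loss, the government's information-acquisition difficulty, and
#' the initial reputations.
#'
#' Defaults are the baseline values of the published numerical study (see
#' [baseline_scenario()]); `beta_gov`, `beta_union` and `c` have no single
#' published value (the study varies beta in {1, 2} and sweeps the cost) so
#' their defaults here are the study's low-beta, unit-cost configuration.
#'
#' @param rho discount rate per unit time, in (0, 1].
#' @param delta reputation decay rate per unit time, > 0.
#' @param l weight of reputation in the flow payoff, > 0.
#' @param a_gov,a_union unit gain from improved mental health, per actor, > 0.
#' @param c unit effort-cost coefficient, > 0, applied to every (mode, actor)
#'   problem (the screening-mode government cost is additionally inflated by
#'   `log(exp(1) + I_S)`; see [reduce_to_canonical()]).
#' @param p_gov,p_union screening success probabilities, in (0, 1].
#' @param beta_gov,beta_union reputation gained per unit effort, > 0.
#' @param f_gov,f_union screening dissatisfaction per unit effort, > 0.
#' @param d training resistance per unit effort, > 0 (shared by both actors).
#' @param b_T1 societal contribution per unit government training effort, > 0.
#' @param b_G2 sabotage loss per unit union security effort, > 0.
#' @param I_S government information-acquisition difficulty (screening), > 0.
#' @param x0_gov,x0_union initial reputations (any sign).
#' @param comment free-text provenance note carried through serialization.
#' @return An object of class `mh_scenario`: a named list with the fields
#'   above in a fixed canonical order.
#' @seealso [validate_scenario()], [sample_scenarios()], [read_scenario()]
#' @export
#' @examples
#' sc <- mh_scenario()
#' sc$rho
mh_scenario <- function(rho = 0.9, delta = 0.1, l = 1,
                        a_gov = 1.5, a_union = 2, c = 1,
                        p_gov = 0.4, p_union = 0.5,
                        beta_gov = 1, beta_union = 1,
                        f_gov = 0.6, f_union = 0.4,
                        d = 2, b_T1 = 3, b_G2 = 1.5, I_S = 2,
                        x0_gov = 1, x0_union = 1,
                        comment = "") {
  sc <- list(rho = rho, delta = delta, l = l,
             a_gov = a_gov, a_union = a_union, c = c,
             p_gov = p_gov, p_union = p_union,
             beta_gov = beta_gov, beta_union = beta_union,
             f_gov = f_gov, f_union = f_union,
             d = d, b_T1 = b_T1, b_G2 = b_G2, I_S = I_S,
             x0_gov = x0_gov, x0_union = x0_union)
  for (f in .scenario_fields) {
    v <- sc[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("field '", f, "' must be a single finite number", call. = FALSE)
    sc[[f]] <- as.numeric(v)
  }
  sc$comment <- as.character(comment)[1L]
  structure(sc, class = "mh_scenario")
}

#' Baseline scenario of the published numerical study
#'
#' Returns the parameter values used in the study's numerical section:
#' discount rate 0.9, reputation decay 0.1, reputation weight 1, government
#' gain 1.5, union gain 2, screening dissatisfaction 0.6 (government) and
#' 0.4 (union), screening probabilities 0.4 and 0.5, information difficulty
#' 2, training resistance 2, training contribution 3, sabotage loss 1.5,
#' and initial reputation 1 for both actors.  Reputation-per-effort (beta)
#' and the cost coefficient are supplied by the caller because the study
#' varies beta in {1, 2} and plots benefits against the cost.
#'
#' @param beta_gov,beta_union reputation gained per unit effort.
#' @param c unit effort-cost coefficient.
#' @return An `mh_scenario`.
#' @export
#' @examples
#' baseline_scenario()$delta  # 0.1
baseline_scenario <- function(beta_gov = 1, beta_union = 1, c = 1) {
  mh_scenario(beta_gov = beta_gov, beta_union = beta_union, c = c,
              comment = "baseline numerical-study scenario")
}

#' Update fields of a scenario
#'
#' @param params an `mh_scenario`.
#' @param ... named scalar replacements for scenario fields.
#' @return The updated `mh_scenario`.
#' @export
scenario_update <- function(params, ...) {
  stopifnot(inherits(params, "mh_scenario"))
  upd <- list(...)
  if (length(upd) == 0L) return(params)
  bad <- setdiff(names(upd), c(.scenario_fields, "comment"))
  if (length(bad))
    stop("unknown scenario field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  args <- unclass(params)
  args[names(upd)] <- upd
  do.call(mh_scenario, args)
}

# Constraint table: field -> c(lower bound, upper bound, lower open?, upper open?)
# NA bound means unconstrained on that side.  rho is required strictly
# positive even though the original formulation allows 0, because every
# value function carries a 1/rho factor.
.scenario_constraints <- list(
  rho        = list(lo = 0, hi = 1, lo_open = TRUE,  hi_open = FALSE, txt = "0 < rho <= 1"),
  delta      = list(lo = 0, hi = NA, lo_open = TRUE, hi_open = NA,    txt = "delta > 0"),
  l          = list(lo = 0, hi = NA, lo_open = TRUE, hi_open = NA,    txt = "l > 0"),
  a_gov      = list(lo = 0, hi = NA, lo_open = TRUE, hi_open = NA,    txt = "a_gov > 0"),
  a_union    = list(lo = 0, hi = NA, lo_open = TRUE, hi_open = NA,    txt = "a_union > 0"),
  c          = list(lo = 0, hi = NA, lo_open = TRUE, hi_open = NA,    txt = "c > 0"),
  p_gov      = list(lo = 0, hi = 1, lo_open = TRUE,  hi_open = FALSE, txt = "0 < p_gov <= 1"),
  p_union    = list(lo = 0, hi = 1, lo_open = TRUE,  hi_open = FALSE, txt = "0 < p_union <= 1"),
  beta_gov   = list(lo = 0, hi = NA, lo_open = TRUE, hi_open = NA,    txt = "beta_gov > 0"),
  beta_union = list(lo = 0, hi = NA, lo_open = TRUE, hi_open = NA,    txt = "beta_union > 0"),
  f_gov      = list(lo = 0, hi = NA, lo_open = TRUE, hi_open = NA,    txt = "f_gov > 0"),
  f_union    = list(lo = 0, hi = NA, lo_open = TRUE, hi_open = NA,    txt = "f_union > 0"),
  d          = list(lo = 0, hi = NA, lo_open = TRUE, hi_open = NA,    txt = "d > 0"),
  b_T1       = list(lo = 0, hi = NA, lo_open = TRUE, hi_open = NA,    txt = "b_T1 > 0"),
  b_G2       = list(lo = 0, hi = NA, lo_open = TRUE, hi_open = NA,    txt = "b_G2 > 0"),
  I_S        = list(lo = 0, hi = NA, lo_open = TRUE, hi_open = NA,    txt = "I_S > 0")
)

#' Validate a scenario against the model's sign and range constraints
#'
#' Checks every parameter constraint of the model (strict positivity for
#' rates, gains, costs and frictions; probabilities and the discount rate in
#' (0, 1]).  Initial reputations are unconstrained.  When all hard
#' constraints hold, the function additionally inspects the six
#' (mode, actor) problems and records a non-fatal `"boundary"` row for any
#' problem whose closed-form equilibrium effort is not strictly positive
#' (i.e. the interior solution fails and the feasible optimum is zero
#' effort).
#'
#' Validation never throws: all findings are returned as rows.
#'
#' @param params an `mh_scenario`.
#' @return A data frame with columns `field`, `constraint`, `value` and
#'   `severity` (`"violation"` for a hard constraint, `"boundary"` for a
#'   non-interior equilibrium).  Zero rows means the scenario is valid and
#'   every problem has an interior equilibrium.
#' @export
#' @examples
#' nrow(validate_scenario(baseline_scenario()))  # 0
validate_scenario <- function(params) {
  stopifnot(inherits(params, "mh_scenario"))
  rows <- list()
  for (f in names(.scenario_constraints)) {
    cn <- .scenario_constraints[[f]]
    v <- params[[f]]
    ok <- TRUE
    if (!is.na(cn$lo)) ok <- ok && (if (cn$lo_open) v > cn$lo else v >= cn$lo)
    if (!is.na(cn$hi)) ok <- ok && (if (isTRUE(cn$hi_open)) v < cn$hi else v <= cn$hi)
    if (!ok)
      rows[[length(rows) + 1L]] <- data.frame(
        field = f, constraint = cn$txt, value = v,
        severity = "violation", stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) {
    for (mode in mh_modes()) {
      for (actor in mh_actors()) {
        lq <- reduce_to_canonical(mode, actor, params)
        gain <- lq$m + shadow_price(params) * lq$k
        if (gain <= 0)
          rows[[length(rows) + 1L]] <- data.frame(
            field = paste(mode, actor, sep = "/"),
            constraint = sprintf(
              "interior equilibrium requires m + A*k > 0 (got %.6g)", gain),
            value = gain, severity = "boundary", stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L)
    return(data.frame(field = character(), constraint = character(),
                      value = numeric(), severity = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Default sampling ranges for random scenarios
#'
#' Uniform sampling intervals per field, chosen to bracket the baseline
#' study values while respecting the model constraints: rho in [0.1, 1],
#' delta in (0, 1], l in (0, 3], gains and the cost coefficient in (0, 5],
#' probabilities in (0, 1], and all remaining positive parameters (betas,
#' frictions, contributions, information difficulty, initial reputations)
#' in (0, 4].
#'
#' @return A named list of length-2 numeric vectors `c(lower, upper)`.
#' @export
default_scenario_ranges <- function() {
  list(
    rho = c(0.1, 1), delta = c(0, 1), l = c(0, 3),
    a_gov = c(0, 5), a_union = c(0, 5), c = c(0, 5),
    p_gov = c(0, 1), p_union = c(0, 1),
    beta_gov = c(0, 4), beta_union = c(0, 4),
    f_gov = c(0, 4), f_union = c(0, 4),
    d = c(0, 4), b_T1 = c(0, 4), b_G2 = c(0, 4), I_S = c(0, 4),
    x0_gov = c(0, 4), x0_union = c(0, 4)
  )
}

.check_ranges <- function(ranges) {
  for (f in .scenario_fields) {
    r <- ranges[[f]]
    if (is.null(r) || length(r) != 2L || !all(is.finite(r)) || r[1] > r[2])
      stop("range for field '", f, "' must be a finite c(lower, upper)",
           call. = FALSE)
    cn <- .scenario_constraints[[f]]
    if (is.null(cn)) next
    if (!is.na(cn$lo) && r[1] < cn$lo)
      stop("range for field '", f, "' violates the model constraint ",
           cn$txt, call. = FALSE)
    if (!is.na(cn$hi) && r[2] > cn$hi)
      stop("range for field '", f, "' violates the model constraint ",
           cn$txt, call. = FALSE)
  }
  invisible(TRUE)
}

#' Draw random scenarios reproducibly
#'
#' Samples each parameter independently and uniformly within its range, in
#' the fixed canonical field order (`rho, delta, l, a_gov, a_union, c,
#' p_gov, p_union, beta_gov, beta_union, f_gov, f_union, d, b_T1, b_G2,
#' I_S, x0_gov, x0_union`), so that identical `(seed, n, ranges)` always
#' reproduce identical output.  The caller's RNG state is left untouched.
#'
#' With `require_interior = TRUE`, candidate draws are rejected until every
#' one of the six (mode, actor) problems has a strictly positive
#' equilibrium effort, i.e. `m + A*k > 0` in canonical form.
#'
#' @param seed integer seed.
#' @param n number of scenarios (>= 1).
#' @param ranges named list of `c(lower, upper)` intervals; defaults to
#'   [default_scenario_ranges()].  Ranges must respect the model's sign
#'   constraints.
#' @param require_interior reject scenarios with any non-interior problem.
#' @param max_tries rejection-sampling cap (per accepted scenario on
#'   average); exceeded only for ranges that make interior solutions rare.
#' @return A list of `n` `mh_scenario` objects.
#' @export
#' @examples
#' s <- sample_scenarios(seed = 7, n = 2)
#' identical(s, sample_scenarios(seed = 7, n = 2))  # TRUE
sample_scenarios <- function(seed, n, ranges = default_scenario_ranges(),
                             require_interior = FALSE, max_tries = 1000L) {
  stopifnot(length(n) == 1L, n >= 1)
  .check_ranges(ranges)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  out <- vector("list", n)
  tries <- 0L
  i <- 1L
  while (i <= n) {
    tries <- tries + 1L
    if (tries > max_tries * n)
      stop("rejection sampling failed: interior scenarios too rare ",
           "under the given ranges", call. = FALSE)
    vals <- lapply(.scenario_fields, function(f) {
      r <- ranges[[f]]
      stats::runif(1L, r[1], r[2])
    })
    names(vals) <- .scenario_fields
    sc <- do.call(mh_scenario, c(vals, list(comment = "sampled scenario")))
    viol <- validate_scenario(sc)
    if (any(viol$severity == "violation")) next
    if (require_interior) {
      A <- shadow_price(sc)
      interior <- all(vapply(mh_modes(), function(mode)
        all(vapply(mh_actors(), function(actor) {
          lq <- reduce_to_canonical(mode, actor, sc)
          lq$m + A * lq$k > 0
        }, logical(1))), logical(1)))
      if (!interior) next
    }
    out[[i]] <- sc
    i <- i + 1L
  }
  out
}

#' @export
print.mh_scenario <- function(x, ...) {
  cat("Mental-health game scenario\n")
  vals <- unlist(x[.scenario_fields])
  cat(paste0("  ", format(names(vals), width = 10), " = ",
             format(vals, digits = 6), collapse = "\n"), "\n")
  if (nzchar(x$comment)) cat("  comment:", x$comment, "\n")
  invisible(x)
}

#' Write a scenario to disk
#'
#' Canonical JSON: sorted keys, full precision, one scalar per field.
#'
#' @param params an `mh_scenario`.
#' @param path output path (`.json`).
#' @return `path`, invisibly.
#' @export
write_scenario <- function(params, path) {
  stopifnot(inherits(params, "mh_scenario"))
  rec <- unclass(params)
  rec <- rec[order(names(rec))]
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a scenario from JSON or YAML
#'
#' The format is chosen by file extension (`.json`, `.yaml`/`.yml`).  The
#' record must be a flat key/value map using the canonical field names;
#' missing fields fall back to the constructor defaults.
#'
#' @param path input path.
#' @return An `mh_scenario`.
#' @export
read_scenario <- function(path) {
  ext <- tolower(tools::file_ext(path))
  rec <- switch(ext,
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    yaml = ,
    yml  = yaml::read_yaml(path),
    stop("unrecognised scenario file extension: '", ext,
         "' (expected json, yaml or yml)", call. = FALSE))
  if (!is.list(rec)) rec <- as.list(rec)
  known <- intersect(names(rec), c(.scenario_fields, "comment"))
  do.call(mh_scenario, rec[known])
}
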