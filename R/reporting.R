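# Reporting: deterministic end-to-end reproduction of the numerical study
# (figures, tables, conclusion checks) and a thin command-line interface.

.fmt6 <- function(x) signif(x, 6)

.write_csv6 <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], .fmt6)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

.plot_benefit_figure <- function(curves, actor, beta, path, overlay = NULL) {
  sub <- curves[curves$actor == actor & curves$beta == beta, ]
  grDevices::png(path, width = 800, height = 600)
  on.exit(grDevices::dev.off())
  cols <- c(screening = "steelblue", security = "darkorange", training = "forestgreen")
  ylim <- range(sub$V)
  if (!is.null(overlay)) ylim <- range(ylim, overlay$V)
  graphics::plot(NA, xlim = range(sub$c), ylim = ylim, log = "x",
                 xlab = "effort cost coefficient c",
                 ylab = "equilibrium value V",
                 main = sprintf("%s benefits vs cost (beta = %g)", actor, beta))
  for (m in mh_modes()) {
    s <- sub[sub$mode == m, ]
    graphics::lines(s$c, s$V, col = cols[m], lwd = 2)
    if (!is.null(overlay)) {
      o <- overlay[overlay$mode == m, ]
      graphics::lines(o$c, o$V, col = cols[m], lwd = 1, lty = 3)
    }
  }
  leg <- mh_modes()
  if (!is.null(overlay)) leg <- c(leg, "dotted: reported coefficients")
  graphics::legend("topright", legend = leg,
                   col = c(cols, if (!is.null(overlay)) "grey30"),
                   lwd = c(2, 2, 2, if (!is.null(overlay)) 1),
                   lty = c(1, 1, 1, if (!is.null(overlay)) 3), bty = "n")
  invisible(path)
}

#' Reproduce the numerical mode-comparison study
#'
#' Runs the full deterministic pipeline at the given scenario: four
#' benefit-versus-cost figures (government and union, each at the low and
#' high reputation-gain value), the equilibrium table for all six
#' (mode, actor) problems at both beta values, the coefficient-audit
#' table, and the conclusion-check report, all derived from the
#' closed-form equilibria.  Figures are drawn from the derived closed
#' forms; with `paper_printed = TRUE` the originally reported coefficients
#' are overlaid as dotted reference curves.
#'
#' All CSV/JSON outputs are deterministic: re-running the pipeline on the
#' same scenario reproduces them byte for byte (the manifest's timestamp
#' field aside).
#'
#' @param output_dir writable output directory (created if missing).
#' @param params an `mh_scenario`.
#' @param beta_values reputation-gain sweep values.
#' @param c_grid cost grid for curves and figures (default 200 log-spaced
#'   points on `[0.25, 10]`).
#' @param paper_printed overlay the originally reported coefficients on
#'   the figures as dotted reference curves.
#' @return A run manifest (list): scenario, options, artifact file list,
#'   package version, timestamp.  Written to `manifest.json` as well.
#' @export
reproduce_study <- function(output_dir,
                            params = baseline_scenario(),
                            beta_values = c(1, 2),
                            c_grid = exp(seq(log(0.25), log(10),
                                             length.out = 200)),
                            paper_printed = FALSE) {
  if (!dir.exists(output_dir) &&
      !dir.create(output_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", output_dir, call. = FALSE)
  report <- check_conclusions(params, beta_values, c_grid)
  artifacts <- character()

  # (i) figures
  A <- shadow_price(params)
  for (actor in mh_actors()) {
    x0 <- if (actor == "government") params$x0_gov else params$x0_union
    for (b in beta_values) {
      f <- file.path(output_dir, sprintf("benefits_%s_beta%g.png", actor, b))
      overlay <- NULL
      if (paper_printed) {
        rep_tab <- reported_benefit_coefficients()
        rt <- rep_tab[rep_tab$actor == actor & rep_tab$beta == b, ]
        if (nrow(rt)) {
          overlay <- do.call(rbind, lapply(seq_len(nrow(rt)), function(i)
            data.frame(mode = rt$mode[i], c = c_grid,
                       V = A * x0 + rt$reported[i] / c_grid)))
        }
      }
      .plot_benefit_figure(report$curves, actor, b, f, overlay)
      artifacts <- c(artifacts, f)
    }
  }

  # (ii) equilibrium table, all six problems at both beta values
  eq_rows <- do.call(rbind, lapply(beta_values, function(b) {
    do.call(rbind, lapply(mh_actors(), function(actor) {
      sc <- if (actor == "government") scenario_update(params, beta_gov = b)
            else scenario_update(params, beta_union = b)
      do.call(rbind, lapply(mh_modes(), function(m) {
        eq <- mh_equilibrium(m, actor, sc)
        data.frame(actor = actor, mode = m, beta = b, c = sc$c,
                   F_star = eq$F_star, A = eq$A, premium = eq$premium,
                   V = eq$V_at_x0, interior = eq$interior)
      }))
    }))
  }))
  f_eq <- file.path(output_dir, "equilibria.csv")
  .write_csv6(eq_rows, f_eq)

  # (iii) coefficient audit; (iv) conclusion report; curves
  f_audit <- file.path(output_dir, "coefficient_audit.csv")
  .write_csv6(report$audit, f_audit)
  f_curves <- file.path(output_dir, "benefit_curves.csv")
  .write_csv6(report$curves, f_curves)
  f_concl <- file.path(output_dir, "conclusions.json")
  jsonlite::write_json(report$conclusions, f_concl, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  artifacts <- c(artifacts, f_eq, f_audit, f_curves, f_concl)

  manifest <- list(
    scenario = unclass(params)[order(names(unclass(params)))],
    options = list(beta_values = beta_values,
                   c_grid = c(min(c_grid), max(c_grid), length(c_grid)),
                   paper_printed = paper_printed),
    artifacts = basename(artifacts),
    package_version = as.character(utils::packageVersion("mhgame")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  f_man <- file.path(output_dir, "manifest.json")
  jsonlite::write_json(manifest, f_man, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(manifest)
}

# --- minimal flag parser: --key value pairs after the subcommand ----------

.parse_flags <- function(args) {
  flags <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[[i]]
    if (!startsWith(a, "--"))
      stop("unexpected argument: ", a, call. = FALSE)
    key <- sub("^--", "", a)
    if (i == length(args) || startsWith(args[[i + 1L]], "--")) {
      flags[[key]] <- TRUE
      i <- i + 1L
    } else {
      flags[[key]] <- args[[i + 1L]]
      i <- i + 2L
    }
  }
  flags
}

.flag_num <- function(flags, key, default = NULL) {
  if (is.null(flags[[key]])) return(default)
  as.numeric(flags[[key]])
}

.cli_scenario <- function(flags) {
  sc <- if (!is.null(flags$scenario)) read_scenario(flags$scenario)
        else baseline_scenario()
  overrides <- list()
  for (f in .scenario_fields)
    if (!is.null(flags[[f]])) overrides[[f]] <- as.numeric(flags[[f]])
  if (!is.null(flags$beta)) {
    overrides$beta_gov <- as.numeric(flags$beta)
    overrides$beta_union <- as.numeric(flags$beta)
  }
  if (length(overrides)) sc <- do.call(scenario_update, c(list(sc), overrides))
  sc
}

#' Command-line interface
#'
#' Thin dispatcher used by the `mhgame` script in `inst/cli/`.
#' Subcommands:
#' \describe{
#'   \item{solve}{`--mode --actor [--scenario file] [--beta v] [--c v]
#'     [--x0 v] [--out file]` — closed-form equilibrium as JSON.}
#'   \item{simulate}{as `solve`, plus `--T --step --out file` — trajectory
#'     CSV under the equilibrium effort.}
#'   \item{compare}{`--actor [--beta v] [--c-min v] [--c-max v] [--n v]
#'     [--out file]` — benefit curves CSV plus the mode ordering.}
#'   \item{verify}{`--seed s [--n-scenarios n]` — oracle-equivalence and
#'     HJB-residual property checks on random interior scenarios.}
#'   \item{reproduce}{`--out dir [--paper-printed]` — the full study
#'     pipeline via [reproduce_study()].}
#' }
#' Scenario constraint violations exit non-zero with a message naming the
#' violated constraint.
#'
#' @param args character vector of command-line arguments
#'   (default `commandArgs(trailingOnly = TRUE)`).
#' @return Exit status, invisibly (0 on success).
#' @export
mh_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    if (length(args) == 0L)
      stop("usage: mhgame <solve|simulate|compare|verify|reproduce> [--flags]",
           call. = FALSE)
    cmd <- args[[1L]]
    flags <- .parse_flags(args[-1L])
    switch(cmd,
      solve = .cli_solve(flags),
      simulate = .cli_simulate(flags),
      compare = .cli_compare(flags),
      verify = .cli_verify(flags),
      reproduce = .cli_reproduce(flags),
      stop("unknown subcommand: '", cmd, "'", call. = FALSE))
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

.cli_solve <- function(flags) {
  sc <- .cli_scenario(flags)
  mode <- .match_mode(flags$mode)
  actor <- .match_actor(flags$actor)
  eq <- mh_equilibrium(mode, actor, sc, x0 = .flag_num(flags, "x0"))
  message(sprintf("scenario: rho=%g delta=%g l=%g; canonical m=%.6g C=%.6g k=%.6g",
                  sc$rho, sc$delta, sc$l, eq$lq$m, eq$lq$C, eq$lq$k))
  out <- list(mode = mode, actor = actor, x0 = eq$x0,
              F_star = eq$F_star, A = eq$A, premium = eq$premium,
              V = eq$V_at_x0, interior = eq$interior)
  json <- jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(flags$out)) writeLines(json, flags$out) else cat(json, "\n")
  if (!eq$interior)
    message("warning: non-interior equilibrium; feasible optimum is F = 0 ",
            sprintf("with value %.6g",
                    constant_control_value(eq$lq, 0, eq$x0)))
  invisible(eq)
}

.cli_simulate <- function(flags) {
  sc <- .cli_scenario(flags)
  mode <- .match_mode(flags$mode)
  actor <- .match_actor(flags$actor)
  eq <- mh_equilibrium(mode, actor, sc, x0 = .flag_num(flags, "x0"))
  tr <- simulate(eq, T = .flag_num(flags, "T", 40),
                 step = .flag_num(flags, "step", 0.05))
  path <- if (!is.null(flags$out)) flags$out else "trajectory.csv"
  write_trajectory(tr, path)
  message("trajectory written to ", path)
  invisible(tr)
}

.cli_compare <- function(flags) {
  sc <- .cli_scenario(flags)
  actor <- .match_actor(flags$actor)
  c_grid <- exp(seq(log(.flag_num(flags, "c-min", 0.25)),
                    log(.flag_num(flags, "c-max", 10)),
                    length.out = .flag_num(flags, "n", 200)))
  curves <- do.call(rbind, lapply(mh_modes(), function(m)
    benefit_curve(m, actor, sc, c_grid)))
  path <- if (!is.null(flags$out)) flags$out else "benefit_curves.csv"
  .write_csv6(curves, path)
  ord <- mode_ordering(actor, sc)
  message("mode ordering at c = ", sc$c, ": ",
          paste(ord$mode, collapse = " > "))
  message("curves written to ", path)
  invisible(curves)
}

.cli_verify <- function(flags) {
  if (is.null(flags$seed)) stop("--seed is required", call. = FALSE)
  n <- as.integer(.flag_num(flags, "n-scenarios", 50))
  scs <- sample_scenarios(seed = as.integer(flags$seed), n = n,
                          require_interior = TRUE)
  worst_F <- worst_V <- worst_res <- 0
  for (sc in scs) {
    for (mode in mh_modes()) for (actor in mh_actors()) {
      lq <- reduce_to_canonical(mode, actor, sc)
      eq <- solve_closed_form(lq, x0 = 1)
      bf <- brute_force_best_constant(lq, x0 = 1)
      worst_F <- max(worst_F, abs(bf$F_grid_best - eq$F_star))
      worst_V <- max(worst_V, abs(bf$value_best - eq$V_at_x0))
      worst_res <- max(worst_res, hjb_residual(lq, eq))
    }
  }
  message(sprintf(
    "verified %d scenarios x 6 problems: max |F_grid - F*| = %.3g, max |V_bf - V| = %.3g, max HJB residual = %.3g",
    length(scs), worst_F, worst_V, worst_res))
  invisible(list(worst_F = worst_F, worst_V = worst_V, worst_res = worst_res))
}

.cli_reproduce <- function(flags) {
  out <- if (!is.null(flags$out)) flags$out else "study_output"
  man <- reproduce_study(out, params = .cli_scenario(flags),
                         paper_printed = isTRUE(flags[["paper-printed"]]))
  message("artifacts written to ", out, ": ",
          paste(man$artifacts, collapse = ", "))
  invisible(man)
}
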