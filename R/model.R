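# markov_cua(): the package's central fitting function.  Calibrates the
# exponential baseline hazards to the comparator life-year target,
# optionally calibrates per-arm cost scales to the published lifetime
# cost totals, runs both arms through the cohort engine and returns a
# classed object with the incremental comparison.

#' Fit the cost-utility Markov model
#'
#' Calibrates baseline monthly hazards so that the comparator (KRd) arm
#' reproduces its target undiscounted restricted life-years, derives
#' the intervention (DRd) arm through hazard-ratio transforms, runs the
#' monthly-cycle cohort model over the horizon and computes the
#' incremental cost-utility comparison at the configured
#' willingness-to-pay threshold.
#'
#' When `costs$calibrate_to_totals` is `TRUE` in the configuration, the
#' per-arm cost scale factors are solved (exactly, by linearity) so
#' that each arm's discounted lifetime cost equals its configured
#' target; otherwise the configured `cost_scale` values are used as-is.
#'
#' @param config A [load_config()] result, or a path to a YAML
#'   configuration; defaults to the shipped base case.
#' @param values Optional named numeric vector overriding parameter
#'   base-case values (used by the sensitivity machinery).
#' @param base Optional pre-calibrated [baseline_hazards()]; when
#'   supplied, calibration is skipped (sensitivity analyses re-use the
#'   base-case calibration).
#' @param cost_scale Optional named numeric vector of per-arm cost
#'   scales overriding the configured/calibrated ones.
#' @return An object of class `markov_cua` with elements `config`,
#'   `settings`, `values`, `baseline`, `arms` (named list of
#'   `arm_result`), `comparison` (a `cea_comparison`), `cost_scale`,
#'   and `intervention`/`comparator` arm names.
#' @examples
#' fit <- markov_cua()
#' fit
#' summary(fit)
#' @export
markov_cua <- function(config = load_config(), values = NULL,
                       base = NULL, cost_scale = NULL) {
  if (is.character(config)) config <- load_config(config)
  stopifnot(inherits(config, "cea_config"))
  settings <- config$settings
  vals <- param_means(config$params)
  if (!is.null(values)) vals[names(values)] <- values

  cal <- config$calibration
  hr_pfs_on_death <- isTRUE(cal$apply_hr_pfs_to_death)
  if (is.null(base))
    base <- calibrate_baseline(
      cal$target_ly_krd, settings,
      median_ttp_months = cal$median_ttp_months,
      pd_mortality_ratio = cal$pd_mortality_ratio,
      bracket = as.numeric(cal$bracket %||% c(1e-6, 5)))

  # comparator is the arm without hazard ratios (carries the baseline)
  is_base <- vapply(config$arms, function(a)
    is.null(a$hr_pfs) && is.null(a$hr_os), logical(1))
  if (sum(is_base) != 1)
    config_error("exactly one arm must carry the baseline (no hazard ratios)")
  comparator <- names(config$arms)[is_base]
  intervention <- names(config$arms)[!is_base][1]

  scales <- unlist(config$costs$cost_scale[names(config$arms)])
  if (is.null(scales)) scales <- stats::setNames(
    rep(1, length(config$arms)), names(config$arms))
  if (isTRUE(config$costs$calibrate_to_totals) && is.null(cost_scale)) {
    targets <- config$costs$total_cost_targets
    for (nm in names(config$arms)) {
      if (is.null(targets[[nm]])) next
      unscaled <- run_arm(config$arms[[nm]], base, vals, settings,
                          config$costs, cost_scale = 1,
                          hr_pfs_on_death = hr_pfs_on_death)$total_cost
      if (unscaled <= 0)
        calibration_error("arm '%s': cannot scale zero cost to target", nm)
      scales[nm] <- targets[[nm]] / unscaled
    }
  }
  if (!is.null(cost_scale)) scales[names(cost_scale)] <- cost_scale

  arms <- lapply(names(config$arms), function(nm)
    run_arm(config$arms[[nm]], base, vals, settings, config$costs,
            cost_scale = scales[[nm]],
            hr_pfs_on_death = hr_pfs_on_death))
  names(arms) <- names(config$arms)

  structure(
    list(config = config, settings = settings, values = vals,
         baseline = base, arms = arms,
         comparison = cea_compare(arms[[intervention]],
                                  arms[[comparator]],
                                  settings$wtp_per_qaly),
         cost_scale = scales,
         intervention = intervention, comparator = comparator),
    class = "markov_cua")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.markov_cua <- function(x, ...) {
  cat("Markov cohort cost-utility model (3 states: PFS, PD, Death)\n")
  cat(sprintf("  horizon: %d monthly cycles; WTP $%g/QALY\n",
              x$settings$horizon_cycles, x$settings$wtp_per_qaly))
  for (a in x$arms)
    cat(sprintf("  %-40s cost $%8.0f  QALY %6.3f  LY %6.3f\n",
                a$label, a$total_cost, a$total_qaly, a$total_ly))
  cmp <- x$comparison
  cat(sprintf("  incremental: cost $%.0f, QALY %.3f, LY %.3f",
              cmp$delta_cost, cmp$delta_qaly, cmp$delta_ly))
  if (!cmp$ratio_undefined)
    cat(sprintf("; ICUR $%.0f/QALY", cmp$icur))
  cat("\n")
  invisible(x)
}

#' Summarise a fitted cost-utility model
#'
#' @param object A `markov_cua` fit.
#' @param ... Unused.
#' @return A `summary.markov_cua`: the base-case results table (see
#'   [cea_table()]) plus calibration details.
#' @export
summary.markov_cua <- function(object, ...) {
  tab <- cea_table(object$comparison,
                   object$arms[[object$intervention]],
                   object$arms[[object$comparator]])
  structure(list(table = tab, baseline = object$baseline,
                 cost_scale = object$cost_scale,
                 achieved_ly = attr(object$baseline, "achieved_ly"),
                 wtp = object$settings$wtp_per_qaly),
            class = "summary.markov_cua")
}

#' @export
print.summary.markov_cua <- function(x, ...) {
  cat("Base-case cost-utility results\n")
  print(x$table, row.names = FALSE, digits = 6)
  cat(sprintf("\nCalibrated baseline hazards (per month): progression %.5f, death PFS %.5f, death PD %.5f\n",
              x$baseline$r_progress, x$baseline$r_die_pfs,
              x$baseline$r_die_pd))
  if (!is.null(x$achieved_ly))
    cat(sprintf("Comparator restricted life-years achieved: %.6f\n",
                x$achieved_ly))
  cat(sprintf("Cost scale factors: %s\n",
              paste(sprintf("%s = %.4f", names(x$cost_scale),
                            x$cost_scale), collapse = ", ")))
  invisible(x)
}

#' @export
coef.markov_cua <- function(object, ...) {
  b <- object$baseline
  out <- c(r_progress = b$r_progress, r_die_pfs = b$r_die_pfs,
           r_die_pd = b$r_die_pd)
  iv <- object$config$arms[[object$intervention]]
  if (!is.null(iv$hr_pfs)) out["hr_pfs"] <- object$values[[iv$hr_pfs]]
  if (!is.null(iv$hr_os)) out["hr_os"] <- object$values[[iv$hr_os]]
  out
}

#' Plot state occupancy over time for a fitted model
#'
#' @param x A `markov_cua` fit.
#' @param ... Passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.markov_cua <- function(x, ...) {
  old <- graphics::par(mfrow = c(1, length(x$arms)))
  on.exit(graphics::par(old))
  for (a in x$arms) {
    graphics::matplot(
      0:(nrow(a$occupancy) - 1), a$occupancy, type = "l", lty = 1,
      col = c("forestgreen", "orange", "grey30"),
      xlab = "cycle (months)", ylab = "state occupancy",
      main = a$label, ylim = c(0, 1), ...)
    graphics::legend("right", legend = colnames(a$occupancy), lty = 1,
                     col = c("forestgreen", "orange", "grey30"),
                     bty = "n")
  }
  invisible(x)
}

#' Probabilistic draws from a fitted model
#'
#' `simulate()` on a `markov_cua` runs the probabilistic sensitivity
#' analysis: `nsim` parameter draws, each re-run through the
#' deterministic pipeline.  See [run_psa()] for details.
#'
#' @param object A `markov_cua` fit.
#' @param nsim Number of draws.
#' @param seed Integer seed.
#' @param ... Passed to [run_psa()].
#' @return A `psa_result` data frame.
#' @export
simulate.markov_cua <- function(object, nsim = 1000,
                                seed = object$config$psa$seed, ...) {
  run_psa(object, n = nsim, seed = seed, ...)
}
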