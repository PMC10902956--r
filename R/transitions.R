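# Transition structure: three ordered states (PFS, PD, Death), monthly
# cycles, constant (exponential) cause-specific baseline hazards.
# The comparator arm carries the baseline; the intervention arm scales
# the cause-specific hazards by its hazard ratios.

.states <- c("PFS", "PD", "Death")

domain_error <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("rrmmcea_domain_error", "rrmmcea_error")))
}

calibration_error <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("rrmmcea_calibration_error", "rrmmcea_error")))
}

#' Convert a hazard rate to a per-cycle probability
#'
#' `1 - exp(-rate * dt)` under a constant hazard.
#'
#' @param rate Nonnegative hazard per month.
#' @param dt Cycle length in months.
#' @return Transition probability in `[0, 1]`.
#' @seealso [prob_to_rate()] for the inverse.
#' @export
rate_to_prob <- function(rate, dt = 1) {
  if (any(rate < 0)) domain_error("rate_to_prob: negative rate")
  if (any(dt <= 0)) domain_error("rate_to_prob: dt must be positive")
  1 - exp(-rate * dt)
}

#' Convert a per-cycle probability to a hazard rate
#' @param p Probability in `[0, 1)`.
#' @param dt Cycle length in months.
#' @return Hazard per month; round-trips with [rate_to_prob()].
#' @export
prob_to_rate <- function(p, dt = 1) {
  if (any(p < 0 | p >= 1)) domain_error("prob_to_rate: p must lie in [0, 1)")
  -log(1 - p) / dt
}

#' Apply a hazard ratio to a per-cycle probability
#'
#' Hazard-scale multiplication under a piecewise-exponential assumption:
#' `1 - (1 - p)^hr`.  `hr = 1` is the identity.
#'
#' @param p Per-cycle probability in `[0, 1)` (`p = 1` only with
#'   `hr = 1`).
#' @param hr Positive hazard ratio.
#' @return Transformed probability.
#' @examples
#' apply_hazard_ratio(0.1, 0.6)  # 1 - 0.9^0.6
#' @export
apply_hazard_ratio <- function(p, hr) {
  if (any(hr <= 0)) domain_error("apply_hazard_ratio: hr must be positive")
  if (any(p < 0 | p > 1)) domain_error("apply_hazard_ratio: p outside [0, 1]")
  if (any(p == 1 & hr != 1))
    domain_error("apply_hazard_ratio: degenerate p = 1 with hr != 1")
  1 - (1 - p)^hr
}

#' Baseline cause-specific monthly hazards
#'
#' @param r_progress Hazard of progression (PFS to PD), per month.
#' @param r_die_pfs Hazard of death from PFS, per month.
#' @param r_die_pd Hazard of death from PD, per month.
#' @return An object of class `baseline_hazards`.
#' @export
baseline_hazards <- function(r_progress, r_die_pfs, r_die_pd) {
  h <- c(r_progress = r_progress, r_die_pfs = r_die_pfs,
         r_die_pd = r_die_pd)
  if (any(!is.finite(h)) || any(h < 0))
    validation_error("baseline hazards must be finite and nonnegative")
  structure(as.list(h), class = "baseline_hazards")
}

#' @export
print.baseline_hazards <- function(x, ...) {
  cat(sprintf(
    "<baseline_hazards> per month: progression %.5f, death (PFS) %.5f, death (PD) %.5f\n",
    x$r_progress, x$r_die_pfs, x$r_die_pd))
  invisible(x)
}

#' Per-cycle transition matrix from cause-specific hazards
#'
#' Competing risks are composed jointly from the cause-specific
#' exponential hazards: from PFS the stay probability is
#' `exp(-(r_progress + r_die_pfs) * dt)`, death takes
#' `1 - exp(-r_die_pfs * dt)` and progression the remainder, so that
#' the marginal per-cause death probability equals the single-risk
#' conversion `rate_to_prob(r_die_pfs, dt)` exactly.  Death is
#' absorbing and PD cannot return to PFS.
#'
#' @param hazards A [baseline_hazards()] (already arm-specific if
#'   hazard ratios apply).
#' @param dt Cycle length in months.
#' @return A 3x3 row-stochastic matrix over (PFS, PD, Death).
#' @export
transition_matrix <- function(hazards, dt = 1) {
  stopifnot(inherits(hazards, "baseline_hazards"))
  rp <- hazards$r_progress * dt
  rd1 <- hazards$r_die_pfs * dt
  rd2 <- hazards$r_die_pd * dt
  m <- rbind(
    c(exp(-(rp + rd1)), exp(-rd1) - exp(-(rp + rd1)), 1 - exp(-rd1)),
    c(0, exp(-rd2), 1 - exp(-rd2)),
    c(0, 0, 1))
  dimnames(m) <- list(.states, .states)
  validate_transition_matrix(m)
  m
}

validate_transition_matrix <- function(m) {
  if (!all(dim(m) == c(3, 3)))
    validation_error("transition matrix must be 3x3")
  if (any(m < 0 | m > 1))
    validation_error("transition probabilities outside [0, 1]")
  if (any(abs(rowSums(m) - 1) > 1e-12))
    validation_error("transition matrix rows must sum to 1")
  if (!all(m[3, ] == c(0, 0, 1)))
    validation_error("Death must be absorbing")
  if (m[2, 1] != 0)
    validation_error("PD cannot return to PFS")
  invisible(m)
}

#' Arm-specific hazards from the baseline and hazard ratios
#'
#' The overall-survival hazard ratio scales both cause-specific death
#' hazards; the progression hazard ratio scales PFS to PD (and, when
#' `hr_pfs_on_death` is `TRUE`, PFS to Death jointly with `hr_os`).
#'
#' @param base A [baseline_hazards()].
#' @param hr_pfs,hr_os Positive hazard ratios (1 leaves the baseline
#'   unchanged).
#' @param hr_pfs_on_death Logical; also apply `hr_pfs` to the PFS to
#'   Death hazard (strict progression-or-death interpretation).
#' @return A [baseline_hazards()] for the arm.
#' @export
arm_hazards <- function(base, hr_pfs = 1, hr_os = 1,
                        hr_pfs_on_death = FALSE) {
  stopifnot(inherits(base, "baseline_hazards"))
  if (hr_pfs <= 0 || hr_os <= 0)
    domain_error("hazard ratios must be positive")
  d1_mult <- if (isTRUE(hr_pfs_on_death)) hr_pfs * hr_os else hr_os
  baseline_hazards(base$r_progress * hr_pfs,
                   base$r_die_pfs * d1_mult,
                   base$r_die_pd * hr_os)
}

#' Transition matrices for a strategy arm over the model horizon
#'
#' With exponential baselines the matrices are time-homogeneous; the
#' sequence is returned as a `3 x 3 x horizon` array for use with
#' [run_cohort()].
#'
#' @param base A [baseline_hazards()] (comparator scale).
#' @param arm A [strategy_arm()]; its `hr_pfs`/`hr_os` parameter names
#'   are resolved in `values` (an arm with `NULL` refs uses the baseline
#'   directly).
#' @param settings A [model_settings()].
#' @param values Named numeric vector of parameter values.
#' @param hr_pfs_on_death Passed to [arm_hazards()].
#' @return A `3 x 3 x horizon_cycles` array of row-stochastic matrices.
#' @export
build_arm_matrices <- function(base, arm, settings, values = NULL,
                               hr_pfs_on_death = FALSE) {
  stopifnot(inherits(arm, "strategy_arm"),
            inherits(settings, "model_settings"))
  hrp <- if (is.null(arm$hr_pfs)) 1 else param_value(values, arm$hr_pfs)
  hro <- if (is.null(arm$hr_os)) 1 else param_value(values, arm$hr_os)
  h <- arm_hazards(base, hrp, hro, hr_pfs_on_death)
  m <- transition_matrix(h, dt = settings$cycle_length_months)
  array(m, dim = c(3, 3, settings$horizon_cycles),
        dimnames = list(.states, .states, NULL))
}

#' Calibrate baseline hazards to a restricted life-year target
#'
#' The progression hazard is fixed by the assumed median time to
#' progression (`r_progress = log(2) / median_ttp_months`) and the
#' post-progression death hazard is a fixed multiple of the
#' progression-free death hazard.  The single remaining degree of
#' freedom -- the progression-free mortality hazard -- is found by
#' root finding (on its logarithm) so that the comparator cohort's
#' undiscounted restricted life-years over the model horizon equal
#' `target_ly`.
#'
#' @param target_ly Target undiscounted restricted life-years for the
#'   baseline (comparator) arm; must lie in `(0, horizon in years)`.
#' @param settings A [model_settings()].
#' @param median_ttp_months Assumed median time to progression, months.
#' @param pd_mortality_ratio Ratio `r_die_pd / r_die_pfs`.
#' @param bracket Monthly-hazard bracket for the mortality scale.
#' @param tol Convergence tolerance on the log hazard.
#' @return A [baseline_hazards()] with attributes `achieved_ly` and
#'   `residual`.
#' @examples
#' base <- calibrate_baseline(3.52, model_settings())
#' attr(base, "achieved_ly")
#' @export
calibrate_baseline <- function(target_ly, settings,
                               median_ttp_months = 26,
                               pd_mortality_ratio = 2,
                               bracket = c(1e-6, 5), tol = 1e-10) {
  stopifnot(inherits(settings, "model_settings"))
  horizon_years <- settings$horizon_cycles *
    settings$cycle_length_months / 12
  if (target_ly <= 0 || target_ly >= horizon_years)
    calibration_error(
      "target_ly must lie in (0, %g) years, got %g", horizon_years,
      target_ly)
  rp <- log(2) / median_ttp_months
  ly_at <- function(m) {
    h <- baseline_hazards(rp, m, pd_mortality_ratio * m)
    occ <- run_cohort(array(transition_matrix(
      h, settings$cycle_length_months),
      dim = c(3, 3, settings$horizon_cycles)))
    sum(1 - occ[-1, 3]) * settings$cycle_length_months / 12
  }
  f <- function(logm) ly_at(exp(logm)) - target_ly
  flo <- f(log(bracket[1])); fhi <- f(log(bracket[2]))
  if (flo * fhi > 0)
    calibration_error(
      "life-year target %g unreachable in bracket [%g, %g] (residuals %.4g, %.4g)",
      target_ly, bracket[1], bracket[2], flo, fhi)
  root <- stats::uniroot(f, log(bracket), tol = tol)
  m <- exp(root$root)
  out <- baseline_hazards(rp, m, pd_mortality_ratio * m)
  attr(out, "achieved_ly") <- ly_at(m)
  attr(out, "residual") <- attr(out, "achieved_ly") - target_ly
  out
}
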