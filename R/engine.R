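# Markov cohort engine: state occupancy over the horizon and
# accumulation of discounted costs, QALYs and life-years.
#
# Conventions: the cohort starts fully progression-free; cycle index t
# runs 1..horizon; outcomes are valued on end-of-cycle occupancy with
# discount factor (1 + r)^(-t/12) (optionally trapezoid half-cycle
# corrected); life-years are undiscounted unless settings$discount_ly.

engine_error <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("rrmmcea_engine_error", "rrmmcea_error")))
}

#' Run the cohort through a sequence of transition matrices
#'
#' @param matrices A `3 x 3 x T` array (see [build_arm_matrices()]) or a
#'   list of `T` row-stochastic 3x3 matrices.
#' @param initial Initial distribution over (PFS, PD, Death); defaults
#'   to everyone progression-free.
#' @return A `(T + 1) x 3` occupancy matrix; row 1 is the initial
#'   distribution, row `t + 1` the occupancy after `t` cycles.
#' @examples
#' m <- transition_matrix(baseline_hazards(0.05, 0.01, 0.02))
#' occ <- run_cohort(array(m, c(3, 3, 12)))
#' @export
run_cohort <- function(matrices, initial = c(1, 0, 0)) {
  if (is.list(matrices))
    matrices <- array(unlist(matrices), dim = c(3, 3, length(matrices)))
  if (length(dim(matrices)) != 3 || any(dim(matrices)[1:2] != 3))
    engine_error("matrices must be a 3 x 3 x T array or list of 3x3 matrices")
  if (length(initial) != 3 || abs(sum(initial) - 1) > 1e-10 ||
      any(initial < 0))
    engine_error("initial must be a distribution over the 3 states")
  horizon <- dim(matrices)[3]
  occ <- matrix(0, horizon + 1, 3,
                dimnames = list(NULL, c("PFS", "PD", "Death")))
  occ[1, ] <- initial
  for (t in seq_len(horizon))
    occ[t + 1, ] <- occ[t, ] %*% matrices[, , t]
  occ
}

# Discount factors for cycles 1..T at an annual rate, end-of-cycle
# timing.  dt is the cycle length in months.
discount_factors <- function(rate_annual, horizon, dt = 1) {
  (1 + rate_annual)^(-(seq_len(horizon) * dt) / 12)
}

# End-of-cycle occupancy rows (2..T+1), trapezoid-averaged with the
# start-of-cycle rows when half-cycle correction is on.
.cycle_occupancy <- function(occ, half_cycle_correction) {
  horizon <- nrow(occ) - 1
  ends <- occ[-1, , drop = FALSE]
  if (half_cycle_correction)
    (occ[-(horizon + 1), , drop = FALSE] + ends) / 2
  else
    ends
}

#' Accumulate life-years and QALYs from a cohort trace
#'
#' Per cycle, life-years gain the alive fraction times the cycle length
#' in years; QALYs gain `occ_PFS * u_pfs + occ_PD * u_pd` minus the
#' expected adverse-event disutility `occ_PFS * p_ae * |du_ae|` while on
#' treatment, discounted at the outcome rate.  The post-progression
#' utility is the progression-free utility plus the progression
#' disutility.
#'
#' @param occ Occupancy matrix from [run_cohort()].
#' @param u_pfs Progression-free utility in `[0, 1]`.
#' @param u_pd Post-progression utility in `[0, 1]`.
#' @param p_ae Per-cycle adverse-event probability while on treatment.
#' @param du_ae Adverse-event disutility (negative or zero).
#' @param duration On-treatment cycles (adverse events apply to
#'   progression-free occupancy in cycles `1..duration`).
#' @param settings A [model_settings()].
#' @return List with `ly` (years), `qaly`, and per-cycle vectors
#'   `ly_by_cycle`, `qaly_by_cycle`.
#' @export
accumulate_outcomes <- function(occ, u_pfs, u_pd, p_ae = 0, du_ae = 0,
                                duration = 0, settings = model_settings()) {
  if (u_pfs < 0 || u_pfs > 1 || u_pd < 0 || u_pd > 1)
    validation_error("utilities must lie in [0, 1]")
  horizon <- nrow(occ) - 1
  dt_years <- settings$cycle_length_months / 12
  cyc <- .cycle_occupancy(occ, settings$half_cycle_correction)
  alive <- cyc[, 1] + cyc[, 2]
  on_trt <- as.numeric(seq_len(horizon) <= duration)
  d_out <- discount_factors(settings$discount_outcome_annual, horizon,
                            settings$cycle_length_months)
  d_ly <- if (settings$discount_ly) d_out else rep(1, horizon)
  ly_by_cycle <- alive * dt_years * d_ly
  qaly_raw <- cyc[, 1] * u_pfs + cyc[, 2] * u_pd -
    on_trt * cyc[, 1] * p_ae * abs(du_ae)
  qaly_by_cycle <- qaly_raw * dt_years * d_out
  list(ly = sum(ly_by_cycle), qaly = sum(qaly_by_cycle),
       ly_by_cycle = ly_by_cycle, qaly_by_cycle = qaly_by_cycle)
}

#' Accumulate discounted costs from a cohort trace
#'
#' Per cycle `t`: progression-free occupancy is charged the on-treatment
#' cycle cost while `t <= duration` and the supportive-care cost
#' afterwards; post-progression occupancy is charged the PD cycle cost;
#' on-treatment progression-free occupancy additionally incurs the
#' expected adverse-event episode cost `p_ae * ae_event_cost`.  All
#' terms are discounted at the cost rate and multiplied by `cost_scale`.
#'
#' @param occ Occupancy matrix from [run_cohort()].
#' @param cost_schedule A [build_cycle_costs()] result.
#' @param p_ae Per-cycle adverse-event probability while on treatment.
#' @param settings A [model_settings()].
#' @param cost_scale Arm-level multiplicative scale on every cost
#'   component.
#' @return List with `cost` (total discounted USD) and `cost_by_cycle`.
#' @export
accumulate_costs <- function(occ, cost_schedule, p_ae = 0,
                             settings = model_settings(),
                             cost_scale = 1) {
  stopifnot(inherits(cost_schedule, "cycle_cost_schedule"))
  if (cost_scale < 0)
    validation_error("cost_scale must be nonnegative")
  horizon <- nrow(occ) - 1
  duration <- length(cost_schedule$on_treatment_cost_by_cycle)
  cyc <- .cycle_occupancy(occ, settings$half_cycle_correction)
  pfs_cost <- rep(cost_schedule$post_treatment_pfs_cost_per_cycle, horizon)
  k <- min(duration, horizon)
  pfs_cost[seq_len(k)] <- cost_schedule$on_treatment_cost_by_cycle[seq_len(k)]
  on_trt <- as.numeric(seq_len(horizon) <= duration)
  d_cost <- discount_factors(settings$discount_cost_annual, horizon,
                             settings$cycle_length_months)
  per_cycle <- (cyc[, 1] * pfs_cost +
                  cyc[, 2] * cost_schedule$pd_cost_per_cycle +
                  on_trt * cyc[, 1] * p_ae * cost_schedule$ae_event_cost) *
    d_cost * cost_scale
  list(cost = sum(per_cycle), cost_by_cycle = per_cycle)
}

#' Run one strategy arm through the full pipeline
#'
#' Composes dose schedules, cycle costs, arm-specific transition
#' matrices, the cohort run and outcome/cost accumulation.
#'
#' @param arm A [strategy_arm()].
#' @param base A [baseline_hazards()] (comparator scale).
#' @param values Named numeric vector of parameter values (must contain
#'   `u_pfs`, `du_progression`, `du_ae`, the arm's adverse-event
#'   probability and every referenced unit cost).
#' @param settings A [model_settings()].
#' @param cost_cfg The `costs` block of a configuration.
#' @param cost_scale Arm-level cost scale factor.
#' @param hr_pfs_on_death Passed to [arm_hazards()].
#' @return An object of class `arm_result`: `total_cost`, `total_qaly`,
#'   `total_ly`, `trace` (a per-cycle data frame), `occupancy`, `arm`,
#'   `settings`.
#' @export
run_arm <- function(arm, base, values, settings, cost_cfg,
                    cost_scale = 1, hr_pfs_on_death = FALSE) {
  schedules <- build_dose_schedule(arm)
  costs <- build_cycle_costs(schedules, values, arm, cost_cfg)
  matrices <- build_arm_matrices(base, arm, settings, values,
                                 hr_pfs_on_death)
  occ <- run_cohort(matrices)
  p_ae <- param_value(values, arm$ae_prob)
  u_pfs <- param_value(values, "u_pfs")
  u_pd <- u_pfs + param_value(values, "du_progression")
  outc <- accumulate_outcomes(occ, u_pfs, u_pd, p_ae,
                              param_value(values, "du_ae"),
                              arm$planned_duration_cycles, settings)
  cst <- accumulate_costs(occ, costs, p_ae, settings, cost_scale)
  horizon <- settings$horizon_cycles
  trace <- data.frame(
    cycle = seq_len(horizon),
    occ_PFS = occ[-1, 1], occ_PD = occ[-1, 2], occ_Death = occ[-1, 3],
    disc_cost = cst$cost_by_cycle, disc_qaly = outc$qaly_by_cycle,
    ly = outc$ly_by_cycle)
  structure(
    list(arm = arm$name, label = arm$label,
         total_cost = cst$cost, total_qaly = outc$qaly,
         total_ly = outc$ly, trace = trace, occupancy = occ,
         settings = settings, cost_scale = cost_scale),
    class = "arm_result")
}

#' @export
print.arm_result <- function(x, ...) {
  cat(sprintf(
    "<arm_result> %s: cost $%.0f, QALY %.3f, LY %.3f (over %d cycles)\n",
    x$label, x$total_cost, x$total_qaly, x$total_ly,
    x$settings$horizon_cycles))
  invisible(x)
}
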