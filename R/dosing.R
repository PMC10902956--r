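# Dosing calendars and per-cycle cost schedules.
#
# A treatment cycle is 28 days.  Administration counts per cycle follow
# the regimens' published calendars:
#   daratumumab: once weekly in cycles 1-2, every 2 weeks in cycles 3-6,
#     every 4 weeks thereafter (through cycle 25);
#   carfilzomib: days 1, 2, 8, 9, 15, 16 in cycles 1-12 and days 1, 2,
#     15, 16 in cycles 13-18;
#   dexamethasone: days 1, 8, 15, 22 of every cycle;
#   lenalidomide: days 1-21 of every cycle.

unsupported_strategy_error <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("rrmmcea_strategy_error", "rrmmcea_error")))
}

# administrations per 28-day cycle for a named calendar
.calendar_counts <- function(calendar, duration) {
  cyc <- seq_len(duration)
  switch(calendar,
    daratumumab = ifelse(cyc <= 2, 4L, ifelse(cyc <= 6, 2L, 1L)),
    carfilzomib = ifelse(cyc <= 12, 6L, 4L),
    dexamethasone = rep(4L, duration),
    lenalidomide = rep(21L, duration),
    unsupported_strategy_error("unknown dosing calendar '%s'", calendar))
}

#' Build dose schedules for a strategy arm
#'
#' Expands each drug's administration calendar over the arm's planned
#' treatment duration.
#'
#' @param arm A [strategy_arm()].
#' @return A list of `dose_schedule` objects, one per drug, each with
#'   `drug`, `administrations_by_cycle` (length = planned duration),
#'   `units_per_administration` and `unit_cost_ref`.
#' @examples
#' cfg <- load_config()
#' sched <- build_dose_schedule(cfg$arms$drd)
#' sum(sched$daratumumab$administrations_by_cycle)  # 35
#' @export
build_dose_schedule <- function(arm) {
  stopifnot(inherits(arm, "strategy_arm"))
  if (length(arm$drugs) == 0)
    unsupported_strategy_error("arm '%s' defines no drugs", arm$name)
  dur <- arm$planned_duration_cycles
  out <- lapply(arm$drugs, function(d) {
    counts <- .calendar_counts(d$calendar, dur)
    upa <- if (is.null(d$units_per_administration)) 1 else
      d$units_per_administration
    if (upa <= 0)
      validation_error("drug '%s': units_per_administration must be > 0",
                       d$drug)
    structure(list(drug = d$drug,
                   administrations_by_cycle = counts,
                   units_per_administration = upa,
                   unit_cost_ref = d$unit_cost),
              class = "dose_schedule")
  })
  names(out) <- vapply(arm$drugs, `[[`, character(1), "drug")
  out
}

#' Per-cycle cost schedule for a strategy arm
#'
#' Combines drug acquisition costs (administrations x units x unit
#' cost), a per-cycle administration fee and routine monitoring while on
#' treatment, supportive-care monitoring after the planned treatment
#' period, a post-progression per-cycle cost, and the expected cost of
#' an adverse-event episode.  Every component is linear in the unit
#' prices.
#'
#' @param schedules Output of [build_dose_schedule()].
#' @param values Named numeric vector of parameter values (see
#'   [param_means()]).
#' @param arm The [strategy_arm()].
#' @param cost_cfg The `costs` block of a [load_config()] result.
#' @return An object of class `cycle_cost_schedule` with elements
#'   `arm`, `on_treatment_cost_by_cycle` (USD per cycle, length =
#'   planned duration), `post_treatment_pfs_cost_per_cycle`,
#'   `pd_cost_per_cycle`, `ae_event_cost` and `drug_cost_by_cycle`.
#' @export
build_cycle_costs <- function(schedules, values, arm, cost_cfg) {
  stopifnot(inherits(arm, "strategy_arm"))
  dur <- arm$planned_duration_cycles
  drug_cost <- rep(0, dur)
  for (s in schedules) {
    unit <- param_value(values, s$unit_cost_ref)
    drug_cost <- drug_cost +
      s$administrations_by_cycle * s$units_per_administration * unit
  }
  comp_sum <- function(refs) {
    if (is.null(refs) || length(refs) == 0) return(0)
    sum(vapply(refs, function(r) param_value(values, r), numeric(1)))
  }
  admin <- param_value(values, cost_cfg$administration_per_cycle)
  monitoring <- comp_sum(cost_cfg$monitoring_on_treatment)
  on_trt <- drug_cost + admin + monitoring
  out <- structure(
    list(arm = arm$name,
         on_treatment_cost_by_cycle = on_trt,
         drug_cost_by_cycle = drug_cost,
         post_treatment_pfs_cost_per_cycle = comp_sum(cost_cfg$pfs_post_treatment),
         pd_cost_per_cycle = comp_sum(cost_cfg$pd_per_cycle),
         ae_event_cost = comp_sum(cost_cfg$ae_event)),
    class = "cycle_cost_schedule")
  bad <- c(out$on_treatment_cost_by_cycle,
           out$post_treatment_pfs_cost_per_cycle,
           out$pd_cost_per_cycle, out$ae_event_cost)
  if (any(bad < 0))
    validation_error("arm '%s': negative cycle cost component", arm$name)
  out
}

#' @export
print.cycle_cost_schedule <- function(x, ...) {
  cat(sprintf(
    "<cycle_cost_schedule> %s: on-treatment $%.2f-$%.2f/cycle (%d cycles), PFS off-treatment $%.2f, PD $%.2f, AE episode $%.2f\n",
    x$arm, min(x$on_treatment_cost_by_cycle),
    max(x$on_treatment_cost_by_cycle),
    length(x$on_treatment_cost_by_cycle),
    x$post_treatment_pfs_cost_per_cycle, x$pd_cost_per_cycle,
    x$ae_event_cost))
  invisible(x)
}

#' Dose schedules as a tidy table
#'
#' @param arm A [strategy_arm()].
#' @param values Named numeric vector of parameter values.
#' @return A data frame with columns `arm`, `drug`, `cycle`,
#'   `administrations`, `cost` (administrations x units x unit cost).
#' @export
dose_schedule_table <- function(arm, values = NULL) {
  schedules <- build_dose_schedule(arm)
  do.call(rbind, lapply(schedules, function(s) {
    n <- length(s$administrations_by_cycle)
    cost <- if (is.null(values)) NA_real_ else
      s$administrations_by_cycle * s$units_per_administration *
        param_value(values, s$unit_cost_ref)
    data.frame(arm = arm$name, drug = s$drug, cycle = seq_len(n),
               administrations = s$administrations_by_cycle,
               cost = cost, row.names = NULL)
  }))
}
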