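# Dosing calendars and per-cycle cost construction.

# Independent oracle: enumerate administration days on a 28-day cycle
# grid and count them per cycle.
enumerate_days <- function(regimen, duration) {
  days <- switch(regimen,
    daratumumab = c(seq(1, 56, by = 7),                  # weekly, cycles 1-2
                    seq(57, 168, by = 14),               # q2w, cycles 3-6
                    seq(169, duration * 28, by = 28)),   # q4w thereafter
    carfilzomib = c(outer(c(1, 2, 8, 9, 15, 16), (0:11) * 28, `+`),
                    outer(c(1, 2, 15, 16), (12:(duration - 1)) * 28, `+`)),
    dexamethasone = c(outer(c(1, 8, 15, 22),
                            (seq_len(duration) - 1) * 28, `+`)),
    lenalidomide = c(outer(1:21, (seq_len(duration) - 1) * 28, `+`)))
  tabulate(ceiling(days / 28), nbins = duration)
}

test_that("daratumumab calendar gives 4/2/1 administrations per cycle, 35 total", {
  sched <- build_dose_schedule(default_cfg()$arms$drd)
  counts <- sched$daratumumab$administrations_by_cycle
  expect_length(counts, 25)
  expect_equal(counts, enumerate_days("daratumumab", 25))
  expect_equal(counts[1:2], c(4, 4))
  expect_equal(counts[3:6], rep(2, 4))
  expect_equal(counts[7:25], rep(1, 19))
  expect_equal(sum(counts), 35)
})

test_that("carfilzomib calendar gives 6 then 4 administrations per cycle, 96 total", {
  sched <- build_dose_schedule(default_cfg()$arms$krd)
  counts <- sched$carfilzomib$administrations_by_cycle
  expect_length(counts, 18)
  expect_equal(counts, enumerate_days("carfilzomib", 18))
  expect_equal(sum(counts), 72 + 24)
})

test_that("dexamethasone and lenalidomide run 4 and 21 administrations every cycle in both arms", {
  cfg <- default_cfg()
  for (arm in cfg$arms) {
    sched <- build_dose_schedule(arm)
    dur <- arm$planned_duration_cycles
    expect_equal(sched$dexamethasone$administrations_by_cycle,
                 enumerate_days("dexamethasone", dur))
    expect_equal(sched$lenalidomide$administrations_by_cycle,
                 rep(21, dur))
  }
})

test_that("unknown calendars and empty arms are rejected", {
  arm <- strategy_arm("x", planned_duration_cycles = 5, ae_prob = "p",
                      drugs = list(list(drug = "mystery",
                                        calendar = "mystery",
                                        unit_cost = "c")))
  expect_error(build_dose_schedule(arm), class = "rrmmcea_strategy_error")
  none <- strategy_arm("y", planned_duration_cycles = 5, ae_prob = "p")
  expect_error(build_dose_schedule(none), class = "rrmmcea_strategy_error")
})

test_that("first-cycle DRd cost equals the hand-computed component sum", {
  cfg <- default_cfg()
  vals <- param_means(cfg$params)
  sched <- build_dose_schedule(cfg$arms$drd)
  costs <- build_cycle_costs(sched, vals, cfg$arms$drd, cfg$costs)
  drug_admin <- 4 * 274.2 + 4 * 0.83 + 21 * 2.9 + 19.7
  monitoring <- 2.08 + 20
  expect_equal(costs$drug_cost_by_cycle[1], drug_admin - 19.7)
  expect_equal(costs$on_treatment_cost_by_cycle[1],
               drug_admin + monitoring)
  expect_equal(costs$ae_event_cost, 24.4 + 21.6)
  expect_equal(costs$pd_cost_per_cycle, 2.08 + 20 + 10.4 + 11.8 + 14.2)
  expect_equal(costs$post_treatment_pfs_cost_per_cycle, 2.08 + 20)
})

test_that("cycle costs are linear in unit prices and match calendar enumeration", {
  cfg <- default_cfg()
  vals <- param_means(cfg$params)
  for (arm_name in names(cfg$arms)) {
    arm <- cfg$arms[[arm_name]]
    sched <- build_dose_schedule(arm)
    c1 <- build_cycle_costs(sched, vals, arm, cfg$costs)
    c2 <- build_cycle_costs(sched, vals * 2, arm, cfg$costs)
    expect_equal(c2$on_treatment_cost_by_cycle,
                 2 * c1$on_treatment_cost_by_cycle)
    expect_equal(c2$pd_cost_per_cycle, 2 * c1$pd_cost_per_cycle)
    # total undiscounted drug cost vs independent enumeration
    total_drug <- sum(vapply(sched, function(s)
      sum(enumerate_days(s$drug, arm$planned_duration_cycles)) *
        s$units_per_administration * vals[[s$unit_cost_ref]],
      numeric(1)))
    expect_equal(sum(c1$drug_cost_by_cycle), total_drug)
  }
})

test_that("an empty drug schedule leaves only non-drug cost components", {
  cfg <- default_cfg()
  vals <- param_means(cfg$params)
  costs <- build_cycle_costs(list(), vals, cfg$arms$krd, cfg$costs)
  expect_equal(unique(costs$drug_cost_by_cycle), 0)
  expect_equal(unique(costs$on_treatment_cost_by_cycle),
               19.7 + 2.08 + 20)
})

test_that("missing unit costs raise a configuration error", {
  cfg <- default_cfg()
  vals <- param_means(cfg$params)
  vals <- vals[names(vals) != "cost_carfilzomib_60mg"]
  sched <- build_dose_schedule(cfg$arms$krd)
  expect_error(build_cycle_costs(sched, vals, cfg$arms$krd, cfg$costs),
               "cost_carfilzomib_60mg", class = "rrmmcea_config_error")
})

test_that("the dose-schedule audit table is tidy and complete", {
  cfg <- default_cfg()
  tab <- dose_schedule_table(cfg$arms$drd, param_means(cfg$params))
  expect_named(tab, c("arm", "drug", "cycle", "administrations", "cost"))
  expect_equal(nrow(tab), 3 * 25)
  expect_equal(sum(tab$administrations[tab$drug == "daratumumab"]), 35)
  expect_equal(sum(tab$cost[tab$drug == "daratumumab"]), 35 * 274.2)
})
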