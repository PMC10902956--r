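# Cohort engine: occupancy recursion, accumulation, discounting.

test_that("occupancy follows the matrix recursion and conserves mass", {
  ident <- array(diag(3), c(3, 3, 10))
  occ <- run_cohort(ident, initial = c(0.6, 0.3, 0.1))
  expect_true(all(apply(occ, 1, function(r)
    isTRUE(all.equal(r, c(0.6, 0.3, 0.1), check.names = FALSE)))))

  kill <- rbind(c(0, 0, 1), c(0, 0, 1), c(0, 0, 1))
  occ2 <- run_cohort(array(kill, c(3, 3, 5)))
  expect_equal(unname(occ2[2, ]), c(0, 0, 1))
  expect_equal(unname(occ2[6, ]), c(0, 0, 1))

  set.seed(3)
  for (rep in 1:5) {
    mats <- replicate(8, random_transition_matrix(), simplify = FALSE)
    occ3 <- run_cohort(mats)
    # brute-force oracle: repeated explicit multiplication
    expected <- Reduce(`%*%`, mats, accumulate = TRUE)
    for (t in 1:8)
      expect_equal(unname(occ3[t + 1, ]),
                   as.numeric(c(1, 0, 0) %*% expected[[t]]),
                   tolerance = 1e-12)
    expect_equal(rowSums(occ3), rep(1, 9), tolerance = 1e-10)
    expect_true(all(diff(occ3[, 3]) >= -1e-12))  # death monotone
  }
  expect_error(run_cohort(array(diag(3), c(3, 3, 2)), initial = c(1, 1, 0)),
               class = "rrmmcea_engine_error")
  expect_error(run_cohort(matrix(1, 2, 2)), class = "rrmmcea_engine_error")
})

test_that("outcome accumulation matches closed forms", {
  s0 <- model_settings(discount_outcome_annual = 0, horizon_cycles = 120)
  ident <- array(diag(3), c(3, 3, 120))
  occ <- run_cohort(ident)
  out <- accumulate_outcomes(occ, u_pfs = 0.73, u_pd = 0.676,
                             settings = s0)
  expect_equal(out$ly, 10)
  expect_equal(out$qaly, 120 * (1 / 12) * 0.73)

  dead <- run_cohort(array(rbind(c(0, 0, 1), c(0, 0, 1), c(0, 0, 1)),
                           c(3, 3, 120)))
  out0 <- accumulate_outcomes(dead, 0.73, 0.676, settings = s0)
  expect_equal(out0$ly, 0)
  expect_equal(out0$qaly, 0)

  # discounting at rate zero equals the undiscounted sum
  s3 <- model_settings(horizon_cycles = 120)
  out3 <- accumulate_outcomes(occ, 0.73, 0.676, settings = s3)
  expect_equal(out3$qaly, 0.73 / 12 * sum(1.03^(-(1:120) / 12)))
  expect_lt(out3$qaly, out$qaly)
  expect_equal(out3$ly, 10)  # life-years undiscounted by default
  expect_error(accumulate_outcomes(occ, 1.2, 0.5, settings = s3),
               class = "rrmmcea_validation_error")
})

test_that("cost accumulation reproduces the geometric-series closed form", {
  cfg <- default_cfg()
  vals <- param_means(cfg$params)
  ident <- array(diag(3), c(3, 3, 120))
  occ <- run_cohort(ident)  # everyone stays progression-free
  flat <- structure(
    list(arm = "flat", on_treatment_cost_by_cycle = rep(100, 120),
         drug_cost_by_cycle = rep(0, 120),
         post_treatment_pfs_cost_per_cycle = 100,
         pd_cost_per_cycle = 0, ae_event_cost = 0),
    class = "cycle_cost_schedule")
  s0 <- model_settings(discount_cost_annual = 0)
  expect_equal(accumulate_costs(occ, flat, settings = s0)$cost, 12000)
  s <- model_settings()
  expect_equal(accumulate_costs(occ, flat, settings = s)$cost,
               100 * sum(1.072^(-(1:120) / 12)))
  # nobody alive -> zero cost
  dead <- run_cohort(array(rbind(c(0, 0, 1), c(0, 0, 1), c(0, 0, 1)),
                           c(3, 3, 120)))
  expect_equal(accumulate_costs(dead, flat, settings = s)$cost, 0)
  # cost scale is multiplicative
  expect_equal(accumulate_costs(occ, flat, settings = s,
                                cost_scale = 2)$cost,
               2 * accumulate_costs(occ, flat, settings = s)$cost)
})

test_that("run_arm composes the pipeline deterministically", {
  fit <- base_fit()
  krd <- fit$arms$krd
  expect_equal(krd$total_ly, 3.52, tolerance = 1e-6)
  expect_equal(krd$total_cost, sum(krd$trace$disc_cost), tolerance = 1e-9)
  expect_equal(krd$total_qaly, sum(krd$trace$disc_qaly), tolerance = 1e-9)
  expect_equal(krd$total_ly, sum(krd$trace$ly), tolerance = 1e-9)

  # identity hazard ratios make the intervention clinically identical
  vals1 <- fit$values; vals1[c("hr_pfs", "hr_os")] <- 1
  drd1 <- run_arm(fit$config$arms$drd, fit$baseline, vals1,
                  fit$settings, fit$config$costs)
  krd1 <- run_arm(fit$config$arms$krd, fit$baseline, vals1,
                  fit$settings, fit$config$costs)
  expect_equal(drd1$total_ly, krd1$total_ly)
  expect_equal(drd1$occupancy, krd1$occupancy)
  expect_false(isTRUE(all.equal(drd1$total_cost, krd1$total_cost)))

  # determinism
  drd2 <- run_arm(fit$config$arms$drd, fit$baseline, vals1,
                  fit$settings, fit$config$costs)
  expect_identical(drd1$total_cost, drd2$total_cost)
})

test_that("a shorter horizon never increases any accumulated total", {
  cfg <- default_cfg()
  base <- baseline_hazards(log(2) / 26, 0.015, 0.03)
  totals <- lapply(c(60, 120), function(h) {
    cfg$settings$horizon_cycles <- as.integer(h)
    cfg$costs$calibrate_to_totals <- FALSE
    fit <- markov_cua(cfg, base = base)
    fit$arms$drd[c("total_cost", "total_qaly", "total_ly")]
  })
  expect_true(all(unlist(totals[[1]]) <= unlist(totals[[2]])))
})

test_that("half-cycle correction averages adjacent occupancy rows", {
  s_on <- model_settings(half_cycle_correction = TRUE,
                         discount_outcome_annual = 0)
  s_off <- model_settings(discount_outcome_annual = 0)
  base <- baseline_hazards(0.05, 0.02, 0.04)
  occ <- run_cohort(array(transition_matrix(base), c(3, 3, 120)))
  ly_on <- accumulate_outcomes(occ, 1, 1, settings = s_on)$ly
  ly_off <- accumulate_outcomes(occ, 1, 1, settings = s_off)$ly
  alive <- 1 - occ[, 3]
  expect_equal(ly_off, sum(alive[-1]) / 12)
  expect_equal(ly_on, sum((alive[-1] + alive[-121]) / 2) / 12)
  expect_gt(ly_on, ly_off)  # declining survival: trapezoid adds half the drop
})
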