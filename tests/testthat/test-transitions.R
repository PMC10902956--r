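# Hazard/probability conversions, matrix construction, calibration.

test_that("rate_to_prob follows the exponential identity and round-trips", {
  expect_equal(rate_to_prob(0), 0)
  expect_equal(rate_to_prob(1e6), 1, tolerance = 1e-12)
  expect_equal(rate_to_prob(0.1, 1), 1 - exp(-0.1))
  expect_equal(rate_to_prob(0.1, 3), 1 - exp(-0.3))
  for (r in c(0, 0.01, 0.2, 2)) {
    expect_equal(prob_to_rate(rate_to_prob(r)), r, tolerance = 1e-12)
  }
  expect_error(rate_to_prob(-0.1), class = "rrmmcea_domain_error")
  expect_error(rate_to_prob(0.1, dt = 0), class = "rrmmcea_domain_error")
  expect_error(prob_to_rate(1), class = "rrmmcea_domain_error")
})

test_that("hazard-ratio transform scales survival on the hazard scale", {
  expect_equal(apply_hazard_ratio(0.2, 1), 0.2)
  expect_equal(apply_hazard_ratio(0, 5), 0)
  expect_equal(apply_hazard_ratio(0.1, 0.6), 1 - 0.9^0.6)
  expect_equal(apply_hazard_ratio(1, 1), 1)
  # equivalence with the rate-scale route
  p <- 0.13
  expect_equal(apply_hazard_ratio(p, 0.46),
               rate_to_prob(0.46 * prob_to_rate(p)))
  expect_error(apply_hazard_ratio(1, 0.5), class = "rrmmcea_domain_error")
  expect_error(apply_hazard_ratio(0.2, -1), class = "rrmmcea_domain_error")
})

test_that("transition matrices are row-stochastic with absorbing death and no recovery", {
  set.seed(11)
  for (i in 1:20) {
    h <- baseline_hazards(runif(1, 0, 0.3), runif(1, 0, 0.2),
                          runif(1, 0, 0.4))
    m <- transition_matrix(h)
    expect_equal(rowSums(m), c(PFS = 1, PD = 1, Death = 1),
                 tolerance = 1e-13)
    expect_true(all(m >= 0 & m <= 1))
    expect_equal(unname(m[3, ]), c(0, 0, 1))
    expect_equal(m[2, 1], 0)
    # marginal per-cause death probability matches the single-risk form
    expect_equal(m[1, 3], rate_to_prob(h$r_die_pfs))
    expect_equal(m[2, 3], rate_to_prob(h$r_die_pd))
  }
  expect_error(baseline_hazards(-0.1, 0, 0),
               class = "rrmmcea_validation_error")
})

test_that("arm matrices apply hazard ratios to the intended transitions", {
  cfg <- default_cfg()
  base <- baseline_hazards(0.06, 0.01, 0.04)
  vals <- param_means(cfg$params)

  # identity ratios reproduce the baseline exactly
  vals1 <- vals; vals1[c("hr_pfs", "hr_os")] <- 1
  m_drd <- build_arm_matrices(base, cfg$arms$drd, cfg$settings, vals1)
  m_krd <- build_arm_matrices(base, cfg$arms$krd, cfg$settings, vals1)
  expect_equal(m_drd, m_krd)

  # zero hazards give the identity matrix every cycle
  m0 <- build_arm_matrices(baseline_hazards(0, 0, 0), cfg$arms$krd,
                           cfg$settings, vals)
  expect_equal(m0[, , 1], diag(3), ignore_attr = TRUE)
  expect_equal(m0[, , cfg$settings$horizon_cycles], diag(3),
               ignore_attr = TRUE)

  # the OS ratio scales the PFS -> Death cause-specific probability
  vals2 <- vals; vals2["hr_pfs"] <- 1; vals2["hr_os"] <- 0.46
  m <- build_arm_matrices(base, cfg$arms$drd, cfg$settings, vals2)
  expect_equal(m["PFS", "Death", 1],
               1 - (1 - rate_to_prob(0.01, 1))^0.46)
  expect_equal(m["PD", "Death", 1],
               1 - (1 - rate_to_prob(0.04, 1))^0.46)
  # and the PFS ratio scales progression (via the joint composition)
  vals3 <- vals; vals3["hr_pfs"] <- 0.6; vals3["hr_os"] <- 1
  m3 <- build_arm_matrices(base, cfg$arms$drd, cfg$settings, vals3)
  expect_equal(m3["PFS", "PFS", 1], exp(-(0.06 * 0.6 + 0.01)))
})

test_that("calibration reproduces the life-year target and is idempotent", {
  s <- model_settings()
  base <- calibrate_baseline(3.52, s)
  expect_lt(abs(attr(base, "achieved_ly") - 3.52), 1e-6)
  expect_equal(base$r_progress, log(2) / 26)
  expect_equal(base$r_die_pd, 2 * base$r_die_pfs)
  # idempotence: calibrating to the achieved value returns the same scale
  base2 <- calibrate_baseline(attr(base, "achieved_ly"), s)
  expect_equal(base2$r_die_pfs, base$r_die_pfs, tolerance = 1e-8)
})

test_that("calibration recovers known hazards from a synthetic target", {
  s <- model_settings()
  m_true <- 0.021
  truth <- baseline_hazards(log(2) / 26, m_true, 2 * m_true)
  occ <- run_cohort(array(transition_matrix(truth), c(3, 3, 120)))
  ly_true <- sum(1 - occ[-1, 3]) / 12
  recovered <- calibrate_baseline(ly_true, s)
  expect_equal(recovered$r_die_pfs, m_true, tolerance = 1e-4)
})

test_that("worse overall survival never increases model life-years", {
  fit <- base_fit()
  ly_at_hr <- function(hr) {
    vals <- fit$values; vals["hr_os"] <- hr
    run_arm(fit$config$arms$drd, fit$baseline, vals, fit$settings,
            fit$config$costs)$total_ly
  }
  lys <- vapply(c(0.28, 0.46, 0.75, 1, 1.5), ly_at_hr, numeric(1))
  expect_true(all(diff(lys) < 0))
})

test_that("cohort life-years match an independent survival summation", {
  base <- calibrate_baseline(3.52, model_settings())
  m <- transition_matrix(base)
  # oracle: restricted mean of the discrete survival curve from
  # explicit matrix powers
  surv <- numeric(120)
  pw <- diag(3)
  for (t in 1:120) {
    pw <- pw %*% m
    surv[t] <- 1 - (c(1, 0, 0) %*% pw)[3]
  }
  expect_equal(sum(surv) / 12, 3.52, tolerance = 1e-6)
})

test_that("unreachable targets and bad inputs raise calibration errors", {
  s <- model_settings()
  expect_error(calibrate_baseline(10, s),
               class = "rrmmcea_calibration_error")
  expect_error(calibrate_baseline(0, s),
               class = "rrmmcea_calibration_error")
  expect_error(calibrate_baseline(9.99, s, bracket = c(1e-4, 5)),
               class = "rrmmcea_calibration_error")
})
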