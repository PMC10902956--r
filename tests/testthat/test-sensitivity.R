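# Deterministic and probabilistic sensitivity analysis.

test_that("tornado entries are ordered by range with isolation across arms", {
  fit <- base_fit()
  dsa <- one_way_dsa(fit)
  expect_s3_class(dsa, "dsa_result")
  ok <- !dsa$flagged
  expect_true(all(diff(dsa$range[ok]) <= 1e-9))
  expect_true(all(dsa$range[ok] >= 0))
  expect_setequal(dsa$parameter,
                  names(Filter(function(s) s$family != "fixed",
                               fit$config$params)))

  # a comparator-side price change leaves the intervention arm untouched
  lo <- markov_cua(fit$config,
                   values = c(cost_carfilzomib_60mg = 173),
                   base = fit$baseline, cost_scale = fit$cost_scale)
  expect_equal(lo$arms$drd$total_cost, fit$arms$drd$total_cost)
  expect_equal(lo$arms$drd$total_qaly, fit$arms$drd$total_qaly)
  expect_false(isTRUE(all.equal(lo$arms$krd$total_cost,
                                fit$arms$krd$total_cost)))
})

test_that("a zero-width parameter has zero range and sinks to the bottom", {
  cfg <- default_cfg()
  cfg$params$cost_ae$low <- 24.4
  cfg$params$cost_ae$high <- 24.4
  fit <- markov_cua(cfg)
  dsa <- one_way_dsa(fit)
  expect_equal(dsa$range[dsa$parameter == "cost_ae"], 0)
  expect_equal(dsa$parameter[nrow(dsa)], "cost_ae")
})

test_that("the intervention drug price brackets the base-case ICUR monotonically", {
  fit <- base_fit()
  icur_at <- function(p) {
    markov_cua(fit$config, values = c(cost_daratumumab_400mg = p),
               base = fit$baseline,
               cost_scale = fit$cost_scale)$comparison$icur
  }
  lo <- icur_at(219.4); mid <- fit$comparison$icur; hi <- icur_at(329)
  expect_lt(lo, mid)
  expect_lt(mid, hi)
})

test_that("price thresholds agree with the closed-form linear solve", {
  fit <- base_fit()
  # fixed point: with WTP set at the base-case ICUR, the threshold
  # price is the base price
  th0 <- price_threshold(fit, "daratumumab", "icur_wtp",
                         wtp = fit$comparison$icur)
  expect_true(th0$crossed)
  expect_equal(th0$threshold, fit$values[["cost_daratumumab_400mg"]],
               tolerance = 0.05)

  # dominance: incremental cost is linear in the unit price
  dc_at <- function(p)
    markov_cua(fit$config, values = c(cost_daratumumab_400mg = p),
               base = fit$baseline,
               cost_scale = fit$cost_scale)$comparison$delta_cost
  p0 <- 0; p1 <- 400
  slope <- (dc_at(p1) - dc_at(p0)) / (p1 - p0)
  p_star <- p0 - dc_at(p0) / slope
  th <- price_threshold(fit, "daratumumab", "dominance")
  expect_true(th$crossed)
  expect_equal(th$threshold, p_star, tolerance = 0.02)
  # and the midpoint check: delta cost vanishes at the threshold
  expect_equal(dc_at(th$threshold), 0, tolerance = abs(slope) * 0.02)

  # doubling the WTP never lowers the ICUR threshold price
  th1 <- price_threshold(fit, "daratumumab", "icur_wtp", wtp = 1290)
  th2 <- price_threshold(fit, "daratumumab", "icur_wtp", wtp = 2580)
  expect_gte(th2$threshold, th1$threshold)

  expect_error(price_threshold(fit, "bortezomib"),
               class = "rrmmcea_config_error")
})

test_that("PSA draws are reproducible and re-run the deterministic pipeline", {
  fit <- base_fit()
  psa1 <- run_psa(fit, n = 64, seed = 99)
  psa2 <- run_psa(fit, n = 64, seed = 99)
  expect_identical(as.data.frame(psa1), as.data.frame(psa2))
  expect_equal(nrow(run_psa(fit, n = 1, seed = 5)), 1)

  # per-draw totals equal a full run_arm() at the sampled values
  pars <- names(fit_all_distributions(fit$config$params))
  for (i in c(1, 17, 50)) {
    ov <- unlist(psa1[i, pars])
    refit <- markov_cua(fit$config, values = ov, base = fit$baseline,
                        cost_scale = fit$cost_scale)
    expect_equal(psa1$cost_drd[i], refit$arms$drd$total_cost,
                 tolerance = 1e-9)
    expect_equal(psa1$qaly_drd[i], refit$arms$drd$total_qaly,
                 tolerance = 1e-9)
    expect_equal(psa1$cost_krd[i], refit$arms$krd$total_cost,
                 tolerance = 1e-9)
    expect_equal(psa1$delta_qaly[i],
                 refit$comparison$delta_qaly, tolerance = 1e-9)
  }
})

test_that("PSA parameter samples centre on the base-case means", {
  fit <- base_fit()
  psa <- run_psa(fit, n = 10000, seed = 4)
  pars <- names(fit_all_distributions(fit$config$params))
  for (nm in pars) {
    x <- psa[[nm]]
    se <- stats::sd(x) / sqrt(length(x))
    expect_lt(abs(mean(x) - fit$values[[nm]]), 3.5 * se,
              label = sprintf("sample mean of %s", nm))
  }
})

test_that("hazard ratios and utilities can be held fixed in the PSA", {
  fit <- base_fit()
  psa <- run_psa(fit, n = 20, seed = 1, vary_hazard_ratios = FALSE,
                 vary_utilities = FALSE)
  expect_false("hr_os" %in% names(psa))
  expect_false("u_pfs" %in% names(psa))
  # only the small adverse-event term still moves the QALY increment
  expect_lt(diff(range(psa$delta_qaly)), 1e-3)
  expect_equal(mean(psa$delta_qaly), fit$comparison$delta_qaly,
               tolerance = 1e-3)
})

test_that("the acceptability curve follows its definition and is monotone", {
  fit <- base_fit()
  psa <- run_psa(fit, n = 500, seed = 12)
  curve <- ceac(psa, wtp_grid = c(0, 500, 1290, 2580, 5000))
  expect_equal(curve$probability[1], mean(psa$delta_cost < 0))
  expect_true(all(curve$probability >= 0 & curve$probability <= 1))
  expect_equal(curve$probability[3],
               mean(1290 * psa$delta_qaly - psa$delta_cost > 0))

  pos <- psa[psa$delta_qaly > 0, ]
  curve_pos <- ceac(pos, wtp_grid = seq(0, 5000, by = 100))
  expect_true(all(diff(curve_pos$probability) >= 0))

  # switch point consistency with the median sampled ICUR
  if (all(psa$delta_qaly > 0)) {
    sp <- ceac_switch_point(psa)
    expect_equal(sp, stats::median(psa$delta_cost / psa$delta_qaly))
    expect_gte(mean(sp * psa$delta_qaly - psa$delta_cost >= 0), 0.5)
  }
})
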