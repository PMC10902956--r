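# Deterministic and probabilistic sensitivity analysis.
#
# DSA re-runs the full deterministic pipeline at each varied
# parameter's bounds (baseline hazards and cost scales held at their
# base-case calibration).  PSA samples every varied parameter from its
# fitted distribution and re-runs the pipeline per draw; the per-draw
# evaluation is vectorised across draws for speed but is exactly the
# cohort-engine recursion.

#' One-way deterministic sensitivity analysis
#'
#' Each parameter with a sampling family other than `"fixed"` is set to
#' its lower and upper 95% bound in turn, all else held at base case,
#' and the full deterministic pipeline is re-run.  The primary outcome
#' is the incremental net monetary benefit at the configured
#' willingness-to-pay; the incremental cost-utility ratio is reported
#' alongside.  Entries are ordered by outcome range (tornado order),
#' ties broken alphabetically.  A pipeline failure at a bound flags the
#' entry instead of aborting the run.
#'
#' @param fit A [markov_cua()] fit.
#' @param parameters Optional character vector restricting the
#'   parameters varied.
#' @return A `dsa_result` data frame with columns `parameter`, `low`,
#'   `high`, `inmb_at_low`, `inmb_at_high`, `icur_at_low`,
#'   `icur_at_high`, `range`, `flagged`.
#' @export
one_way_dsa <- function(fit, parameters = NULL) {
  stopifnot(inherits(fit, "markov_cua"))
  varied <- Filter(function(s) s$family != "fixed", fit$config$params)
  if (!is.null(parameters))
    varied <- varied[intersect(names(varied), parameters)]
  wtp <- fit$settings$wtp_per_qaly
  eval_at <- function(name, value) {
    ov <- stats::setNames(value, name)
    refit <- markov_cua(fit$config, values = ov, base = fit$baseline,
                        cost_scale = fit$cost_scale)
    cmp <- refit$comparison
    c(inmb = cmp$nmb_intervention - cmp$nmb_comparator, icur = cmp$icur)
  }
  rows <- lapply(varied, function(s) {
    res <- tryCatch({
      lo <- eval_at(s$name, s$low)
      hi <- eval_at(s$name, s$high)
      data.frame(parameter = s$name, low = s$low, high = s$high,
                 inmb_at_low = lo[["inmb"]], inmb_at_high = hi[["inmb"]],
                 icur_at_low = lo[["icur"]], icur_at_high = hi[["icur"]],
                 range = abs(hi[["inmb"]] - lo[["inmb"]]),
                 flagged = FALSE)
    }, rrmmcea_error = function(e)
      data.frame(parameter = s$name, low = s$low, high = s$high,
                 inmb_at_low = NA_real_, inmb_at_high = NA_real_,
                 icur_at_low = NA_real_, icur_at_high = NA_real_,
                 range = NA_real_, flagged = TRUE))
    res
  })
  out <- do.call(rbind, rows)
  out <- out[order(-ifelse(is.na(out$range), -Inf, out$range),
                   out$parameter), ]
  rownames(out) <- NULL
  class(out) <- c("dsa_result", "data.frame")
  attr(out, "wtp") <- wtp
  attr(out, "base_inmb") <- fit$comparison$nmb_intervention -
    fit$comparison$nmb_comparator
  out
}

#' Tornado diagram of a one-way sensitivity analysis
#'
#' @param dsa A `dsa_result` from [one_way_dsa()].
#' @param top Number of parameters displayed (largest ranges first).
#' @param ... Unused.
#' @return `dsa`, invisibly.
#' @export
plot_tornado <- function(dsa, top = 12, ...) {
  stopifnot(inherits(dsa, "dsa_result"))
  d <- utils::head(dsa[!dsa$flagged, ], top)
  d <- d[nrow(d):1, ]
  base <- attr(dsa, "base_inmb")
  old <- graphics::par(mar = c(4, 12, 2, 1))
  on.exit(graphics::par(old))
  graphics::plot(NA, xlim = range(c(d$inmb_at_low, d$inmb_at_high, base)),
                 ylim = c(0.5, nrow(d) + 0.5), yaxt = "n",
                 xlab = "incremental NMB (USD)", ylab = "",
                 main = "One-way sensitivity (tornado)")
  graphics::axis(2, at = seq_len(nrow(d)), labels = d$parameter,
                 las = 1, cex.axis = 0.8)
  for (i in seq_len(nrow(d))) {
    graphics::segments(d$inmb_at_low[i], i, base, i, lwd = 8,
                       col = "seagreen", lend = 1)
    graphics::segments(base, i, d$inmb_at_high[i], i, lwd = 8,
                       col = "darkorange", lend = 1)
  }
  graphics::abline(v = base, lty = 2)
  invisible(dsa)
}

#' Threshold price of a drug
#'
#' Finds the unit price of a drug at which a cost-effectiveness
#' criterion is met: `"icur_wtp"` (the incremental cost-utility ratio
#' equals the willingness-to-pay threshold) or `"dominance"` (the
#' incremental cost reaches zero, so the intervention dominates below
#' this price).  Since arm costs are linear in every unit price, the
#' criterion has at most one root; it is located by bisection on
#' `[0, 10 x base price]` to $0.01.
#'
#' @param fit A [markov_cua()] fit.
#' @param drug Drug identifier as used in the arm definitions (e.g.
#'   `"daratumumab"`).
#' @param criterion `"icur_wtp"` or `"dominance"`.
#' @param wtp Willingness-to-pay; defaults to the fit's threshold.
#' @return A `price_threshold` list with `threshold` (USD per unit, or
#'   `NA` if the criterion is never crossed), `criterion`, `drug`,
#'   `parameter`, `base_price` and `crossed`.
#' @export
price_threshold <- function(fit, drug, criterion = c("icur_wtp", "dominance"),
                            wtp = fit$settings$wtp_per_qaly) {
  stopifnot(inherits(fit, "markov_cua"))
  criterion <- match.arg(criterion)
  par_name <- NULL
  for (a in fit$config$arms)
    for (d in a$drugs)
      if (identical(d$drug, drug)) par_name <- d$unit_cost
  if (is.null(par_name))
    config_error("drug '%s' not found in any arm", drug)
  base_price <- fit$values[[par_name]]
  g <- function(price) {
    refit <- markov_cua(fit$config,
                        values = stats::setNames(price, par_name),
                        base = fit$baseline, cost_scale = fit$cost_scale)
    cmp <- refit$comparison
    if (criterion == "icur_wtp") cmp$icur - wtp else cmp$delta_cost
  }
  lo <- 0; hi <- 10 * base_price
  glo <- g(lo); ghi <- g(hi)
  out <- list(drug = drug, parameter = par_name, criterion = criterion,
              base_price = base_price, wtp = wtp)
  if (glo * ghi > 0) {
    out$threshold <- NA_real_
    out$crossed <- FALSE
  } else {
    while (hi - lo > 0.005) {
      mid <- (lo + hi) / 2
      if (g(mid) * glo <= 0) hi <- mid else { lo <- mid; glo <- g(lo) }
    }
    out$threshold <- round((lo + hi) / 2, 2)
    out$crossed <- TRUE
  }
  class(out) <- "price_threshold"
  out
}

#' @export
print.price_threshold <- function(x, ...) {
  lbl <- if (x$criterion == "icur_wtp")
    sprintf("ICUR = WTP ($%g/QALY)", x$wtp) else "zero incremental cost"
  if (x$crossed)
    cat(sprintf(
      "<price_threshold> %s: $%.2f per unit reaches %s (base price $%.2f)\n",
      x$drug, x$threshold, lbl, x$base_price))
  else
    cat(sprintf(
      "<price_threshold> %s: criterion %s never crossed in [0, %.2f]\n",
      x$drug, lbl, 10 * x$base_price))
  invisible(x)
}

# Vectorised evaluation of one arm across PSA draws.  V is a named list
# of per-draw value vectors (length n) for sampled parameters; base-case
# values are used for the rest.  Reproduces run_arm() draw by draw.
.run_arm_psa <- function(arm, base, V, base_values, n, settings,
                         cost_cfg, cost_scale, hr_pfs_on_death) {
  val <- function(name) {
    if (name %in% names(V)) V[[name]] else
      rep(param_value(base_values, name), n)
  }
  dt <- settings$cycle_length_months
  horizon <- settings$horizon_cycles
  dur <- arm$planned_duration_cycles
  hrp <- if (is.null(arm$hr_pfs)) 1 else val(arm$hr_pfs)
  hro <- if (is.null(arm$hr_os)) 1 else val(arm$hr_os)
  rp <- base$r_progress * hrp
  rd1 <- base$r_die_pfs * (if (hr_pfs_on_death) hrp * hro else hro)
  rd2 <- base$r_die_pd * hro
  a11 <- exp(-(rp + rd1) * dt)
  a13 <- 1 - exp(-rd1 * dt)
  a12 <- exp(-rd1 * dt) - a11
  a22 <- exp(-rd2 * dt)

  schedules <- build_dose_schedule(arm)
  # duration x n on-treatment cost matrix, linear in sampled prices
  drug_cost <- matrix(0, dur, n)
  for (s in schedules)
    drug_cost <- drug_cost +
      outer(s$administrations_by_cycle * s$units_per_administration,
            val(s$unit_cost_ref))
  comp_sum <- function(refs) {
    tot <- rep(0, n)
    for (r in refs) tot <- tot + val(r)
    tot
  }
  admin <- val(cost_cfg$administration_per_cycle)
  monitoring <- comp_sum(cost_cfg$monitoring_on_treatment)
  on_cost <- sweep(drug_cost, 2, admin + monitoring, `+`)
  post_cost <- comp_sum(cost_cfg$pfs_post_treatment)
  pd_cost <- comp_sum(cost_cfg$pd_per_cycle)
  ae_cost <- comp_sum(cost_cfg$ae_event)
  p_ae <- val(arm$ae_prob)
  u_pfs <- val("u_pfs")
  u_pd <- u_pfs + val("du_progression")
  du_ae <- abs(val("du_ae"))

  d_cost <- discount_factors(settings$discount_cost_annual, horizon, dt)
  d_out <- discount_factors(settings$discount_outcome_annual, horizon, dt)
  d_ly <- if (settings$discount_ly) d_out else rep(1, horizon)
  dt_years <- dt / 12
  hcc <- settings$half_cycle_correction

  pfs <- rep(1, n); pd <- rep(0, n)
  cost <- qaly <- ly <- rep(0, n)
  for (t in seq_len(horizon)) {
    pfs_new <- pfs * a11
    pd_new <- pfs * a12 + pd * a22
    cpfs <- if (hcc) (pfs + pfs_new) / 2 else pfs_new
    cpd <- if (hcc) (pd + pd_new) / 2 else pd_new
    on <- t <= dur
    cyc_cost <- cpfs * (if (on) on_cost[t, ] else post_cost) +
      cpd * pd_cost + (if (on) cpfs * p_ae * ae_cost else 0)
    cost <- cost + cyc_cost * d_cost[t]
    qaly <- qaly + (cpfs * u_pfs + cpd * u_pd -
                      (if (on) cpfs * p_ae * du_ae else 0)) *
      dt_years * d_out[t]
    ly <- ly + (cpfs + cpd) * dt_years * d_ly[t]
    pfs <- pfs_new; pd <- pd_new
  }
  list(cost = cost * cost_scale, qaly = qaly, ly = ly)
}

#' Probabilistic sensitivity analysis
#'
#' Draws every varied parameter independently from its fitted
#' distribution (see [fit_distribution()]) and re-runs the
#' deterministic pipeline per draw.  Baseline hazards and per-arm cost
#' scales are kept at their base-case calibration; hazard-ratio draws
#' shift the intervention arm only.  Draws yielding an invalid state
#' utility (the post-progression utility falling outside `[0, 1]`) are
#' re-sampled; a resample rate above 1% triggers a warning.
#'
#' @param fit A [markov_cua()] fit.
#' @param n Number of draws.
#' @param seed Integer seed (draws are reproducible per seed).
#' @param vary_hazard_ratios,vary_utilities Logical switches; defaults
#'   from the configuration's `psa` block.
#' @return A `psa_result` data frame: one row per draw with the sampled
#'   parameters, per-arm discounted `cost_*`/`qaly_*` totals,
#'   `delta_cost` and `delta_qaly` (intervention minus comparator).
#'   Attributes: `wtp`, `seed`, `n_resampled`, arm names.
#' @examples
#' fit <- markov_cua()
#' psa <- run_psa(fit, n = 200, seed = 1)
#' mean(1290 * psa$delta_qaly - psa$delta_cost > 0)
#' @export
run_psa <- function(fit, n = fit$config$psa$n_draws,
                    seed = fit$config$psa$seed,
                    vary_hazard_ratios = NULL, vary_utilities = NULL) {
  stopifnot(inherits(fit, "markov_cua"), n >= 1)
  psa_cfg <- fit$config$psa
  if (is.null(vary_hazard_ratios))
    vary_hazard_ratios <- isTRUE(psa_cfg$vary_hazard_ratios)
  if (is.null(vary_utilities))
    vary_utilities <- isTRUE(psa_cfg$vary_utilities)
  skip <- character()
  if (!vary_hazard_ratios) skip <- c(skip, "hazard-ratio")
  if (!vary_utilities) skip <- c(skip, "utility", "disutility")
  dists <- fit_all_distributions(fit$config$params, skip_roles = skip)
  if (length(dists) == 0)
    config_error("no varied parameters available for PSA")

  set.seed(as.integer(seed))
  draw_block <- function(m) {
    out <- lapply(dists, dist_draw, n = m)
    names(out) <- names(dists)
    out
  }
  V <- draw_block(n)
  invalid_rows <- function(V) {
    u_pd <- (if ("u_pfs" %in% names(V)) V$u_pfs else
      fit$values[["u_pfs"]]) +
      (if ("du_progression" %in% names(V)) V$du_progression else
        fit$values[["du_progression"]])
    which(u_pd < 0 | u_pd > 1)
  }
  n_resampled <- 0L
  for (iter in 1:50) {
    bad <- invalid_rows(V)
    if (length(bad) == 0) break
    n_resampled <- n_resampled + length(bad)
    repl <- draw_block(length(bad))
    for (nm in names(V)) V[[nm]][bad] <- repl[[nm]]
  }
  if (n_resampled > 0.01 * n)
    warning(sprintf("PSA re-sampled %d draw(s) (> 1%% of %d)",
                    n_resampled, n))

  hr_pfs_on_death <- isTRUE(fit$config$calibration$apply_hr_pfs_to_death)
  res <- lapply(names(fit$arms), function(nm)
    .run_arm_psa(fit$config$arms[[nm]], fit$baseline, V, fit$values, n,
                 fit$settings, fit$config$costs,
                 fit$cost_scale[[nm]], hr_pfs_on_death))
  names(res) <- names(fit$arms)
  iv <- fit$intervention; cp <- fit$comparator
  out <- data.frame(draw = seq_len(n), as.data.frame(V))
  out[[paste0("cost_", iv)]] <- res[[iv]]$cost
  out[[paste0("qaly_", iv)]] <- res[[iv]]$qaly
  out[[paste0("cost_", cp)]] <- res[[cp]]$cost
  out[[paste0("qaly_", cp)]] <- res[[cp]]$qaly
  out$delta_cost <- res[[iv]]$cost - res[[cp]]$cost
  out$delta_qaly <- res[[iv]]$qaly - res[[cp]]$qaly
  class(out) <- c("psa_result", "data.frame")
  attr(out, "wtp") <- fit$settings$wtp_per_qaly
  attr(out, "seed") <- seed
  attr(out, "n_resampled") <- n_resampled
  attr(out, "intervention") <- iv
  attr(out, "comparator") <- cp
  out
}

#' @export
print.psa_result <- function(x, ...) {
  wtp <- attr(x, "wtp")
  cat(sprintf(
    "<psa_result> %d draws (seed %s): P(cost-effective at WTP $%g) = %.3f; NE quadrant %.3f\n",
    nrow(x), format(attr(x, "seed")), wtp,
    mean(wtp * x$delta_qaly - x$delta_cost > 0),
    mean(x$delta_cost > 0 & x$delta_qaly > 0)))
  invisible(x)
}

#' Cost-effectiveness plane scatter of PSA draws
#'
#' @param x A `psa_result`.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.psa_result <- function(x, ...) {
  wtp <- attr(x, "wtp")
  graphics::plot(x$delta_qaly, x$delta_cost, pch = 16, cex = 0.3,
                 col = grDevices::adjustcolor("steelblue", 0.4),
                 xlab = "incremental QALYs", ylab = "incremental cost (USD)",
                 main = "Cost-effectiveness plane", ...)
  graphics::abline(h = 0, v = 0, col = "grey60")
  graphics::abline(a = 0, b = wtp, lty = 2)
  invisible(x)
}

#' Cost-effectiveness acceptability curve
#'
#' Fraction of PSA draws with positive net monetary benefit,
#' `wtp * delta_qaly - delta_cost > 0`, at each grid threshold.
#'
#' @param psa A `psa_result`.
#' @param wtp_grid Thresholds (USD/QALY) at which to evaluate.
#' @return A `ceac_curve` data frame with columns `wtp` and
#'   `probability`.
#' @export
ceac <- function(psa, wtp_grid = seq(0, 4000, by = 50)) {
  stopifnot(inherits(psa, "psa_result"), nrow(psa) > 0)
  prob <- vapply(wtp_grid, function(w)
    mean(w * psa$delta_qaly - psa$delta_cost > 0), numeric(1))
  out <- data.frame(wtp = wtp_grid, probability = prob)
  class(out) <- c("ceac_curve", "data.frame")
  out
}

#' Acceptability switch point
#'
#' The willingness-to-pay at which the acceptability crosses 0.5.  When
#' every draw has a positive QALY increment this equals the median of
#' the per-draw cost-utility ratios; otherwise it is located on a grid.
#'
#' @param psa A `psa_result`.
#' @return USD per QALY (may be `NA` if acceptability never crosses
#'   0.5).
#' @export
ceac_switch_point <- function(psa) {
  stopifnot(inherits(psa, "psa_result"))
  if (all(psa$delta_qaly > 0))
    return(stats::median(psa$delta_cost / psa$delta_qaly))
  grid <- seq(0, 20 * attr(psa, "wtp"), length.out = 2001)
  cv <- ceac(psa, grid)
  i <- which(cv$probability >= 0.5)[1]
  if (is.na(i)) NA_real_ else cv$wtp[i]
}

#' Plot a cost-effectiveness acceptability curve
#'
#' @param curve A `ceac_curve` from [ceac()].
#' @param wtp Optional threshold marked with a vertical line.
#' @param ... Passed to [graphics::plot()].
#' @return `curve`, invisibly.
#' @export
plot_ceac <- function(curve, wtp = NULL, ...) {
  stopifnot(inherits(curve, "ceac_curve"))
  graphics::plot(curve$wtp, curve$probability, type = "l", lwd = 2,
                 ylim = c(0, 1), xlab = "willingness to pay (USD/QALY)",
                 ylab = "probability cost-effective",
                 main = "Cost-effectiveness acceptability curve", ...)
  graphics::abline(h = 0.5, col = "grey70", lty = 3)
  if (!is.null(wtp)) graphics::abline(v = wtp, lty = 2)
  invisible(curve)
}
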