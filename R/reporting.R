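# Reproduction runs: emit the base-case tables, sensitivity outputs and
# budget-impact table as CSV/JSON/PNG artifacts, with a JSON manifest.
# A thin command-line wrapper over these functions is installed at
# inst/scripts/rrmmcea-cli.R.

io_error <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("rrmmcea_io_error", "rrmmcea_error")))
}

.ensure_outdir <- function(out_dir) {
  if (!dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir) || file.access(out_dir, mode = 2) != 0)
    io_error("output directory '%s' is not writable", out_dir)
  invisible(out_dir)
}

.write_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}

# Manifest: config digest, seed, package version, artifact list.  The
# digest is the MD5 of the configuration file, so identical configs
# give identical digests.
run_manifest <- function(config, seed, artifacts, out_dir) {
  man <- list(
    config = config$path,
    config_digest = unname(tools::md5sum(config$path)),
    seed = seed,
    package = "rrmmcea",
    version = as.character(utils::packageVersion("rrmmcea")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    artifacts = basename(artifacts))
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(man, path, auto_unbox = TRUE, pretty = TRUE)
  man$path <- path
  class(man) <- "run_manifest"
  man
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("<run_manifest> %d artifact(s) in %s (config %s)\n",
              length(x$artifacts), dirname(x$path),
              substr(x$config_digest, 1, 8)))
  invisible(x)
}

#' Run and export the base case
#'
#' Fits the model ([markov_cua()]) and writes the arm summaries, the
#' incremental comparison table, per-arm cohort traces, dose-schedule
#' audit table and calibrated baseline hazards to `out_dir`.
#'
#' @param config A configuration path or [load_config()] result.
#' @param out_dir Output directory (created if needed).
#' @return A `run_manifest`, invisibly; the fitted model is attached as
#'   attribute `"fit"`.
#' @export
run_base_case <- function(config = load_config(), out_dir = "results") {
  if (is.character(config)) config <- load_config(config)
  .ensure_outdir(out_dir)
  fit <- markov_cua(config)
  arts <- character()
  arm_tab <- do.call(rbind, lapply(fit$arms, function(a)
    data.frame(arm = a$arm, label = a$label, cost = a$total_cost,
               qaly = a$total_qaly, ly = a$total_ly,
               cost_scale = a$cost_scale)))
  arts <- c(arts, .write_csv(arm_tab, file.path(out_dir, "arm_summary.csv")))
  arts <- c(arts, .write_csv(
    cea_table(fit$comparison, fit$arms[[fit$intervention]],
              fit$arms[[fit$comparator]]),
    file.path(out_dir, "comparison.csv")))
  for (nm in names(fit$arms))
    arts <- c(arts, .write_csv(
      fit$arms[[nm]]$trace, file.path(out_dir,
                                      sprintf("trace_%s.csv", nm))))
  doses <- do.call(rbind, lapply(fit$config$arms, dose_schedule_table,
                                 values = fit$values))
  arts <- c(arts, .write_csv(doses, file.path(out_dir, "dose_schedule.csv")))
  b <- fit$baseline
  arts <- c(arts, .write_csv(
    data.frame(r_progress = b$r_progress, r_die_pfs = b$r_die_pfs,
               r_die_pd = b$r_die_pd,
               achieved_ly = attr(b, "achieved_ly"),
               residual = attr(b, "residual")),
    file.path(out_dir, "baseline_hazards.csv")))
  man <- run_manifest(config, seed = NA, arts, out_dir)
  attr(man, "fit") <- fit
  invisible(man)
}

#' Run and export a sensitivity analysis
#'
#' @param config A configuration path or [load_config()] result.
#' @param out_dir Output directory.
#' @param mode `"dsa"` (tornado CSV + plot), `"psa"` (sample CSV, CEAC
#'   CSV, cost-effectiveness plane and CEAC plots, summary JSON) or
#'   `"threshold"` (price-threshold CSV).
#' @param n_draws PSA draws (mode `"psa"`).
#' @param seed PSA seed; defaults to the configuration's.
#' @param drug Drug identifier for mode `"threshold"`.
#' @return A `run_manifest`, invisibly.
#' @export
run_sensitivity <- function(config = load_config(), out_dir = "results",
                            mode = c("dsa", "psa", "threshold"),
                            n_draws = NULL, seed = NULL,
                            drug = "daratumumab") {
  if (is.character(config)) config <- load_config(config)
  mode <- match.arg(mode)
  .ensure_outdir(out_dir)
  fit <- markov_cua(config)
  arts <- character()
  seed_used <- NA
  if (mode == "dsa") {
    dsa <- one_way_dsa(fit)
    arts <- c(arts, .write_csv(as.data.frame(dsa),
                               file.path(out_dir, "tornado.csv")))
    grDevices::png(file.path(out_dir, "tornado.png"), 900, 600)
    plot_tornado(dsa)
    grDevices::dev.off()
    arts <- c(arts, file.path(out_dir, "tornado.png"))
  } else if (mode == "psa") {
    n <- n_draws %||% config$psa$n_draws
    seed_used <- seed %||% config$psa$seed
    psa <- run_psa(fit, n = n, seed = seed_used)
    arts <- c(arts, .write_csv(as.data.frame(psa),
                               file.path(out_dir, "psa_samples.csv")))
    curve <- ceac(psa)
    arts <- c(arts, .write_csv(as.data.frame(curve),
                               file.path(out_dir, "ceac.csv")))
    wtp <- fit$settings$wtp_per_qaly
    summ <- list(
      n_draws = n, seed = seed_used, wtp = wtp,
      prob_cost_effective = mean(wtp * psa$delta_qaly -
                                   psa$delta_cost > 0),
      prob_ne_quadrant = mean(psa$delta_cost > 0 & psa$delta_qaly > 0),
      switch_point = ceac_switch_point(psa),
      n_resampled = attr(psa, "n_resampled"))
    jsonlite::write_json(summ, file.path(out_dir, "psa_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    arts <- c(arts, file.path(out_dir, "psa_summary.json"))
    grDevices::png(file.path(out_dir, "ce_plane.png"), 700, 600)
    plot(psa)
    grDevices::dev.off()
    grDevices::png(file.path(out_dir, "ceac.png"), 700, 500)
    plot_ceac(curve, wtp = wtp)
    grDevices::dev.off()
    arts <- c(arts, file.path(out_dir, "ce_plane.png"),
              file.path(out_dir, "ceac.png"))
  } else {
    rows <- lapply(c("icur_wtp", "dominance"), function(cr) {
      th <- price_threshold(fit, drug, cr)
      data.frame(drug = th$drug, parameter = th$parameter,
                 criterion = cr, base_price = th$base_price,
                 threshold = th$threshold, crossed = th$crossed)
    })
    arts <- c(arts, .write_csv(do.call(rbind, rows),
                               file.path(out_dir, "price_threshold.csv")))
  }
  invisible(run_manifest(config, seed_used, arts, out_dir))
}

#' Run and export the budget impact analysis
#'
#' @param config A configuration path or [load_config()] result.
#' @param out_dir Output directory.
#' @return A `run_manifest`, invisibly; the `bia_result` is attached as
#'   attribute `"bia"`.
#' @export
run_bia_report <- function(config = load_config(), out_dir = "results") {
  if (is.character(config)) config <- load_config(config)
  .ensure_outdir(out_dir)
  bia <- run_bia(config)
  tab <- as.data.frame(bia)
  tab$total_impact <- c(attr(bia, "total_impact"),
                        rep(NA, nrow(tab) - 1))
  arts <- .write_csv(tab, file.path(out_dir, "budget_impact.csv"))
  man <- run_manifest(config, seed = NA, arts, out_dir)
  attr(man, "bia") <- bia
  invisible(man)
}
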