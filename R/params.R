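# Parameter registry: typed model parameters with uncertainty ranges,
# model settings, strategy arms and budget-impact inputs, read from a
# YAML configuration file.

.param_roles <- c("cost-USD", "probability-per-cycle", "utility",
                  "disutility", "hazard-ratio", "rate", "share")
.param_families <- c("beta", "gamma", "lognormal", "fixed")

config_error <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("rrmmcea_config_error", "rrmmcea_error")))
}

validation_error <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("rrmmcea_validation_error", "rrmmcea_error")))
}

#' Construct a model parameter specification
#'
#' A `param_spec` is a named scalar with its mean, 95% interval bounds,
#' sampling-distribution family and semantic role.  Fixed parameters
#' (family `"fixed"`) carry no interval and are excluded from
#' sensitivity analyses.
#'
#' @param name Identifier, unique within a parameter set.
#' @param mean Point estimate (base-case value).
#' @param low,high Lower and upper 95% bounds; `NA` for fixed parameters.
#' @param family Sampling family: `"beta"`, `"gamma"`, `"lognormal"` or
#'   `"fixed"`.
#' @param role One of `"cost-USD"`, `"probability-per-cycle"`,
#'   `"utility"`, `"disutility"`, `"hazard-ratio"`, `"rate"`, `"share"`.
#' @return An object of class `param_spec`.
#' @examples
#' param_spec("u_pfs", 0.73, 0.584, 0.876, "beta", "utility")
#' @export
param_spec <- function(name, mean, low = NA_real_, high = NA_real_,
                       family = "fixed", role = "rate") {
  family <- match.arg(family, .param_families)
  role <- match.arg(role, .param_roles)
  spec <- structure(
    list(name = as.character(name), mean = as.numeric(mean),
         low = as.numeric(low), high = as.numeric(high),
         family = family, role = role),
    class = "param_spec")
  validate_param_spec(spec)
  spec
}

#' @export
print.param_spec <- function(x, ...) {
  iv <- if (x$family == "fixed") "(not varied)" else
    sprintf("[%g, %g] ~ %s", x$low, x$high, x$family)
  cat(sprintf("<param_spec> %s = %g %s  role: %s\n",
              x$name, x$mean, iv, x$role))
  invisible(x)
}

# Invariant checks; errors carry the parameter name and the rule broken.
validate_param_spec <- function(spec) {
  with(spec, {
    if (!is.finite(mean))
      validation_error("parameter '%s': mean must be finite", name)
    if (family != "fixed") {
      if (!is.finite(low) || !is.finite(high))
        validation_error("parameter '%s': low/high required unless fixed", name)
      if (!(low <= mean && mean <= high))
        validation_error("parameter '%s': requires low <= mean <= high", name)
    }
    bounds01 <- role %in% c("probability-per-cycle", "utility", "share")
    if (bounds01 && (mean < 0 || mean > 1))
      validation_error("parameter '%s': role %s must lie in [0, 1]", name, role)
    if (role == "disutility" && (mean < -1 || mean > 0))
      validation_error("parameter '%s': disutility must lie in [-1, 0]", name)
    if (role == "cost-USD" && mean < 0)
      validation_error("parameter '%s': cost must be nonnegative", name)
    if (role == "hazard-ratio" && family != "fixed" && mean <= 0)
      validation_error("parameter '%s': hazard ratio must be positive", name)
    if (family == "beta" && !(bounds01 || role == "disutility"))
      validation_error("parameter '%s': beta family only for [0,1]-bounded roles", name)
    if (family == "gamma" && !(role %in% c("cost-USD", "rate")))
      validation_error("parameter '%s': gamma family only for nonnegative roles", name)
  })
  invisible(spec)
}

#' Bundle parameter specifications into a set
#'
#' @param specs A list of [param_spec()] objects.
#' @return A `param_set`: a named list of `param_spec`s.
#' @export
param_set <- function(specs) {
  stopifnot(all(vapply(specs, inherits, logical(1), "param_spec")))
  nm <- vapply(specs, `[[`, character(1), "name")
  if (anyDuplicated(nm))
    config_error("duplicate parameter name(s): %s",
                 paste(unique(nm[duplicated(nm)]), collapse = ", "))
  structure(stats::setNames(specs, nm), class = "param_set")
}

#' @export
print.param_set <- function(x, ...) {
  cat(sprintf("<param_set> %d parameters (%d varied)\n", length(x),
              sum(vapply(x, function(s) s$family != "fixed", logical(1)))))
  print(as.data.frame(x))
  invisible(x)
}

#' @export
as.data.frame.param_set <- function(x, ...) {
  data.frame(
    name = vapply(x, `[[`, character(1), "name"),
    mean = vapply(x, `[[`, numeric(1), "mean"),
    low = vapply(x, `[[`, numeric(1), "low"),
    high = vapply(x, `[[`, numeric(1), "high"),
    family = vapply(x, `[[`, character(1), "family"),
    role = vapply(x, `[[`, character(1), "role"),
    row.names = NULL)
}

#' Extract base-case parameter values
#'
#' @param params A `param_set`.
#' @return Named numeric vector of parameter means.
#' @export
param_means <- function(params) {
  vapply(params, `[[`, numeric(1), "mean")
}

# Look up one parameter value in a named numeric vector, with a clear
# error when a referenced cost or probability is absent.
param_value <- function(values, name) {
  if (!name %in% names(values))
    config_error("missing parameter value '%s'", name)
  unname(values[[name]])
}

#' Construct model settings
#'
#' Global run controls for the cohort model: cycle length, horizon,
#' willingness-to-pay threshold and annual discount rates.  Discounting
#' uses end-of-cycle timing, `(1 + r)^(-t/12)` for cycle `t`.
#'
#' @param cycle_length_months Cycle length in months (default 1).
#' @param horizon_cycles Number of cycles modelled (default 120).
#' @param wtp_per_qaly Willingness-to-pay threshold, USD per QALY.
#' @param discount_cost_annual Annual discount rate for costs.
#' @param discount_outcome_annual Annual discount rate for QALYs.
#' @param discount_ly Logical; discount life-years as well (default
#'   `FALSE`: life-years are reported undiscounted).
#' @param half_cycle_correction Logical; apply the trapezoid half-cycle
#'   correction to state occupancy when accumulating (default `FALSE`).
#' @return An object of class `model_settings`.
#' @export
model_settings <- function(cycle_length_months = 1, horizon_cycles = 120,
                           wtp_per_qaly = 1290,
                           discount_cost_annual = 0.072,
                           discount_outcome_annual = 0.03,
                           discount_ly = FALSE,
                           half_cycle_correction = FALSE) {
  s <- structure(
    list(cycle_length_months = cycle_length_months,
         horizon_cycles = as.integer(horizon_cycles),
         wtp_per_qaly = wtp_per_qaly,
         discount_cost_annual = discount_cost_annual,
         discount_outcome_annual = discount_outcome_annual,
         discount_ly = isTRUE(discount_ly),
         half_cycle_correction = isTRUE(half_cycle_correction)),
    class = "model_settings")
  if (s$horizon_cycles < 1)
    validation_error("settings: horizon_cycles must be >= 1")
  if (s$wtp_per_qaly <= 0)
    validation_error("settings: wtp_per_qaly must be positive")
  for (d in c("discount_cost_annual", "discount_outcome_annual"))
    if (s[[d]] < 0 || s[[d]] >= 1)
      validation_error("settings: %s must lie in [0, 1)", d)
  s
}

#' @export
print.model_settings <- function(x, ...) {
  cat(sprintf(
    "<model_settings> %d cycles of %g month(s); WTP $%g/QALY; discount %g%% (cost) / %g%% (outcomes)\n",
    x$horizon_cycles, x$cycle_length_months, x$wtp_per_qaly,
    100 * x$discount_cost_annual, 100 * x$discount_outcome_annual))
  invisible(x)
}

#' Construct a treatment strategy arm
#'
#' @param name Arm identifier (e.g. `"drd"`).
#' @param label Human-readable label.
#' @param planned_duration_cycles Planned active-treatment duration in
#'   28-day cycles.
#' @param ae_prob Name of the per-cycle adverse-event probability
#'   parameter for this arm.
#' @param hr_pfs,hr_os Names of hazard-ratio parameters applied to the
#'   baseline hazards (`NULL` for the comparator arm carrying the
#'   baseline).
#' @param drugs List of drug entries, each a list with fields `drug`,
#'   `calendar`, `unit_cost` (a parameter name) and
#'   `units_per_administration`.
#' @return An object of class `strategy_arm`.
#' @export
strategy_arm <- function(name, label = name, planned_duration_cycles,
                         ae_prob, hr_pfs = NULL, hr_os = NULL,
                         drugs = list()) {
  structure(
    list(name = name, label = label,
         planned_duration_cycles = as.integer(planned_duration_cycles),
         ae_prob = ae_prob, hr_pfs = hr_pfs, hr_os = hr_os,
         drugs = drugs),
    class = "strategy_arm")
}

#' @export
print.strategy_arm <- function(x, ...) {
  cat(sprintf("<strategy_arm> %s: %d planned cycles, drugs: %s\n",
              x$label, x$planned_duration_cycles,
              paste(vapply(x$drugs, `[[`, character(1), "drug"),
                    collapse = ", ")))
  invisible(x)
}

.required_config_keys <- c("settings", "parameters", "arms", "costs",
                           "calibration", "psa", "bia")
.required_settings_keys <- c("cycle_length_months", "horizon_cycles",
                             "wtp_per_qaly", "discount_cost_annual",
                             "discount_outcome_annual")

#' Load and validate a model configuration
#'
#' Reads a YAML configuration carrying the parameter table (means and
#' 95% intervals with sampling families), model settings, the two
#' strategy arms with their dosing calendars, cost composition rules,
#' calibration targets, PSA controls and budget-impact inputs.  The
#' shipped default (`default_config_path()`) reproduces the published
#' base case.
#'
#' @param path Path to a YAML configuration file; defaults to the
#'   shipped base-case configuration.
#' @return An object of class `cea_config`: a list with elements
#'   `params` (a `param_set`), `settings` (a `model_settings`), `arms`
#'   (named list of `strategy_arm`), `costs`, `calibration`, `psa`,
#'   `bia` and `path`.
#' @examples
#' cfg <- load_config()
#' cfg$params$u_pfs
#' @export
load_config <- function(path = default_config_path()) {
  if (!file.exists(path))
    config_error("configuration file not found: %s", path)
  raw <- yaml::read_yaml(path)
  missing <- setdiff(.required_config_keys, names(raw))
  if (length(missing))
    config_error("configuration missing key(s): %s",
                 paste(missing, collapse = ", "))
  missing_s <- setdiff(.required_settings_keys, names(raw$settings))
  if (length(missing_s))
    config_error("settings missing key(s): %s",
                 paste(missing_s, collapse = ", "))

  settings <- do.call(model_settings, raw$settings)
  params <- param_set(lapply(raw$parameters, function(p) {
    for (k in c("name", "mean", "family", "role"))
      if (is.null(p[[k]]))
        config_error("parameter entry missing field '%s'", k)
    param_spec(p$name, p$mean,
               if (is.null(p$low) || is.na(p$low)) NA_real_ else p$low,
               if (is.null(p$high) || is.na(p$high)) NA_real_ else p$high,
               p$family, p$role)
  }))
  arms <- lapply(names(raw$arms), function(nm) {
    a <- raw$arms[[nm]]
    for (k in c("planned_duration_cycles", "ae_prob", "drugs"))
      if (is.null(a[[k]]))
        config_error("arm '%s' missing field '%s'", nm, k)
    strategy_arm(nm, label = if (is.null(a$label)) nm else a$label,
                 planned_duration_cycles = a$planned_duration_cycles,
                 ae_prob = a$ae_prob, hr_pfs = a$hr_pfs, hr_os = a$hr_os,
                 drugs = a$drugs)
  })
  names(arms) <- names(raw$arms)

  # every parameter referenced by arms/costs must exist
  refs <- c(vapply(arms, `[[`, character(1), "ae_prob"),
            unlist(lapply(arms, function(a)
              vapply(a$drugs, `[[`, character(1), "unit_cost"))),
            unlist(raw$costs[c("administration_per_cycle",
                               "monitoring_on_treatment",
                               "pfs_post_treatment", "pd_per_cycle",
                               "ae_event")]),
            unlist(lapply(arms, function(a)
              c(a$hr_pfs, a$hr_os))))
  bad <- setdiff(unique(refs), names(params))
  if (length(bad))
    config_error("configuration references unknown parameter(s): %s",
                 paste(bad, collapse = ", "))

  structure(
    list(params = params, settings = settings, arms = arms,
         costs = raw$costs, calibration = raw$calibration,
         psa = raw$psa, bia = raw$bia, path = normalizePath(path)),
    class = "cea_config")
}

#' Path to the shipped base-case configuration
#' @return File path of `default_paper.yaml` inside the installed
#'   package.
#' @export
default_config_path <- function() {
  system.file("extdata", "default_paper.yaml", package = "rrmmcea",
              mustWork = TRUE)
}

#' @export
print.cea_config <- function(x, ...) {
  cat("<cea_config>", x$path, "\n")
  print(x$settings)
  cat(sprintf("  %d parameters, arms: %s\n", length(x$params),
              paste(names(x$arms), collapse = " vs ")))
  invisible(x)
}

#' Write a configuration back to YAML
#'
#' Round-trips with [load_config()]: writing and re-loading yields an
#' identical parameter set.
#'
#' @param config A `cea_config`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "cea_config"))
  raw <- list(
    settings = unclass(config$settings),
    parameters = lapply(unname(config$params), function(p) {
      p <- unclass(p)
      if (p$family == "fixed") { p$low <- NULL; p$high <- NULL }
      p
    }),
    arms = lapply(config$arms, function(a)
      Filter(Negate(is.null),
             unclass(a)[c("label", "planned_duration_cycles", "ae_prob",
                          "hr_pfs", "hr_os", "drugs")])),
    costs = config$costs,
    calibration = config$calibration,
    psa = config$psa,
    bia = config$bia)
  yaml::write_yaml(raw, path)
  invisible(path)
}
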