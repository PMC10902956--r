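# Five-year budget impact of introducing DRd: population projection,
# patient funnel, market-share displacement and scenario spending.
#
# The yearly patient counts are anchored on the first-year printed
# figures and scaled with population growth (counts rounded half to
# even at each funnel stage); per-patient annual costs are back-solved
# from the first-year scenario spending anchors.  No discounting or
# inflation applies within the budget-impact horizon.

#' Project population over the budget-impact horizon
#'
#' Constant-growth projection, `pop[y] = base * (1 + growth)^(y - 1)`,
#' rounded to whole persons.
#'
#' @param base Base-year population.
#' @param growth Annual growth fraction (>= 0).
#' @param years Number of years (including the base year).
#' @return Integer-valued numeric vector of length `years`.
#' @export
project_population <- function(base, growth, years) {
  if (growth < 0) validation_error("population growth must be >= 0")
  stopifnot(years >= 1)
  round(base * (1 + growth)^(seq_len(years) - 1))
}

#' Yearly patient funnel
#'
#' From the projected population to the treated-eligible count:
#' myeloma patients scale with population growth from the base-year
#' anchor; the death-rate adjustment keeps the anchored
#' adjusted-to-total ratio; the eligible fraction selects patients who
#' need the triplet regimens.  Alternatively (`mode = "rates"`) the
#' patient pool is recomputed from the incidence and prevalence rates.
#' Counts are rounded half to even at each stage.
#'
#' @param pop Population vector from [project_population()].
#' @param inputs The `bia` block of a configuration (see
#'   [load_config()]).
#' @param mode `"anchor"` (default; scale the printed base-year counts)
#'   or `"rates"` (recompute from incidence + prevalence).
#' @return Data frame with columns `population`, `mm_patients`,
#'   `adjusted_patients`, `eligible`.
#' @export
patient_funnel <- function(pop, inputs, mode = c("anchor", "rates")) {
  mode <- match.arg(mode)
  mm <- if (mode == "anchor")
    round(inputs$mm_patients_2022 * pop / pop[1])
  else
    round(pop * (inputs$incidence_per_100k +
                   inputs$prevalence_per_100k) / 1e5)
  adjusted <- round(mm * inputs$adjusted_patients_2022 /
                      inputs$mm_patients_2022)
  eligible <- round(adjusted * inputs$eligible_fraction)
  data.frame(population = pop, mm_patients = mm,
             adjusted_patients = adjusted, eligible = eligible)
}

#' Scenario spending and financial impact
#'
#' Scenario 1 is the without-intervention world (comparator holds the
#' whole market); scenario 2 gives the intervention its yearly market
#' share.  The financial impact is the difference.
#'
#' @param eligible Yearly eligible patient counts.
#' @param shares Yearly intervention market shares in `[0, 1]`.
#' @param cost_drd,cost_krd Per-patient annual treatment costs, USD
#'   (> 0).
#' @return A `bia_result` data frame with per-year columns `eligible`,
#'   `share_drd`, `share_krd`, `scenario1_cost`, `scenario2_cost`,
#'   `financial_impact`, `impact_pct`, and attribute `total_impact`.
#' @export
scenario_costs <- function(eligible, shares, cost_drd, cost_krd) {
  stopifnot(length(eligible) == length(shares))
  if (any(shares < 0 | shares > 1))
    validation_error("market shares must lie in [0, 1]")
  if (cost_drd <= 0 || cost_krd <= 0)
    validation_error("per-patient costs must be positive")
  s1 <- eligible * cost_krd
  s2 <- eligible * (shares * cost_drd + (1 - shares) * cost_krd)
  out <- data.frame(
    eligible = eligible, share_drd = shares, share_krd = 1 - shares,
    scenario1_cost = s1, scenario2_cost = s2,
    financial_impact = s2 - s1,
    impact_pct = ifelse(s1 > 0, (s2 - s1) / s1, NA_real_))
  attr(out, "total_impact") <- sum(out$financial_impact)
  class(out) <- c("bia_result", "data.frame")
  out
}

#' Run the full budget impact analysis
#'
#' Projects the population (growth derived from the first two printed
#' years), builds the patient funnel, back-solves per-patient annual
#' costs from the first-year scenario anchors and computes yearly and
#' total financial impact.
#'
#' @param config A [load_config()] result or configuration path.
#' @param mode Funnel mode, see [patient_funnel()].
#' @return A `bia_result` data frame (one row per year, with `year`,
#'   funnel and scenario columns) with attributes `total_impact`,
#'   `cost_drd`, `cost_krd`, `growth`.
#' @examples
#' bia <- run_bia(load_config())
#' attr(bia, "total_impact")
#' @export
run_bia <- function(config = load_config(), mode = c("anchor", "rates")) {
  if (is.character(config)) config <- load_config(config)
  stopifnot(inherits(config, "cea_config"))
  inputs <- config$bia
  for (k in c("population_2022", "population_2023", "years",
              "mm_patients_2022", "adjusted_patients_2022",
              "eligible_fraction", "market_share_drd",
              "scenario1_cost_2022", "scenario2_cost_2022"))
    if (is.null(inputs[[k]]))
      config_error("bia block missing key '%s'", k)
  growth <- inputs$population_2023 / inputs$population_2022 - 1
  pop <- project_population(inputs$population_2022, growth, inputs$years)
  funnel <- patient_funnel(pop, inputs, match.arg(mode))
  shares <- as.numeric(inputs$market_share_drd)
  if (length(shares) != inputs$years)
    config_error("market_share_drd must list %d yearly shares",
                 inputs$years)
  cost_krd <- inputs$scenario1_cost_2022 / funnel$eligible[1]
  cost_drd <- cost_krd +
    (inputs$scenario2_cost_2022 - inputs$scenario1_cost_2022) /
    (funnel$eligible[1] * shares[1])
  sc <- scenario_costs(funnel$eligible, shares, cost_drd, cost_krd)
  start_year <- inputs$start_year %||% 2022
  out <- cbind(year = start_year + seq_len(inputs$years) - 1,
               funnel[setdiff(names(funnel), "eligible")], sc)
  attr(out, "total_impact") <- attr(sc, "total_impact")
  attr(out, "cost_drd") <- cost_drd
  attr(out, "cost_krd") <- cost_krd
  attr(out, "growth") <- growth
  class(out) <- c("bia_result", "data.frame")
  out
}

#' @export
print.bia_result <- function(x, ...) {
  cat("Budget impact analysis\n")
  print.data.frame(cbind(x[setdiff(names(x), "impact_pct")],
                         impact_pct = sprintf("%.1f%%",
                                              100 * x$impact_pct)),
                   row.names = FALSE, digits = 10)
  cat(sprintf("Total financial impact over %d years: $%s\n", nrow(x),
              formatC(attr(x, "total_impact"), format = "f", digits = 0,
                      big.mark = ",")))
  invisible(x)
}
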