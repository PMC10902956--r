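# Incremental cost-effectiveness statistics for two strategy arms.

comparison_error <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("rrmmcea_comparison_error", "rrmmcea_error")))
}

#' Net monetary benefit of an arm
#'
#' `wtp * total_qaly - total_cost`.
#'
#' @param result An `arm_result` (or any list with `total_cost` and
#'   `total_qaly`).
#' @param wtp Willingness-to-pay threshold, USD per QALY (> 0).
#' @return NMB in USD.
#' @examples
#' nmb(list(total_cost = 15370, total_qaly = 1.56), wtp = 1290)
#' @export
nmb <- function(result, wtp) {
  if (wtp <= 0) comparison_error("wtp must be positive")
  wtp * result$total_qaly - result$total_cost
}

#' Incremental cost-effectiveness comparison of two arms
#'
#' Computes incremental cost, QALYs and life-years, the incremental
#' cost-utility ratio (ICUR, USD/QALY), the incremental
#' cost-effectiveness ratio on life-years (USD/LYG), per-arm average
#' cost-effectiveness ratios (ACER) and net monetary benefits, and a
#' dominance classification.  Ratios with a zero effect increment are
#' returned as `NA` and flagged rather than printed as infinities.
#'
#' @param intervention,comparator `arm_result` objects produced under
#'   identical settings.
#' @param wtp Willingness-to-pay threshold, USD per QALY.
#' @return An object of class `cea_comparison`.
#' @examples
#' a <- list(total_cost = 15370, total_qaly = 1.56, total_ly = 5.86)
#' b <- list(total_cost = 15106, total_qaly = 1.28, total_ly = 3.52)
#' cea_compare(a, b, wtp = 1290)
#' @export
cea_compare <- function(intervention, comparator, wtp) {
  if (inherits(intervention, "arm_result") &&
      inherits(comparator, "arm_result") &&
      !identical(unclass(intervention$settings),
                 unclass(comparator$settings)))
    comparison_error("arms were run under different settings")
  if (wtp <= 0) comparison_error("wtp must be positive")
  dc <- intervention$total_cost - comparator$total_cost
  dq <- intervention$total_qaly - comparator$total_qaly
  dl <- intervention$total_ly - comparator$total_ly
  icur <- if (dq != 0) dc / dq else NA_real_
  icer_ly <- if (dl != 0) dc / dl else NA_real_
  dominance <- if (dc < 0 && dq > 0) "intervention-dominant"
    else if (dc > 0 && dq < 0) "intervention-dominated"
    else "none"
  acer <- function(r) if (r$total_qaly != 0)
    r$total_cost / r$total_qaly else NA_real_
  structure(
    list(intervention = if (is.null(intervention$label))
           "intervention" else intervention$label,
         comparator = if (is.null(comparator$label))
           "comparator" else comparator$label,
         wtp = wtp,
         delta_cost = dc, delta_qaly = dq, delta_ly = dl,
         icur = icur, icer_ly = icer_ly,
         ratio_undefined = (dq == 0 || dl == 0),
         acer_intervention = acer(intervention),
         acer_comparator = acer(comparator),
         nmb_intervention = nmb(intervention, wtp),
         nmb_comparator = nmb(comparator, wtp),
         dominance = dominance),
    class = "cea_comparison")
}

#' @export
print.cea_comparison <- function(x, digits = 1, ...) {
  cat(sprintf("<cea_comparison> %s vs %s (WTP $%g/QALY)\n",
              x$intervention, x$comparator, x$wtp))
  fm <- function(v) formatC(v, format = "f", digits = digits,
                            big.mark = ",")
  cat(sprintf("  incremental cost  $%s\n", fm(x$delta_cost)))
  cat(sprintf("  incremental QALY  %.3f   incremental LY %.3f\n",
              x$delta_qaly, x$delta_ly))
  if (!x$ratio_undefined) {
    cat(sprintf("  ICUR $%s/QALY   ICER $%s/LYG\n", fm(x$icur),
                fm(x$icer_ly)))
  } else cat("  ICUR/ICER undefined (zero effect increment)\n")
  cat(sprintf("  NMB  %s: $%s   %s: $%s   difference $%s\n",
              x$intervention, fm(x$nmb_intervention), x$comparator,
              fm(x$nmb_comparator),
              fm(x$nmb_intervention - x$nmb_comparator)))
  if (x$dominance != "none") cat("  dominance:", x$dominance, "\n")
  invisible(x)
}

#' Comparison as a summary table
#'
#' One row per quantity, mirroring the usual base-case results table
#' (cost, QALY, LYG, ICUR, ICER, ACER, NMB).
#'
#' @param comparison A `cea_comparison`.
#' @param intervention,comparator Optional `arm_result`s to fill the
#'   per-arm totals columns.
#' @return A data frame with columns `quantity`, `intervention`,
#'   `comparator`, `increment`.
#' @export
cea_table <- function(comparison, intervention = NULL, comparator = NULL) {
  stopifnot(inherits(comparison, "cea_comparison"))
  g <- function(r, f) if (is.null(r)) NA_real_ else r[[f]]
  data.frame(
    quantity = c("cost", "qaly", "ly", "icur", "icer_ly", "acer", "nmb"),
    intervention = c(g(intervention, "total_cost"),
                     g(intervention, "total_qaly"),
                     g(intervention, "total_ly"), NA, NA,
                     comparison$acer_intervention,
                     comparison$nmb_intervention),
    comparator = c(g(comparator, "total_cost"),
                   g(comparator, "total_qaly"),
                   g(comparator, "total_ly"), NA, NA,
                   comparison$acer_comparator,
                   comparison$nmb_comparator),
    increment = c(comparison$delta_cost, comparison$delta_qaly,
                  comparison$delta_ly, comparison$icur,
                  comparison$icer_ly, NA,
                  comparison$nmb_intervention - comparison$nmb_comparator),
    row.names = NULL)
}
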