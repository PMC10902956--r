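# Sampling distributions for probabilistic sensitivity analysis.
#
# Each two-parameter family is fitted so that its mean equals the
# parameter's point estimate exactly, and the remaining free parameter
# minimises the squared distance between the family's 2.5%/97.5%
# quantiles and the stated 95% interval.  Disutilities (negative by
# convention) are fitted as a beta on the absolute value and negated on
# draw.

fitting_error <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("rrmmcea_fitting_error", "rrmmcea_error")))
}

#' Fit a sampling distribution to a parameter specification
#'
#' Fits the spec's family (beta, gamma or lognormal) by matching the
#' mean exactly and choosing the second parameter by least squares on
#' the 2.5% and 97.5% quantiles against the stated 95% bounds.
#'
#' * beta: mean `m` fixed via `shape1 = m * k`, `shape2 = (1 - m) * k`;
#'   the concentration `k` is optimised.
#' * gamma: mean fixed via `rate = shape / m`; the shape is optimised.
#' * lognormal: mean fixed via `meanlog = log(m) - sdlog^2 / 2`; `sdlog`
#'   is optimised (on log-scale quantiles, where the 95% interval of a
#'   lognormal is symmetric about `meanlog`).
#'
#' Parameters with role `"disutility"` are fitted on `|mean|` with the
#' interval reflected, and draws/quantiles are negated.
#'
#' @param spec A [param_spec()] with `family != "fixed"`; fixed specs
#'   return a degenerate distribution.
#' @return An object of class `sampling_dist` with elements `name`,
#'   `family`, `mean`, `pars` (named fitted parameters) and `sign`
#'   (-1 for disutilities).
#' @examples
#' d <- fit_distribution(param_spec("u_pfs", 0.73, 0.584, 0.876,
#'                                  "beta", "utility"))
#' dist_quantile(d, c(0.025, 0.975))
#' @export
fit_distribution <- function(spec) {
  stopifnot(inherits(spec, "param_spec"))
  sign <- if (spec$role == "disutility") -1 else 1
  m <- sign * spec$mean
  lo <- min(sign * spec$low, sign * spec$high)
  hi <- max(sign * spec$low, sign * spec$high)

  if (spec$family == "fixed")
    return(structure(list(name = spec$name, family = "fixed",
                          mean = spec$mean, pars = list(value = spec$mean),
                          sign = 1),
                     class = "sampling_dist"))

  pars <- switch(spec$family,
    beta = {
      if (m <= 0 || m >= 1)
        fitting_error("'%s': beta mean must lie in (0, 1), got %g",
                      spec$name, m)
      sse <- function(logk) {
        k <- exp(logk)
        (stats::qbeta(0.025, m * k, (1 - m) * k) - lo)^2 +
          (stats::qbeta(0.975, m * k, (1 - m) * k) - hi)^2
      }
      k <- exp(stats::optimize(sse, c(-4, 16))$minimum)
      list(shape1 = m * k, shape2 = (1 - m) * k)
    },
    gamma = {
      if (m <= 0)
        fitting_error("'%s': gamma mean must be positive, got %g",
                      spec$name, m)
      sse <- function(logshape) {
        sh <- exp(logshape)
        (stats::qgamma(0.025, sh, rate = sh / m) - lo)^2 +
          (stats::qgamma(0.975, sh, rate = sh / m) - hi)^2
      }
      sh <- exp(stats::optimize(sse, c(-4, 16))$minimum)
      list(shape = sh, rate = sh / m)
    },
    lognormal = {
      if (m <= 0 || lo <= 0)
        fitting_error("'%s': lognormal requires positive mean and bounds",
                      spec$name)
      z <- stats::qnorm(0.975)
      sse <- function(sdlog) {
        mu <- log(m) - sdlog^2 / 2
        (mu - z * sdlog - log(lo))^2 + (mu + z * sdlog - log(hi))^2
      }
      sdlog <- stats::optimize(sse, c(1e-8, 5))$minimum
      list(meanlog = log(m) - sdlog^2 / 2, sdlog = sdlog)
    },
    fitting_error("'%s': unknown family '%s'", spec$name, spec$family))

  structure(list(name = spec$name, family = spec$family, mean = spec$mean,
                 pars = pars, sign = sign),
            class = "sampling_dist")
}

#' @export
print.sampling_dist <- function(x, ...) {
  cat(sprintf("<sampling_dist> %s: %s(%s)%s\n", x$name, x$family,
              paste(sprintf("%s = %.5g", names(x$pars),
                            unlist(x$pars)), collapse = ", "),
              if (x$sign < 0) " [negated]" else ""))
  invisible(x)
}

#' Draw from a fitted sampling distribution
#'
#' Uses the session RNG; seed at the call site for reproducibility.
#'
#' @param dist A `sampling_dist`.
#' @param n Number of draws.
#' @return Numeric vector of length `n` (negated for disutilities).
#' @export
dist_draw <- function(dist, n) {
  stopifnot(inherits(dist, "sampling_dist"))
  x <- switch(dist$family,
    fixed = rep(dist$pars$value, n),
    beta = stats::rbeta(n, dist$pars$shape1, dist$pars$shape2),
    gamma = stats::rgamma(n, dist$pars$shape, rate = dist$pars$rate),
    lognormal = stats::rlnorm(n, dist$pars$meanlog, dist$pars$sdlog))
  dist$sign * x
}

#' Quantiles of a fitted sampling distribution
#'
#' @param dist A `sampling_dist`.
#' @param p Probabilities.
#' @return Quantiles on the parameter's own scale (for disutilities the
#'   negation reverses tail order, which is handled).
#' @export
dist_quantile <- function(dist, p) {
  stopifnot(inherits(dist, "sampling_dist"))
  pp <- if (dist$sign < 0) 1 - p else p
  x <- switch(dist$family,
    fixed = rep(dist$pars$value, length(p)),
    beta = stats::qbeta(pp, dist$pars$shape1, dist$pars$shape2),
    gamma = stats::qgamma(pp, dist$pars$shape, rate = dist$pars$rate),
    lognormal = stats::qlnorm(pp, dist$pars$meanlog, dist$pars$sdlog))
  dist$sign * x
}

#' Analytic mean of a fitted sampling distribution
#' @param dist A `sampling_dist`.
#' @return The distribution mean on the parameter's own scale.
#' @export
dist_mean <- function(dist) {
  x <- switch(dist$family,
    fixed = dist$pars$value,
    beta = dist$pars$shape1 / (dist$pars$shape1 + dist$pars$shape2),
    gamma = dist$pars$shape / dist$pars$rate,
    lognormal = exp(dist$pars$meanlog + dist$pars$sdlog^2 / 2))
  dist$sign * x
}

#' Fit sampling distributions for every varied parameter in a set
#'
#' @param params A `param_set`.
#' @param skip_roles Roles to leave out (e.g. `"hazard-ratio"` when
#'   hazard ratios are held fixed in the PSA).
#' @return Named list of `sampling_dist` objects, excluding fixed
#'   parameters.
#' @export
fit_all_distributions <- function(params, skip_roles = character()) {
  varied <- Filter(function(s) s$family != "fixed" &&
                     !(s$role %in% skip_roles), params)
  lapply(varied, fit_distribution)
}
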