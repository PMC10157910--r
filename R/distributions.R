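#' Fit a (rescaled) Beta distribution from its mean and standard deviation
#'
#' Closed-form moment inversion for a Beta distribution on `[low, high]`.
#' On the unit interval the shapes are
#' `alpha = m * (m * (1 - m) / s^2 - 1)` and `beta = alpha * (1 - m) / m`,
#' where `m` and `s` are the mean and standard deviation rescaled to `[0, 1]`.
#'
#' @param mean Target mean, strictly inside `(low, high)`.
#' @param sd Target standard deviation (> 0).
#' @param low,high Support bounds of the rescaled Beta (defaults 0, 1).
#' @return Named list with `shape1`, `shape2`, `low`, `high`. The fitted
#'   distribution `low + (high - low) * Beta(shape1, shape2)` has exactly the
#'   requested mean and sd.
#' @examples
#' beta_from_moments(0.785, 0.1962)
#' @export
beta_from_moments <- function(mean, sd, low = 0, high = 1) {
  stopifnot(is.numeric(mean), is.numeric(sd), is.numeric(low), is.numeric(high))
  if (!(low < mean && mean < high))
    stop("beta_from_moments: mean must lie strictly inside (low, high)")
  if (sd <= 0)
    stop("beta_from_moments: sd must be positive")
  m <- (mean - low) / (high - low)
  s <- sd / (high - low)
  if (s^2 >= m * (1 - m))
    stop("beta_from_moments: infeasible moments, sd^2 must be < (mean-low)*(high-mean) after rescaling")
  shape1 <- m * ((m * (1 - m) / s^2) - 1)
  shape2 <- shape1 * (1 - m) / m
  list(shape1 = shape1, shape2 = shape2, low = low, high = high)
}

#' Fit a Gamma distribution from its mean and standard deviation
#'
#' Moment inversion: `shape = mean^2 / sd^2`, `scale = sd^2 / mean`.
#'
#' @param mean Target mean (> 0).
#' @param sd Target standard deviation (> 0).
#' @return Named list with `shape` and `scale`.
#' @examples
#' gamma_from_moments(12588.214, 3147.053)
#' @export
gamma_from_moments <- function(mean, sd) {
  if (!is.numeric(mean) || !is.numeric(sd) || mean <= 0 || sd <= 0)
    stop("gamma_from_moments: mean and sd must be positive")
  list(shape = mean^2 / sd^2, scale = sd^2 / mean)
}

#' Fit a Log-normal distribution from a point estimate and its 95% CI
#'
#' The point estimate is taken as the median (`meanlog = log(point)`) and the
#' log-scale sd is recovered from the CI width:
#' `sdlog = (log(hi95) - log(lo95)) / (2 * qnorm(0.975))`.
#' Intended for published hazard ratios / relative risks.
#'
#' @param point Point estimate (> 0).
#' @param lo95,hi95 95% confidence bounds, `0 < lo95 <= point <= hi95`.
#' @return Named list with `meanlog` and `sdlog`.
#' @examples
#' lognormal_from_ci(1.6, 1.24, 2.06)
#' @export
lognormal_from_ci <- function(point, lo95, hi95) {
  if (!is.numeric(point) || point <= 0 || lo95 <= 0 || hi95 <= 0)
    stop("lognormal_from_ci: point and bounds must be positive")
  if (!(lo95 <= point && point <= hi95))
    stop("lognormal_from_ci: require lo95 <= point <= hi95")
  list(meanlog = log(point),
       sdlog = (log(hi95) - log(lo95)) / (2 * stats::qnorm(0.975)))
}

# Internal distribution descriptor ------------------------------------------
#
# A `sarco_dist` carries the declared family and uncertainty statement of one
# model parameter (as published: sd, 95% CI or plain range) together with the
# fitted distribution parameters, so that sampling, quantiles and round-trip
# serialization all read from one object.

#' Build a distribution descriptor for one model parameter
#'
#' Encapsulates the Table-style uncertainty statement of a parameter
#' (mean plus sd, 95% CI, or a plain range) and fits the declared family:
#' \describe{
#'   \item{fixed}{no uncertainty; the value passes through sampling unchanged.}
#'   \item{beta}{from `mean` and `sd` on `support` (default `[0, 1]`); when a
#'     `range` is supplied instead of an sd, the support becomes the range and
#'     the sd defaults to `(high - low) / (2 * 1.96)`; when a `ci95` is
#'     supplied, the sd is the CI half-width divided by 1.96.}
#'   \item{gamma}{from `mean` and `sd`.}
#'   \item{lognormal}{from the point estimate and its `ci95`.}
#' }
#'
#' @param family One of `"fixed"`, `"beta"`, `"gamma"`, `"lognormal"`.
#' @param mean Base-case (mean / point) value.
#' @param sd Standard deviation, where published.
#' @param ci95 Length-2 numeric, 95% CI, where published.
#' @param range Length-2 numeric plain range (used for discount rates).
#' @param support Length-2 support for a rescaled Beta.
#' @return An object of class `sarco_dist`.
#' @export
make_dist <- function(family = c("fixed", "beta", "gamma", "lognormal"),
                      mean, sd = NULL, ci95 = NULL, range = NULL,
                      support = NULL) {
  family <- match.arg(family)
  stopifnot(is.numeric(mean), length(mean) == 1L)
  for (nm in c("ci95", "range", "support")) {
    v <- get(nm)
    if (!is.null(v) && (!is.numeric(v) || length(v) != 2L || v[1] >= v[2]))
      stop("make_dist: '", nm, "' must be numeric of length 2 with v[1] < v[2]")
  }
  if (!is.null(sd) && (!is.numeric(sd) || length(sd) != 1L || sd <= 0))
    stop("make_dist: 'sd' must be a single positive number")
  d <- list(family = family, mean = mean, sd = sd, ci95 = ci95,
            range = range, support = support, fit = NULL)
  if (family == "beta") {
    sup <- support
    if (is.null(sup)) sup <- if (!is.null(range)) range else c(0, 1)
    s <- sd
    if (is.null(s)) {
      if (!is.null(range)) s <- (range[2] - range[1]) / (2 * 1.96)
      else if (!is.null(ci95)) s <- (ci95[2] - ci95[1]) / (2 * 1.96)
      else stop("make_dist: beta needs one of sd, ci95, range")
    }
    d$fit <- beta_from_moments(mean, s, sup[1], sup[2])
  } else if (family == "gamma") {
    s <- sd
    if (is.null(s)) {
      if (!is.null(ci95)) s <- (ci95[2] - ci95[1]) / (2 * 1.96)
      else stop("make_dist: gamma needs sd or ci95")
    }
    d$fit <- gamma_from_moments(mean, s)
  } else if (family == "lognormal") {
    if (is.null(ci95)) stop("make_dist: lognormal needs ci95")
    d$fit <- lognormal_from_ci(mean, ci95[1], ci95[2])
  }
  structure(d, class = "sarco_dist")
}

#' Sample from a distribution descriptor
#'
#' Uses the current R random number stream; a `fixed` descriptor returns its
#' mean unchanged.
#'
#' @param d A `sarco_dist`.
#' @param n Number of draws.
#' @return Numeric vector of length `n`.
#' @export
sample_dist <- function(d, n = 1L) {
  stopifnot(inherits(d, "sarco_dist"))
  switch(d$family,
    fixed = rep(d$mean, n),
    beta = {
      f <- d$fit
      f$low + (f$high - f$low) * stats::rbeta(n, f$shape1, f$shape2)
    },
    gamma = stats::rgamma(n, shape = d$fit$shape, scale = d$fit$scale),
    lognormal = stats::rlnorm(n, meanlog = d$fit$meanlog, sdlog = d$fit$sdlog)
  )
}

#' Quantile of a distribution descriptor
#'
#' @param d A `sarco_dist`.
#' @param p Probability (vectorised).
#' @return Quantiles; for `fixed`, the mean regardless of `p`.
#' @export
quantile_dist <- function(d, p) {
  stopifnot(inherits(d, "sarco_dist"))
  switch(d$family,
    fixed = rep(d$mean, length(p)),
    beta = {
      f <- d$fit
      f$low + (f$high - f$low) * stats::qbeta(p, f$shape1, f$shape2)
    },
    gamma = stats::qgamma(p, shape = d$fit$shape, scale = d$fit$scale),
    lognormal = stats::qlnorm(p, meanlog = d$fit$meanlog, sdlog = d$fit$sdlog)
  )
}

# Analytic mean / sd of the fitted distribution (used for round-trip checks).
dist_moments <- function(d) {
  stopifnot(inherits(d, "sarco_dist"))
  switch(d$family,
    fixed = c(mean = d$mean, sd = 0),
    beta = {
      f <- d$fit
      m <- f$shape1 / (f$shape1 + f$shape2)
      v <- f$shape1 * f$shape2 /
        ((f$shape1 + f$shape2)^2 * (f$shape1 + f$shape2 + 1))
      c(mean = f$low + (f$high - f$low) * m, sd = (f$high - f$low) * sqrt(v))
    },
    gamma = c(mean = d$fit$shape * d$fit$scale,
              sd = sqrt(d$fit$shape) * d$fit$scale),
    lognormal = {
      m <- exp(d$fit$meanlog + d$fit$sdlog^2 / 2)
      c(mean = m, sd = m * sqrt(exp(d$fit$sdlog^2) - 1))
    }
  )
}

# Default tornado range of a descriptor: published CI / range endpoints when
# given, otherwise the 2.5 / 97.5 percentiles of the fitted distribution.
dist_range <- function(d) {
  stopifnot(inherits(d, "sarco_dist"))
  if (d$family == "fixed") return(c(d$mean, d$mean))
  if (!is.null(d$range)) return(d$range)
  if (!is.null(d$ci95)) return(d$ci95)
  quantile_dist(d, c(0.025, 0.975))
}

#' @export
print.sarco_dist <- function(x, ...) {
  cat(sprintf("<sarco_dist %s> mean %.6g", x$family, x$mean))
  if (!is.null(x$sd)) cat(sprintf(", sd %.6g", x$sd))
  if (!is.null(x$ci95)) cat(sprintf(", 95%% CI [%.6g, %.6g]", x$ci95[1], x$ci95[2]))
  if (!is.null(x$range)) cat(sprintf(", range [%.6g, %.6g]", x$range[1], x$range[2]))
  cat("\n")
  invisible(x)
}
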