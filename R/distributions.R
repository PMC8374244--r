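# Schedule distributions.
#
# Marriage-age, mortality, first-birth-delay and birth-interval schedules are
# piecewise-linear CDFs.  Their default knots are a documented, configurable
# approximation of the cited national sources (demographic & health survey
# marriage ages, 2015 WHO life-table survival, district birth-spacing data):
# the published figures give only curves, so the knots are qualitative
# fixtures and every test targets properties (monotonicity, constraint
# satisfaction, means), not knot values.

#' Piecewise-linear cumulative distribution
#'
#' @param x Numeric knot locations (strictly increasing).
#' @param p Cumulative probabilities at the knots (non-decreasing, first 0,
#'   last 1).
#' @return An object of class \code{plcdf}.
#' @export
plcdf <- function(x, p) {
  stopifnot(length(x) == length(p), !is.unsorted(x, strictly = TRUE),
            !is.unsorted(p), abs(p[1]) < 1e-12,
            abs(p[length(p)] - 1) < 1e-9)
  structure(list(x = as.numeric(x), p = as.numeric(p)), class = "plcdf")
}

#' Evaluate a piecewise-linear CDF
#' @param cdf A [plcdf()] object.
#' @param q Numeric vector of quantiles.
#' @return P(X <= q).
#' @export
plcdf_eval <- function(cdf, q) {
  stats::approx(cdf$x, cdf$p, xout = q, yleft = 0, yright = 1,
                ties = "ordered")$y
}

plcdf_quantile <- function(cdf, u) {
  # invert on the strictly-increasing part
  keep <- !duplicated(cdf$p)
  stats::approx(cdf$p[keep], cdf$x[keep], xout = u, rule = 2,
                ties = "ordered")$y
}

#' Sample from a (possibly truncated) piecewise-linear CDF
#'
#' Draws from the viable region \code{[lo, hi]} of the distribution,
#' renormalised.  An empty viable region falls back to the nearest viable
#' bound (the minimum viable value), with an attribute flagging the
#' degeneracy.
#'
#' @param cdf A [plcdf()] object.
#' @param n Number of draws.
#' @param lo,hi Truncation bounds.
#' @return Numeric vector of draws.
#' @export
sample_plcdf <- function(cdf, n, lo = -Inf, hi = Inf) {
  plo <- plcdf_eval(cdf, lo)
  phi <- plcdf_eval(cdf, hi)
  if (phi - plo < 1e-12) {
    # degenerate viable region: pin to the closest bound inside support
    v <- if (is.finite(lo)) max(lo, cdf$x[1]) else cdf$x[1]
    out <- rep(min(v, cdf$x[length(cdf$x)]), n)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  u <- plo + stats::runif(n) * (phi - plo)
  plcdf_quantile(cdf, u)
}

#' Default demographic schedule distributions
#'
#' Bundles the sex-specific marriage-age and death-age CDFs (years), the
#' first-birth delay CDF (years from marriage), and the birth-interval CDF
#' (years between births).  All knots are configurable fixtures.
#'
#' @return A named list of [plcdf()] objects.
#' @export
default_schedules <- function() {
  list(
    marriage_age = list(
      F = plcdf(c(14, 16, 18, 20, 22, 25, 30, 35, 45),
                c(0, 0.08, 0.30, 0.52, 0.68, 0.85, 0.95, 0.98, 1)),
      M = plcdf(c(16, 18, 20, 22, 25, 28, 32, 38, 50),
                c(0, 0.05, 0.22, 0.42, 0.65, 0.82, 0.93, 0.98, 1))
    ),
    death_age = list(
      F = plcdf(c(0, 1, 5, 15, 30, 45, 55, 65, 75, 85, 95, 105),
                c(0, 0.025, 0.035, 0.045, 0.065, 0.10, 0.16, 0.28,
                  0.50, 0.78, 0.96, 1)),
      M = plcdf(c(0, 1, 5, 15, 30, 45, 55, 65, 75, 85, 95, 105),
                c(0, 0.030, 0.040, 0.055, 0.080, 0.125, 0.20, 0.35,
                  0.58, 0.85, 0.98, 1))
    ),
    first_birth_delay = plcdf(c(0.75, 1, 1.5, 2, 3, 5, 8, 12),
                              c(0, 0.18, 0.45, 0.62, 0.80, 0.92, 0.98, 1)),
    birth_interval = plcdf(c(1, 1.5, 2, 2.5, 3, 4, 5, 7, 10),
                           c(0, 0.05, 0.25, 0.45, 0.62, 0.80, 0.90, 0.97, 1))
  )
}

## ---- fertility scenario pmfs ------------------------------------------------

#' Calibrate a desired-children distribution to a target mean
#'
#' The scenario fertility rates (1.6 and 2.1 children per woman) are turned
#' into probability mass functions over 0..6 lifetime children by
#' exponentially tilting a base preference shape that concentrates mass on
#' one and two children (the stated preference of the next generation of
#' parents), solving the tilt so the mean matches the scenario rate.
#'
#' @param target_mean The scenario fertility rate.
#' @param base Base weights over 0..(length-1) children.
#' @param tol Mean tolerance.
#' @return Named numeric pmf over 0..6 with mean within \code{tol} of target.
#' @export
calibrate_fertility_pmf <- function(target_mean,
                                    base = c(0.08, 0.36, 0.40, 0.10,
                                             0.04, 0.015, 0.005),
                                    tol = 5e-3) {
  k <- seq_along(base) - 1
  mean_at <- function(theta) {
    w <- base * exp(theta * k)
    sum(k * w) / sum(w)
  }
  theta <- stats::uniroot(function(t) mean_at(t) - target_mean,
                          lower = -10, upper = 10, tol = 1e-10)$root
  w <- base * exp(theta * k)
  p <- w / sum(w)
  stopifnot(abs(sum(k * p) - target_mean) < tol)
  names(p) <- k
  p
}

#' Draw desired lifetime children for a fertility scenario
#'
#' @param n Number of draws.
#' @param scenario Fertility rate, 1.6 or 2.1.
#' @param floor Minimum value (current child count); the pmf is truncated
#'   below at this value.
#' @return Integer draws.
#' @export
draw_desired_children <- function(n, scenario = c(1.6, 2.1), floor = 0) {
  scenario <- match.arg(as.character(scenario[1]), c("1.6", "2.1"))
  pmf <- calibrate_fertility_pmf(as.numeric(scenario))
  k <- as.integer(names(pmf))
  keep <- k >= floor
  if (!any(keep)) return(rep(as.integer(floor), n))
  p <- pmf[keep] / sum(pmf[keep])
  kk <- k[keep]
  kk[sample.int(length(kk), n, replace = TRUE, prob = p)]
}

## ---- crop yield multiplier distributions ------------------------------------

#' Calibrate a yield-multiplier distribution to a half-yield recurrence
#' interval
#'
#' Annual yield multipliers follow a scaled beta distribution on
#' \code{[0, support_max]} whose mode is pinned at 1 (the standard yield).
#' The single free shape parameter is solved numerically (bisection via
#' \code{uniroot}) so that \code{P(X <= 0.5) = 1/T}, T being the half-yield
#' recurrence interval in years.
#'
#' @param T_years Recurrence interval (> 2).
#' @param support_max Upper bound of the multiplier support (default 1.25).
#' @return A list with elements \code{alpha}, \code{beta},
#'   \code{support_max}, \code{T_years} and class \code{yield_dist}.
#' @export
calibrate_yield_distribution <- function(T_years, support_max = 1.25) {
  if (T_years <= 2) stop("calibration error: T must exceed 2 years")
  m0 <- 1 / support_max                       # mode on the unit scale
  # mode constraint (alpha-1)/(alpha+beta-2) = m0 solved for alpha
  alpha_of <- function(beta) (1 - 2 * m0 + m0 * beta) / (1 - m0)
  tail <- function(beta) {
    stats::pbeta(0.5 / support_max, alpha_of(beta), beta) - 1 / T_years
  }
  # tail mass decreases as beta grows; bracket the root
  lo <- 1 + 1e-6; hi <- 2
  while (tail(hi) > 0 && hi < 1e6) hi <- hi * 2
  if (tail(lo) < 0 || tail(hi) > 0)
    stop("calibration error: half-yield constraint infeasible")
  beta <- stats::uniroot(tail, c(lo, hi), tol = 1e-6)$root
  structure(list(alpha = alpha_of(beta), beta = beta,
                 support_max = support_max, T_years = T_years),
            class = "yield_dist")
}

#' Sample annual yield multipliers
#' @param dist A [calibrate_yield_distribution()] object.
#' @param n Number of annual draws.
#' @return Numeric multipliers in \code{[0, support_max]} with mode 1.
#' @export
sample_yield_multipliers <- function(dist, n) {
  stats::rbeta(n, dist$alpha, dist$beta) * dist$support_max
}

## ---- exponential smoothing ---------------------------------------------------

#' Exponentially smoothed yield forecast
#'
#' Simple exponential smoothing over the trailing yield window (most recent
#' observation last and most heavily weighted):
#' \eqn{S_t = \alpha y_t + (1-\alpha) S_{t-1}}, initialised at the oldest
#' observation.
#'
#' @param history Numeric vector of past multipliers, oldest first
#'   (normally the last ten years).
#' @param alpha Smoothing constant in (0, 1].
#' @return The forecast multiplier (the final smoothed state).
#' @export
forecast_yields <- function(history, alpha = 0.3) {
  stopifnot(length(history) >= 1, alpha > 0, alpha <= 1)
  s <- history[1]
  for (y in history[-1]) s <- alpha * y + (1 - alpha) * s
  s
}
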