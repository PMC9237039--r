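#' Double-logistic seasonal curve
#'
#' The seasonal greenness/productivity model used throughout the package:
#' \deqn{y(t) = b + a\left[\frac{1}{1+e^{-k(t-m)}} - \frac{1}{1+e^{-r(t-n)}}\right]}
#' a rising logistic (spring, rate `k`, inflection `m`) minus a second
#' rising logistic (autumn, rate `r`, inflection `n`), so the curve rises
#' from the winter background `b` to a summer plateau of approximately
#' `a + b` and falls back to `b`. `a` is the seasonal amplitude and `b` the
#' background (dormant-season) value.
#'
#' @param t time in days (any numeric grid).
#' @param a seasonal amplitude (> 0), curve units.
#' @param b background value, curve units.
#' @param k spring rate (1/day, > 0).
#' @param m spring inflection (day of year).
#' @param r autumn rate (1/day, > 0).
#' @param n autumn inflection (day of year, > m).
#' @return curve values at `t`; `double_logistic_deriv2()` returns the
#'   analytic second derivative.
#' @examples
#' t <- 1:365
#' y <- double_logistic(t, a = 0.5, b = 0.15, k = 0.1, m = 120, r = 0.1, n = 280)
#' range(y)  # ~ 0.15 to ~ 0.65
#' @export
double_logistic <- function(t, a, b, k, m, r, n) {
  b + a * (plogis_rate(t, k, m) - plogis_rate(t, r, n))
}

#' @rdname double_logistic
#' @export
double_logistic_deriv2 <- function(t, a, b, k, m, r, n) {
  a * (logistic_d2(t, k, m) - logistic_d2(t, r, n))
}

# rising logistic 1/(1+exp(-k(t-m))), numerically safe in both tails
plogis_rate <- function(t, k, m) {
  stats::plogis(k * (t - m))
}

# second derivative of the rising logistic: k^2 L(1-L)(1-2L)
logistic_d2 <- function(t, k, m) {
  L <- plogis_rate(t, k, m)
  k^2 * L * (1 - L) * (1 - 2 * L)
}

# offset (days) between a rising logistic's inflection and the maximum of
# its second derivative: the maximum sits at m - log(2 + sqrt(3))/k
logistic_d2max_offset <- function(k) log(2 + sqrt(3)) / k

# day (relative to m) at which the rising limb b + a*L reaches a given
# absolute level y: m + log(p/(1-p))/k with p = (y-b)/a
logistic_rise_crossing <- function(level, a, b, k) {
  p <- (level - b) / a
  stopifnot(p > 0, p < 1)
  stats::qlogis(p) / k
}
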