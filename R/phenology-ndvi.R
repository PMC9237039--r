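#' Savitzky-Golay smoothing of a series
#'
#' Local least-squares polynomial smoothing with the given window and
#' polynomial order; output length equals input length, with the leading
#' and trailing half-windows handled by the polynomial fit over the first
#' and last full windows. Used to clean composite NDVI series of
#' atmospheric and sensor noise before curve fitting.
#'
#' @param series a [daily_series()] (any cadence; samples are assumed
#'   evenly spaced in time).
#' @param window odd window length (> `polyorder`).
#' @param polyorder polynomial order.
#' @return the series with smoothed `value`.
#' @export
savitzky_golay <- function(series, window = 7L, polyorder = 4L) {
  if (window %% 2L != 1L) stop("invalid-config: window must be odd", call. = FALSE)
  if (polyorder >= window)
    stop("invalid-config: polyorder must be < window", call. = FALSE)
  if (nrow(series) < window)
    stop("invalid-config: series shorter than window", call. = FALSE)
  s <- series[order(series$year, series$doy), , drop = FALSE]
  s$value <- as.numeric(signal::sgolayfilt(s$value, p = polyorder, n = window))
  s
}

#' Fit the double-logistic seasonal model to one year of data
#'
#' Nonlinear least squares of [double_logistic()] against a year's
#' observations. Starting values: background `b0` = 5th percentile,
#' amplitude `a0` = 95th - 5th percentile, inflections `m0`/`n0` at the
#' first and last half-amplitude crossings, rates `k0 = r0 = 0.1` per
#' day; box bounds keep `a, k, r > 0` and `m, n` within the year. Up to
#' `restarts` refits with jittered starting values are attempted on
#' non-convergence (or when the fit collapses to `m >= n`).
#'
#' @param series a [daily_series()] of e.g. NDVI.
#' @param year which year to fit (>= 8 observations required).
#' @param restarts maximum jittered restarts (default 5).
#' @return a `double_logistic_fit` list: `params` (named vector `a, b, k,
#'   m, r_autumn, n`), `rss`, `converged`, `n_obs`, `year`.
#' @export
fit_double_logistic <- function(series, year, restarts = 5L) {
  s <- year_slice(series, year)
  s <- s[is.finite(s$value), , drop = FALSE]
  if (nrow(s) < 8)
    stop("invalid-config: need >= 8 observations in the year", call. = FALSE)
  t <- s$doy; y <- s$value
  b0 <- quantile(y, 0.05, names = FALSE)
  a0 <- max(quantile(y, 0.95, names = FALSE) - b0, 1e-6)
  half <- b0 + a0 / 2
  above <- which(y >= half)
  m0 <- if (length(above)) t[min(above)] else 120
  n0 <- if (length(above)) t[max(above)] else 280
  if (n0 - m0 < 30) { m0 <- max(m0 - 15, 1); n0 <- min(n0 + 15, 365) }
  start0 <- c(a = a0, b = b0, k = 0.1, m = m0, r_autumn = 0.1, n = n0)
  lower <- c(a = 1e-8, b = -Inf, k = 1e-4, m = 1, r_autumn = 1e-4, n = 1)
  upper <- c(a = Inf, b = Inf, k = 5, m = 365, r_autumn = 5, n = 365)
  best <- NULL
  for (i in 0:restarts) {
    start <- start0
    if (i > 0) {  # deterministic jitter ladder, no RNG involvement
      f <- c(0.8, 1.25, 0.6, 1.6, 1)[((i - 1) %% 5) + 1]
      start[c("k", "r_autumn")] <- start0[c("k", "r_autumn")] * f
      start["m"] <- max(1, min(364, start0["m"] + c(-10, 10, -20, 20, 0)[((i - 1) %% 5) + 1]))
      start["n"] <- max(start["m"] + 1, min(365, start0["n"] + c(10, -10, 20, -20, 0)[((i - 1) %% 5) + 1]))
    }
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ double_logistic(t, a, b, k, m, r_autumn, n),
        start = as.list(start), lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      p <- coef(fit)
      if (p["m"] < p["n"]) {
        rss <- sum(resid(fit)^2)
        if (is.null(best) || rss < best$rss)
          best <- list(params = p, rss = rss)
      }
    }
    if (!is.null(best) && i >= 0 && !is.null(best$params)) break
  }
  structure(list(params = if (!is.null(best)) best$params else
                   setNames(rep(NA_real_, 6), names(start0)),
                 rss = if (!is.null(best)) best$rss else NA_real_,
                 converged = !is.null(best), n_obs = nrow(s), year = year),
            class = "double_logistic_fit")
}

#' @export
print.double_logistic_fit <- function(x, ...) {
  cat("double-logistic fit, year", x$year,
      if (x$converged) "(converged)" else "(FAILED)", "\n")
  if (x$converged) print(round(x$params, 4))
  invisible(x)
}

#' Transition dates from a fitted double logistic (second-derivative rule)
#'
#' Evaluates the fitted curve's analytic second derivative on a 0.1-day
#' grid over the year and returns SOS as the first and EOS as the second
#' local maximum (only maxima with positive curvature value count; the
#' flat summer plateau produces none). For a single rising logistic the
#' first maximum sits at `m - log(2 + sqrt(3))/k`, i.e. SOS leads the
#' spring inflection and EOS lags the autumn inflection by that offset.
#'
#' @param fit a `double_logistic_fit` (or a named params vector).
#' @return list with `sos`, `eos` (integer DOY, `NA` on failure),
#'   `sos_exact`, `eos_exact` (the unrounded grid positions) and `ok`.
#' @export
extract_sos_eos_from_fit <- function(fit) {
  p <- if (inherits(fit, "double_logistic_fit")) fit$params else fit
  failed <- list(sos = NA_integer_, eos = NA_integer_,
                 sos_exact = NA_real_, eos_exact = NA_real_, ok = FALSE)
  if (inherits(fit, "double_logistic_fit") && !fit$converged) return(failed)
  grid <- seq(1, DAYS_PER_YEAR, by = 0.1)
  d2 <- double_logistic_deriv2(grid, p[["a"]], p[["b"]], p[["k"]], p[["m"]],
                               p[["r_autumn"]], p[["n"]])
  i <- 2:(length(grid) - 1)
  is_max <- d2[i] > d2[i - 1] & d2[i] >= d2[i + 1] & d2[i] > 1e-9 * max(abs(d2))
  peaks <- grid[i][is_max]
  if (length(peaks) < 2) return(failed)
  list(sos = as.integer(floor(peaks[1] + 0.5)),
       eos = as.integer(floor(peaks[2] + 0.5)),
       sos_exact = peaks[1], eos_exact = peaks[2], ok = TRUE)
}

#' NDVI phenology for one site: smooth, fit, extract
#'
#' Convenience wrapper chaining [savitzky_golay()], [fit_double_logistic()]
#' and [extract_sos_eos_from_fit()] for every year of a series.
#'
#' @param series NDVI [daily_series()] (daily or 15-day cadence).
#' @param sg_window,sg_polyorder Savitzky-Golay settings.
#' @return data.frame `site_id, year, source, sos, eos, flag`.
#' @export
extract_ndvi_phenology <- function(series, sg_window = 7L, sg_polyorder = 4L) {
  sm <- savitzky_golay(series, sg_window, sg_polyorder)
  years <- sort(unique(sm$year))
  rows <- lapply(years, function(y) {
    fit <- tryCatch(fit_double_logistic(sm, y), error = function(e) NULL)
    if (is.null(fit) || !fit$converged)
      return(data.frame(site_id = series$site_id[1], year = y, source = "ndvi",
                        sos = NA_integer_, eos = NA_integer_, flag = "fit-failure"))
    ext <- extract_sos_eos_from_fit(fit)
    data.frame(site_id = series$site_id[1], year = y, source = "ndvi",
               sos = ext$sos, eos = ext$eos,
               flag = if (ext$ok) "ok" else "extraction-failure")
  })
  do.call(rbind, rows)
}
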