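#' Green chromatic coordinate
#'
#' `Gcc = G / (R + G + B)` from mean red, green and blue digital numbers
#' of a canopy image.
#'
#' @param r,g,b mean digital numbers (all >= 0, not all zero); vectorised.
#' @return Gcc in `[0, 1]`.
#' @examples
#' gcc(50, 100, 50)  # 0.5
#' @export
gcc <- function(r, g, b) {
  tot <- r + g + b
  if (any(tot <= 0)) stop("undefined-ratio: R + G + B must be > 0", call. = FALSE)
  g / tot
}

#' 90th-percentile composite of a daily Gcc series
#'
#' Within each non-overlapping 3-day window takes the 90th percentile of
#' the daily values (the Gcc_90 convention, which suppresses low outliers
#' from weather and exposure), assigning the composite to the last day of
#' the window, consistent with where the upper quantile of a rising
#' segment sits.
#'
#' @param series a daily Gcc [daily_series()].
#' @param window_days compositing window (default 3).
#' @return a [daily_series()] at `window_days` cadence.
#' @export
composite_gcc90 <- function(series, window_days = 3L) {
  out <- lapply(split(series, series$year), function(s) {
    s <- s[order(s$doy), , drop = FALSE]
    bin <- (s$doy - 1L) %/% window_days
    v <- tapply(s$value, bin, quantile, probs = 0.9, names = FALSE, na.rm = TRUE)
    d <- tapply(s$doy, bin, max)
    data.frame(year = s$year[1], doy = as.integer(d), value = as.numeric(v))
  })
  out <- do.call(rbind, out)
  daily_series(series$site_id[1], out$year, out$doy, out$value)
}

#' Start of season from a Gcc series (50%-amplitude rule)
#'
#' Composites the daily Gcc to its 3-day 90th-percentile curve
#' ([composite_gcc90()]), applies a running-median smooth, takes the
#' year's baseline and peak as the 10th and 90th percentiles of the
#' smoothed composite, and returns the first day of the spring segment
#' (up to the seasonal maximum) on which the curve reaches
#' `baseline + 0.5 * (peak - baseline)`, linearly interpolated between
#' the bracketing observations and rounded to the nearest day.
#'
#' @param gcc_series a daily Gcc [daily_series()].
#' @param year which year to extract.
#' @param min_amplitude minimum peak - baseline separation below which the
#'   curve is declared seasonless.
#' @param smooth_k running-median width (odd; 1 disables smoothing).
#' @return SOS as integer day of year.
#' @export
gcc_sos <- function(gcc_series, year, min_amplitude = 1e-3, smooth_k = 3L) {
  comp <- composite_gcc90(year_slice(gcc_series, year))
  v <- comp$value
  if (smooth_k > 1L) v <- as.numeric(stats::runmed(v, smooth_k))
  baseline <- quantile(v, 0.1, names = FALSE)
  peak <- quantile(v, 0.9, names = FALSE)
  if (peak - baseline < min_amplitude)
    stop("no-seasonality: flat Gcc curve (amplitude ",
         signif(peak - baseline, 3), ")", call. = FALSE)
  thr <- baseline + 0.5 * (peak - baseline)
  spring <- seq_len(which.max(v))
  cross <- which(v[spring] >= thr)
  if (length(cross) == 0)
    stop("no-seasonality: threshold never reached in spring segment",
         call. = FALSE)
  i <- min(cross)
  if (i == 1) return(as.integer(comp$doy[1]))
  # linear interpolation between the bracketing composite observations
  d0 <- comp$doy[i - 1]; d1 <- comp$doy[i]
  v0 <- v[i - 1]; v1 <- v[i]
  day <- if (v1 > v0) d0 + (d1 - d0) * (thr - v0) / (v1 - v0) else d1
  as.integer(floor(day + 0.5))
}
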