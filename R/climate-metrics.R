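#' Growing-season mean of a daily series
#'
#' Arithmetic mean over the half-open DOY window (default May-September,
#' DOY `[121, 274)`), the window used for T_GS, the previous-growing-season
#' mean temperature. Years with less than `min_coverage` of the window
#' observed yield `NA` with a flag.
#'
#' @param series a [daily_series()].
#' @param year which year.
#' @param doy_window half-open `[start, end)` DOY window.
#' @param min_coverage minimum fraction of window days present (default 0.8).
#' @return scalar mean (with attribute `flag = "low-coverage"` and value
#'   `NA` when coverage is insufficient).
#' @export
growing_season_mean <- function(series, year, doy_window = c(GS_DOY_START, GS_DOY_END),
                                min_coverage = 0.8) {
  s <- year_slice(series, year)
  w <- s[s$doy >= doy_window[1] & s$doy < doy_window[2], , drop = FALSE]
  n_expected <- doy_window[2] - doy_window[1]
  n_present <- sum(is.finite(w$value))
  if (n_present < min_coverage * n_expected) {
    out <- NA_real_
    attr(out, "flag") <- "low-coverage"
    return(out)
  }
  mean(w$value[is.finite(w$value)])
}

#' Normalized anomalies (z-scores) of a site record
#'
#' Centers a by-year record on its long-term mean and scales by its
#' sample SD, so anomalies of different variables are comparable and a
#' regression slope between them is unit-free. Requires at least 3
#' non-missing years and positive SD.
#'
#' @param values numeric by-year vector (NAs allowed, preserved).
#' @return z-scored vector; errors with class hint on zero SD.
#' @export
normalize_anomalies <- function(values) {
  ok <- is.finite(values)
  if (sum(ok) < 3) stop("empty-input: need >= 3 non-missing years", call. = FALSE)
  s <- sd(values[ok])
  if (s == 0) stop("zero-sd: constant record cannot be normalized", call. = FALSE)
  (values - mean(values[ok])) / s
}

# slice a multi-year daily series over a (year, doy) .. (year, doy) window,
# inclusive start, exclusive end, on the fixed 365-day calendar
window_slice <- function(series, start_year, start_doy, end_year, end_doy) {
  t0 <- start_year * DAYS_PER_YEAR + start_doy
  t1 <- end_year * DAYS_PER_YEAR + end_doy
  tt <- series$year * DAYS_PER_YEAR + series$doy
  stopifnot(t0 < t1)
  series[tt >= t0 & tt < t1, , drop = FALSE]
}

#' Chilling and forcing accumulation over the dormancy window
#'
#' Both run over the window from November 1 of the previous year (DOY
#' 305) to the site(-species) mean SOS of the focal year. Chilling units
#' are the count of days with daily mean temperature in `[0, 5]` degrees C
#' (inclusive bounds); forcing units are growing degree days,
#' `sum(max(T - base, 0))`, accumulating only strictly above the 5 degree C
#' base. Windows with less than `min_coverage` of their days present
#' yield `NA` (no proration of partial sums).
#'
#' @param temp daily temperature [daily_series()].
#' @param year focal year (window starts Nov 1 of `year - 1`).
#' @param mean_sos site(-species) mean SOS (DOY) ending the window
#'   (exclusive).
#' @param chill_range inclusive temperature range for a chilling day.
#' @param base forcing base temperature (deg C).
#' @param min_coverage minimum fraction of window days present.
#' @return scalar count (chilling) or degree-day sum (forcing); `NA` with
#'   flag on insufficient coverage.
#' @export
chilling_units <- function(temp, year, mean_sos, chill_range = c(0, 5),
                           min_coverage = 0.9) {
  w <- dormancy_window(temp, year, mean_sos, min_coverage)
  if (is.null(w)) { out <- NA_real_; attr(out, "flag") <- "low-coverage"; return(out) }
  sum(w$value >= chill_range[1] & w$value <= chill_range[2])
}

#' @rdname chilling_units
#' @export
forcing_units <- function(temp, year, mean_sos, base = 5, min_coverage = 0.9) {
  w <- dormancy_window(temp, year, mean_sos, min_coverage)
  if (is.null(w)) { out <- NA_real_; attr(out, "flag") <- "low-coverage"; return(out) }
  sum(pmax(w$value - base, 0))
}

dormancy_window <- function(temp, year, mean_sos, min_coverage) {
  w <- window_slice(temp, year - 1L, 305L, year, as.integer(round(mean_sos)))
  n_expected <- (DAYS_PER_YEAR - 305L) + as.integer(round(mean_sos))
  w <- w[is.finite(w$value), , drop = FALSE]
  if (nrow(w) < min_coverage * n_expected) return(NULL)
  w
}

#' Bilinear interpolation of a gridded climate field at a point
#'
#' Standard bilinear weighting of the four grid nodes surrounding
#' (lat, lon) at the requested time slice. Points outside the grid hull
#' raise an out-of-domain error; no extrapolation is performed. Sites at
#' a node reproduce the node value exactly, and fields linear in lat and
#' lon are interpolated exactly.
#'
#' @param grid a `climate_grid` (see [generate_climate_grid()]).
#' @param lat,lon point coordinates in degrees.
#' @param time which time slice (matched against `grid$times`).
#' @return interpolated value (scalar).
#' @export
bilinear_at <- function(grid, lat, lon, time = grid$times[1]) {
  ti <- match(time, grid$times)
  if (is.na(ti)) stop("out-of-domain: time slice not in grid", call. = FALSE)
  if (lat < min(grid$lats) || lat > max(grid$lats) ||
      lon < min(grid$lons) || lon > max(grid$lons))
    stop("out-of-domain: point outside grid hull (no extrapolation)",
         call. = FALSE)
  Z <- grid$values[ti, , ]  # lat x lon
  i <- findInterval(lat, grid$lats, rightmost.closed = TRUE)
  j <- findInterval(lon, grid$lons, rightmost.closed = TRUE)
  la0 <- grid$lats[i]; la1 <- grid$lats[i + 1L]
  lo0 <- grid$lons[j]; lo1 <- grid$lons[j + 1L]
  u <- if (is.na(la1) || la1 == la0) 0 else (lat - la0) / (la1 - la0)
  v <- if (is.na(lo1) || lo1 == lo0) 0 else (lon - lo0) / (lo1 - lo0)
  z00 <- Z[i, j]
  z10 <- if (u > 0) Z[i + 1L, j] else z00
  z01 <- if (v > 0) Z[i, j + 1L] else z00
  z11 <- if (u > 0 && v > 0) Z[i + 1L, j + 1L] else if (u > 0) z10 else z01
  (1 - u) * (1 - v) * z00 + u * (1 - v) * z10 + (1 - u) * v * z01 + u * v * z11
}

#' Build matched anomaly pairs: current SOS vs previous-season predictor
#'
#' For one site record, pairs the normalized anomaly of year `y`'s SOS
#' with the normalized anomaly of the predictor (T_GS, GPPmax or mean
#' GPP) of year `y - 1`, the lag through which the previous growing
#' season can influence the next spring. Anomalies are z-scored over the
#' matched years; rows with a missing member are dropped listwise.
#'
#' @param sos_by_year data.frame `year, sos`.
#' @param predictor_by_year data.frame `year, value` of the predictor.
#' @param predictor_name label stored with the pairs.
#' @return data.frame `year, sos_anom, predictor_anom, sos_raw,
#'   predictor_raw` (raw columns retained for back-transforming slopes).
#' @export
anomaly_pairs <- function(sos_by_year, predictor_by_year,
                          predictor_name = "T_GS") {
  prev <- predictor_by_year
  prev$year <- prev$year + 1L  # predictor of year y-1 meets SOS of year y
  m <- merge(sos_by_year, prev, by = "year")
  m <- m[is.finite(m$sos) & is.finite(m$value), , drop = FALSE]
  if (nrow(m) < 3) return(NULL)
  if (sd(m$sos) == 0 || sd(m$value) == 0) return(NULL)
  data.frame(year = m$year,
             sos_anom = normalize_anomalies(m$sos),
             predictor_anom = normalize_anomalies(m$value),
             sos_raw = m$sos, predictor_raw = m$value,
             predictor_name = predictor_name)
}
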