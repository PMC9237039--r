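#' Singular spectrum analysis smoothing
#'
#' Embeds the series in a trajectory (Hankel) matrix of the given window,
#' takes its singular value decomposition, and reconstructs the series
#' from the leading components by diagonal averaging. Used to denoise
#' daily GPP before threshold-based phenology extraction; the leading
#' components capture the smooth seasonal cycle while noise spreads over
#' the trailing ones.
#'
#' Internal gaps of up to 30 consecutive missing days are filled by
#' linear interpolation before embedding; longer gaps raise an error
#' (the caller must fill or drop the year).
#'
#' @param series a daily [daily_series()].
#' @param window_length embedding window in days (< series length / 2).
#' @param n_components leading components kept (<= `window_length`).
#' @return the series with smoothed `value`.
#' @export
ssa_smooth <- function(series, window_length = 60L, n_components = 4L) {
  s <- series[order(series$year, series$doy), , drop = FALSE]
  x <- s$value
  N <- length(x)
  if (window_length >= N / 2)
    stop("invalid-config: window_length must be < series length / 2", call. = FALSE)
  if (n_components > window_length)
    stop("invalid-config: n_components must be <= window_length", call. = FALSE)
  if (anyNA(x)) {
    gap <- rle(is.na(x))
    if (any(gap$lengths[gap$values] > 30))
      stop("gap-error: missing run exceeds 30 consecutive days", call. = FALSE)
    x <- approx(seq_len(N)[!is.na(x)], x[!is.na(x)], xout = seq_len(N),
                rule = 2)$y
  }
  L <- as.integer(window_length)
  K <- N - L + 1L
  X <- matrix(x[outer(seq_len(L), 0:(K - 1), `+`)], nrow = L)
  sv <- svd(X, nu = n_components, nv = n_components)
  Xr <- sv$u %*% (sv$d[seq_len(n_components)] * t(sv$v))
  # diagonal (anti-diagonal) averaging back to a series
  out <- numeric(N); cnt <- numeric(N)
  for (j in seq_len(K)) {
    idx <- j:(j + L - 1L)
    out[idx] <- out[idx] + Xr[, j]
    cnt[idx] <- cnt[idx] + 1
  }
  s$value <- out / cnt
  s
}

#' Start of season from smoothed GPP (15%-of-maximum threshold)
#'
#' The spring threshold is 15% of the multi-year maximum of the smoothed
#' daily GPP. SOS is the first day in the year's first half on which the
#' smoothed GPP rises above the threshold and stays above it for at least
#' `persistence` consecutive days, which excludes single-day noise
#' upcrossings.
#'
#' @param smoothed_gpp an [ssa_smooth()]-smoothed daily GPP series.
#' @param year which year to extract.
#' @param multi_year_max maximum smoothed daily GPP across all record
#'   years (> 0).
#' @param threshold_frac threshold as a fraction of `multi_year_max`
#'   (default 0.15).
#' @param persistence required consecutive days above threshold.
#' @return SOS as integer day of year, or `NA` (with a "no-season"
#'   attribute) when GPP never sustains the threshold.
#' @export
gpp_sos <- function(smoothed_gpp, year, multi_year_max,
                    threshold_frac = 0.15, persistence = 5L) {
  stopifnot(multi_year_max > 0)
  s <- year_slice(smoothed_gpp, year)
  thr <- threshold_frac * multi_year_max
  half <- s[s$doy <= ceiling(DAYS_PER_YEAR / 2), , drop = FALSE]
  above <- half$value > thr
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  ok <- which(runs$values & runs$lengths >= persistence)
  if (length(ok) == 0) {
    out <- NA_integer_
    attr(out, "flag") <- "no-season"
    return(out)
  }
  as.integer(half$doy[starts[ok[1]]])
}

#' Annual carbon-uptake metrics from smoothed GPP
#'
#' `gpp_max` is the year's maximum smoothed daily GPP; `gpp_mean_gs` is
#' the mean smoothed daily GPP over the May-September growing season
#' (DOY 121-273 on the 365-day calendar). Years without full
#' May-September daily coverage are dropped with a flag.
#'
#' @param smoothed_gpp an [ssa_smooth()]-smoothed daily GPP series.
#' @param year which year to summarise.
#' @return data.frame `site_id, year, gpp_max, gpp_mean_gs, flag`.
#' @export
carbon_metrics <- function(smoothed_gpp, year) {
  s <- year_slice(smoothed_gpp, year)
  gs <- s[s$doy >= GS_DOY_START & s$doy < GS_DOY_END, , drop = FALSE]
  n_gs <- GS_DOY_END - GS_DOY_START
  if (nrow(gs) < n_gs || anyNA(gs$value))
    return(data.frame(site_id = s$site_id[1], year = year,
                      gpp_max = NA_real_, gpp_mean_gs = NA_real_,
                      flag = "missing-growing-season"))
  data.frame(site_id = s$site_id[1], year = year,
             gpp_max = max(s$value, na.rm = TRUE),
             gpp_mean_gs = mean(gs$value), flag = "ok")
}

#' GPP phenology and carbon metrics for one site
#'
#' Chains [ssa_smooth()], [gpp_sos()] and [carbon_metrics()] over all
#' years of a daily GPP series, using the multi-year maximum of the
#' smoothed curve for the spring threshold.
#'
#' @param series daily GPP [daily_series()].
#' @param ssa_window,ssa_components SSA settings.
#' @param threshold_frac,persistence threshold rule settings.
#' @return data.frame `site_id, year, source, sos, eos, gpp_max,
#'   gpp_mean_gs, flag` (`eos` is not defined by the threshold rule and
#'   is `NA`).
#' @export
extract_gpp_phenology <- function(series, ssa_window = 60L, ssa_components = 4L,
                                  threshold_frac = 0.15, persistence = 5L) {
  sm <- ssa_smooth(series, ssa_window, ssa_components)
  mmax <- max(sm$value, na.rm = TRUE)
  years <- sort(unique(sm$year))
  rows <- lapply(years, function(y) {
    sos <- gpp_sos(sm, y, mmax, threshold_frac, persistence)
    cm <- carbon_metrics(sm, y)
    data.frame(site_id = sm$site_id[1], year = y, source = "gpp",
               sos = as.integer(sos), eos = NA_integer_,
               gpp_max = cm$gpp_max, gpp_mean_gs = cm$gpp_mean_gs,
               flag = if (is.na(sos)) "no-season" else cm$flag)
  })
  do.call(rbind, rows)
}
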