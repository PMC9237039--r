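#' Site configuration for the synthetic generator
#'
#' @param site_id site label.
#' @param lat,lon coordinates in degrees.
#' @param n_years number of years simulated (>= 2).
#' @param start_year first calendar year.
#' @param species_or_pft species or plant-functional-type label.
#' @return a `site_config` list.
#' @export
site_config <- function(site_id, lat = 50, lon = 10, n_years = 15,
                        start_year = 2000, species_or_pft = "DBF") {
  if (n_years < 2) stop("invalid-config: n_years must be >= 2", call. = FALSE)
  if (lat < -90 || lat > 90) stop("invalid-config: lat out of [-90, 90]", call. = FALSE)
  if (lon < -180 || lon > 180) stop("invalid-config: lon out of [-180, 180]", call. = FALSE)
  structure(list(site_id = as.character(site_id), lat = lat, lon = lon,
                 n_years = as.integer(n_years), start_year = as.integer(start_year),
                 species_or_pft = species_or_pft),
            class = "site_config")
}

# run code with a locally-set RNG seed, restoring global state afterwards
local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Generate a synthetic daily temperature series
#'
#' Daily mean temperature as a seasonal cosine (peaking at DOY 200) plus a
#' linear warming trend and white noise:
#' `T(d) = mean_annual + amplitude * cos(2*pi*(doy - 200)/365) +
#' warming_trend * year_index/10 + N(0, noise_sd^2)`,
#' with `year_index` counted from 0 in the first year, so `warming_trend`
#' is in degrees C per decade.
#'
#' @param site a [site_config()].
#' @param mean_annual annual mean temperature (deg C).
#' @param amplitude seasonal half-range (deg C, > 0).
#' @param warming_trend linear trend (deg C per decade).
#' @param noise_sd daily noise SD (deg C, >= 0).
#' @param seed integer seed; identical seed and config give identical output.
#' @return a [daily_series()] of daily mean temperature.
#' @export
generate_temperature <- function(site, mean_annual = 8, amplitude = 10,
                                 warming_trend = 0, noise_sd = 5, seed = NULL) {
  stopifnot(inherits(site, "site_config"))
  if (amplitude <= 0) stop("invalid-config: amplitude must be > 0", call. = FALSE)
  if (noise_sd < 0) stop("invalid-config: noise_sd must be >= 0", call. = FALSE)
  years <- site$start_year + seq_len(site$n_years) - 1L
  yr <- rep(years, each = DAYS_PER_YEAR)
  doy <- rep(seq_len(DAYS_PER_YEAR), times = site$n_years)
  yi <- rep(seq_len(site$n_years) - 1L, each = DAYS_PER_YEAR)
  base <- mean_annual + amplitude * cos(2 * pi * (doy - 200) / 365) +
    warming_trend * yi / 10
  eps <- local_seed(seed, rnorm(length(base), 0, noise_sd))
  daily_series(site$site_id, yr, doy, base + eps)
}

#' Generate ground-truth phenology driven by previous-season temperature
#'
#' Imposes the effect under study: for every year with a previous growing
#' season, the true start of season responds linearly to the previous
#' year's May-September mean temperature anomaly,
#' `true_sos(y) = base_sos + true_st * (T_GS(y-1) - mean(T_GS)) + noise`,
#' rounded to the nearest day; the end of season follows at a fixed
#' season length. The first year has no previous season, so it carries no
#' anomaly truth (`prev_tgs = NA`) and sits at `base_sos` (plus noise).
#'
#' @param site a [site_config()].
#' @param temp temperature [daily_series()] covering all site years.
#' @param base_sos long-term mean SOS (DOY, in 60-180).
#' @param true_st imposed temperature sensitivity (days per deg C;
#'   negative = warming advances SOS).
#' @param sos_noise_sd interannual SOS noise SD (days); noise is truncated
#'   so that `1 <= sos < eos <= 365` always holds.
#' @param season_length days between SOS and EOS (default 160).
#' @param seed integer seed.
#' @return data.frame with one row per site-year: `site_id`, `year`,
#'   `true_sos`, `true_eos`, `true_st`, `prev_tgs` (previous-season mean
#'   temperature, NA in the first year).
#' @export
generate_phenology_truth <- function(site, temp, base_sos = 120, true_st = -2,
                                     sos_noise_sd = 3, season_length = 160,
                                     seed = NULL) {
  stopifnot(inherits(site, "site_config"))
  if (base_sos < 60 || base_sos > 180)
    stop("invalid-config: base_sos must lie in [60, 180]", call. = FALSE)
  years <- site$start_year + seq_len(site$n_years) - 1L
  if (!all(years %in% unique(temp$year)))
    stop("invalid-config: temperature series must cover all site years", call. = FALSE)
  tgs <- vapply(years, function(y) {
    s <- year_slice(temp, y)
    mean(s$value[s$doy >= GS_DOY_START & s$doy < GS_DOY_END])
  }, numeric(1))
  # long-term mean over the seasons actually used as predictors (years 1..n-1)
  prev <- c(NA_real_, tgs[-length(tgs)])
  tgs_bar <- mean(prev, na.rm = TRUE)
  eps <- local_seed(seed, rnorm(site$n_years, 0, sos_noise_sd))
  shift <- ifelse(is.na(prev), 0, true_st * (prev - tgs_bar))
  sos_max <- DAYS_PER_YEAR - season_length - 1L
  sos <- pmin(pmax(round(base_sos + shift + eps), 1), sos_max)
  data.frame(site_id = site$site_id, year = years,
             true_sos = as.numeric(sos), true_eos = as.numeric(sos + season_length),
             true_st = true_st, prev_tgs = prev)
}

# default observation models for the three curve families
CURVE_DEFAULTS <- list(
  ndvi = list(background = 0.15, amplitude = 0.55, rate = 0.1,
              obs_noise_sd = 0.02, cadence_days = 15L),
  gcc  = list(background = 0.33, amplitude = 0.10, rate = 0.1,
              obs_noise_sd = 0.005, cadence_days = 1L),
  gpp  = list(background = 0.5, amplitude = 10, rate = 0.1,
              obs_noise_sd = 0.5, cadence_days = 1L)
)

#' Generate a seasonal observation series from phenology truth
#'
#' Samples the package's double-logistic seasonal curve
#' ([double_logistic()]) for every truth year, adds Gaussian observation
#' noise, and returns the series at daily or 15-day cadence. For `ndvi`
#' and `gcc` the spring inflection is placed at `true_sos` and the autumn
#' inflection at `true_eos`. For `gpp` the spring limb is positioned so
#' that the noise-free curve crosses 15% of its seasonal maximum exactly
#' at `true_sos`, matching the threshold convention by which flux SOS is
#' defined (the inflection itself then sits a few days after `true_sos`);
#' the autumn inflection stays at `true_eos`.
#'
#' Defaults per curve kind (chosen as realistic observation models, not
#' taken from any archive): NDVI background 0.15, amplitude 0.55, noise SD
#' 0.02, 15-day cadence; Gcc 0.33/0.10/0.005 daily; GPP 0.5/10 gC m-2 d-1,
#' noise SD 5% of amplitude, daily.
#'
#' @param truth data.frame from [generate_phenology_truth()] (one site).
#' @param curve_kind `"ndvi"`, `"gcc"` or `"gpp"`.
#' @param background,amplitude curve units; `amplitude > 0`.
#' @param rate shared spring/autumn logistic rate (1/day, > 0).
#' @param obs_noise_sd additive Gaussian observation noise SD.
#' @param cadence_days 1 (daily) or 15 (15-day composites, sampled at DOY
#'   8, 23, ... giving ~24 samples per year).
#' @param seed integer seed.
#' @return a [daily_series()]; for `gpp` it carries an attribute
#'   `true_gpp_max`, a data.frame of each year's noise-free curve maximum.
#' @export
generate_seasonal_curve <- function(truth, curve_kind = c("ndvi", "gcc", "gpp"),
                                    background = NULL, amplitude = NULL,
                                    rate = NULL, obs_noise_sd = NULL,
                                    cadence_days = NULL, seed = NULL) {
  curve_kind <- match.arg(curve_kind)
  def <- CURVE_DEFAULTS[[curve_kind]]
  background <- background %||% def$background
  amplitude <- amplitude %||% def$amplitude
  rate <- rate %||% def$rate
  obs_noise_sd <- obs_noise_sd %||% def$obs_noise_sd
  cadence_days <- as.integer(cadence_days %||% def$cadence_days)
  if (amplitude <= 0 || rate <= 0)
    stop("invalid-config: amplitude and rate must be > 0", call. = FALSE)
  if (!cadence_days %in% c(1L, 15L))
    stop("invalid-config: cadence_days must be 1 or 15", call. = FALSE)
  # the two logistics must be separated enough to form a plateau
  if (any(truth$true_eos - truth$true_sos < 3 / rate + 3 / rate))
    stop("invalid-config: season too short to separate inflections at this rate",
         call. = FALSE)
  doy_grid <- if (cadence_days == 1L) seq_len(DAYS_PER_YEAR) else
    seq(8L, DAYS_PER_YEAR, by = 15L)
  rows <- vector("list", nrow(truth))
  gppmax <- numeric(nrow(truth))
  for (i in seq_len(nrow(truth))) {
    m <- truth$true_sos[i]
    n <- truth$true_eos[i]
    if (curve_kind == "gpp") {
      # place the rising limb so the 15%-of-maximum crossing falls on true_sos
      peak <- background + amplitude  # plateau value; autumn term negligible there
      level <- 0.15 * peak
      if (level <= background)
        stop("invalid-config: gpp background too high for a 15% threshold",
             call. = FALSE)
      m <- m - logistic_rise_crossing(level, amplitude, background, rate)
    }
    y <- double_logistic(doy_grid, a = amplitude, b = background,
                         k = rate, m = m, r = rate, n = n)
    fine <- double_logistic(seq(1, DAYS_PER_YEAR, by = 0.1), a = amplitude,
                            b = background, k = rate, m = m, r = rate, n = n)
    gppmax[i] <- max(fine)
    rows[[i]] <- data.frame(year = truth$year[i], doy = doy_grid, value = y)
  }
  out <- do.call(rbind, rows)
  eps <- local_seed(seed, rnorm(nrow(out), 0, obs_noise_sd))
  ser <- daily_series(truth$site_id[1], out$year, out$doy, out$value + eps)
  if (curve_kind == "gpp")
    attr(ser, "true_gpp_max") <- data.frame(year = truth$year, gpp_max = gppmax)
  ser
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# the causal graph used by the flux-panel generator: five growing-season
# climate drivers each point at GPPmax and at SOS, and GPPmax points at SOS
FLUX_CLIMATE_VARS <- c("temperature", "radiation", "precipitation",
                       "soil_water", "co2")

#' Default edge set of the climate -> GPPmax -> SOS causal graph
#' @return character vector of `"source->sink"` edge labels.
#' @export
flux_sem_edges <- function() {
  c(paste0(FLUX_CLIMATE_VARS, "->gppmax"),
    paste0(FLUX_CLIMATE_VARS, "->sos"),
    "gppmax->sos")
}

# default generating coefficients: warm/bright seasons raise GPPmax,
# higher GPPmax advances (negative effect on) SOS, plus weak direct paths
default_flux_truth <- function() {
  c("temperature->gppmax" = 0.45, "radiation->gppmax" = 0.35,
    "precipitation->gppmax" = 0.2, "soil_water->gppmax" = 0.15,
    "co2->gppmax" = 0.1,
    "temperature->sos" = 0.1, "radiation->sos" = -0.05,
    "precipitation->sos" = 0.05, "soil_water->sos" = -0.05,
    "co2->sos" = 0.0,
    "gppmax->sos" = -0.5)
}

#' Generate a site-year flux panel from a known causal graph
#'
#' Draws the five growing-season climate drivers as independent standard
#' normals, then builds `gppmax` and `sos` as linear combinations per the
#' supplied edge coefficients plus Gaussian noise. By default the noise
#' variances are chosen so that `gppmax` and `sos` have unit population
#' variance, which makes the generating coefficients equal to the true
#' standardized path coefficients. The population standardized paths (for
#' any noise choice) are returned in the `true_paths` attribute.
#'
#' @param sites list of [site_config()]s.
#' @param sem_truth named coefficient vector over exactly the edges of
#'   [flux_sem_edges()].
#' @param noise_sds optional list with elements `gppmax`, `sos`; `NULL`
#'   selects the unit-variance construction.
#' @param seed integer seed.
#' @return data.frame with one row per site-year and columns `site_id`,
#'   `year`, the five climate variables, `gppmax`, `sos`; attribute
#'   `true_paths` holds the standardized generating coefficients.
#' @export
generate_flux_site_panel <- function(sites, sem_truth = default_flux_truth(),
                                     noise_sds = NULL, seed = NULL) {
  edges <- flux_sem_edges()
  if (!setequal(names(sem_truth), edges))
    stop("invalid-config: sem_truth must contain exactly the edges ",
         paste(setdiff(edges, names(sem_truth)), collapse = ", "),
         call. = FALSE)
  sem_truth <- sem_truth[edges]
  bg <- sem_truth[paste0(FLUX_CLIMATE_VARS, "->gppmax")]
  gs <- sem_truth[paste0(FLUX_CLIMATE_VARS, "->sos")]
  dg <- sem_truth[["gppmax->sos"]]
  if (is.null(noise_sds)) {
    v_g <- 1 - sum(bg^2)
    if (v_g <= 0)
      stop("invalid-config: climate->gppmax coefficients imply variance > 1; ",
           "supply noise_sds explicitly", call. = FALSE)
    sd_g_noise <- sqrt(v_g)
    v_s <- 1 - (sum((gs + dg * bg)^2) + dg^2 * v_g)
    if (v_s <= 0)
      stop("invalid-config: sos structural variance exceeds 1; ",
           "supply noise_sds explicitly", call. = FALSE)
    sd_s_noise <- sqrt(v_s)
  } else {
    sd_g_noise <- noise_sds$gppmax
    sd_s_noise <- noise_sds$sos
  }
  site_ids <- vapply(sites, `[[`, character(1), "site_id")
  ny <- vapply(sites, `[[`, integer(1), "n_years")
  years <- unlist(lapply(sites, function(s) s$start_year + seq_len(s$n_years) - 1L))
  n <- sum(ny)
  panel <- local_seed(seed, {
    clim <- matrix(rnorm(n * length(FLUX_CLIMATE_VARS)), nrow = n,
                   dimnames = list(NULL, FLUX_CLIMATE_VARS))
    gpp <- drop(clim %*% bg) + rnorm(n, 0, sd_g_noise)
    sos <- drop(clim %*% gs) + dg * gpp + rnorm(n, 0, sd_s_noise)
    data.frame(site_id = rep(site_ids, ny), year = years, clim,
               gppmax = gpp, sos = sos)
  })
  # population SDs of the endogenous variables under this parameterisation
  sd_g <- sqrt(sum(bg^2) + sd_g_noise^2)
  sd_s <- sqrt(sum((gs + dg * bg)^2) + dg^2 * sd_g_noise^2 + sd_s_noise^2)
  paths <- c(bg / sd_g, gs / sd_s, sd_g * dg / sd_s)
  names(paths) <- edges
  attr(panel, "true_paths") <- paths
  panel
}

#' Generate a gridded climate field with a known analytic form
#'
#' Builds a regular lat-lon grid whose value at every node comes from a
#' supplied analytic function of (lat, lon, time), so interpolation error
#' is exactly computable.
#'
#' @param lat_range,lon_range numeric length-2 extents in degrees.
#' @param resolution grid spacing in degrees (> 0).
#' @param times vector of time labels (months or days).
#' @param field `function(lat, lon, time)`, vectorised in lat/lon.
#' @return a `climate_grid` list with `lats`, `lons`, `times` and a
#'   `values` array of dimension time x lat x lon.
#' @export
generate_climate_grid <- function(lat_range = c(40, 60), lon_range = c(0, 20),
                                  resolution = 0.25, times = 1L,
                                  field = function(lat, lon, time) 0 * lat) {
  if (resolution <= 0) stop("invalid-config: resolution must be > 0", call. = FALSE)
  if (diff(lat_range) <= 0 || diff(lon_range) <= 0)
    stop("invalid-config: degenerate extent", call. = FALSE)
  lats <- seq(lat_range[1], lat_range[2], by = resolution)
  lons <- seq(lon_range[1], lon_range[2], by = resolution)
  vals <- array(NA_real_, dim = c(length(times), length(lats), length(lons)))
  for (ti in seq_along(times)) {
    vals[ti, , ] <- outer(lats, lons, function(la, lo)
      rep_len(field(la, lo, times[ti]), length(la)))  # allow constant fields
  }
  structure(list(lats = lats, lons = lons, times = times, values = vals),
            class = "climate_grid")
}

#' Write a climate grid as long-format CSV triplets
#'
#' @param grid a `climate_grid`.
#' @param path output CSV (columns `time, lat, lon, value`).
#' @export
write_climate_grid <- function(grid, path) {
  df <- expand.grid(lon = grid$lons, lat = grid$lats, time = grid$times,
                    KEEP.OUT.ATTRS = FALSE)
  df$value <- as.vector(aperm(grid$values, c(3, 2, 1)))
  write.csv(df[, c("time", "lat", "lon", "value")], path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @param path CSV written by [write_climate_grid()].
#' @rdname write_climate_grid
#' @export
read_climate_grid <- function(path) {
  df <- read.csv(path)
  lats <- sort(unique(df$lat))
  lons <- sort(unique(df$lon))
  times <- sort(unique(df$time))
  vals <- array(NA_real_, dim = c(length(times), length(lats), length(lons)))
  vals[cbind(match(df$time, times), match(df$lat, lats), match(df$lon, lons))] <-
    df$value
  structure(list(lats = lats, lons = lons, times = times, values = vals),
            class = "climate_grid")
}
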