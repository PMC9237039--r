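test_that("temperature generator: deterministic limits and seed contract", {
  sc <- site_config("A", n_years = 3)
  # zero noise, zero trend: every year identical
  t0 <- generate_temperature(sc, noise_sd = 0, warming_trend = 0)
  m <- matrix(t0$value, nrow = 365)
  expect_equal(m[, 1], m[, 2])
  expect_equal(m[, 1], m[, 3])
  # cosine peak at doy 200: max = mean + amplitude
  t1 <- generate_temperature(sc, mean_annual = 5, amplitude = 10, noise_sd = 0)
  y1 <- year_max <- t1[t1$year == 2000, ]
  expect_equal(max(y1$value), 15)
  expect_equal(y1$doy[which.max(y1$value)], 200L)
  # same seed twice: bit-identical
  a <- generate_temperature(sc, noise_sd = 2, seed = 1)
  b <- generate_temperature(sc, noise_sd = 2, seed = 1)
  expect_identical(a, b)
  expect_false(identical(a$value,
                         generate_temperature(sc, noise_sd = 2, seed = 2)$value))
  expect_error(site_config("A", n_years = 1), "invalid-config")
})

test_that("phenology truth follows the linear previous-season rule", {
  b <- make_site_bundle(true_st = 0, sos_noise_sd = 0)
  expect_true(all(b$truth$true_sos == 120))
  expect_true(all(b$truth$true_eos == 280))
  expect_true(is.na(b$truth$prev_tgs[1]))       # no previous season
  expect_false(anyNA(b$truth$prev_tgs[-1]))
  # exact linear rule: +1 degree C previous-season anomaly at st = -2 -> -2 days
  sc <- site_config("B", n_years = 3)
  temp <- generate_temperature(sc, noise_sd = 0)
  temp$value[temp$year == 2001] <- temp$value[temp$year == 2001] + 2
  tr <- generate_phenology_truth(sc, temp, base_sos = 120, true_st = -2,
                                 sos_noise_sd = 0)
  # anomalies of prev T_GS: years 2001, 2002 see 2000 (-1) and 2001 (+1)
  expect_equal(tr$true_sos[2] - tr$true_sos[3], 4)  # -2*(-1) - (-2*(+1))
  expect_true(all(tr$true_sos >= 1 & tr$true_sos < tr$true_eos))
})

test_that("regression on generated truth recovers the imposed S_T", {
  # independent oracle: raw-scale OLS of SOS on previous-season T_GS
  slopes <- ns <- numeric(0)
  est <- se <- numeric(40)
  for (i in 1:40) {
    sc <- site_config(paste0("S", i), n_years = 30)
    temp <- generate_temperature(sc, noise_sd = 5, seed = 1000 + i)
    tr <- generate_phenology_truth(sc, temp, true_st = -2, sos_noise_sd = 3,
                                   seed = 2000 + i)
    fit <- lm(true_sos ~ prev_tgs, data = tr[-1, ])
    est[i] <- coef(fit)["prev_tgs"]
  }
  ci <- mean(est) + c(-1, 1) * qt(0.975, 39) * sd(est) / sqrt(40)
  expect_gt(-2, ci[1])
  expect_lt(-2, ci[2])
})

test_that("seasonal curves hit background and plateau at zero noise", {
  b <- make_site_bundle(n_years = 2)
  for (kind in c("ndvi", "gcc", "gpp")) {
    def <- phenoflux:::CURVE_DEFAULTS[[kind]]
    s <- generate_seasonal_curve(b$truth, kind, obs_noise_sd = 0)
    y1 <- s[s$year == 2000, ]
    # midsummer plateau reaches background + amplitude within 1%
    mid <- y1$value[abs(y1$doy - 200) <= 7]
    expect_equal(max(mid), def$background + def$amplitude,
                 tolerance = 0.01)
    # winter tail returns to background within 1%
    expect_equal(min(y1$value), def$background,
                 tolerance = 0.01 * def$amplitude / def$background)
  }
  # 15-day cadence gives ~24 samples per year
  nd <- generate_seasonal_curve(b$truth, "ndvi", obs_noise_sd = 0)
  expect_equal(nrow(nd[nd$year == 2000, ]), 24L)
  # too-short season for the rate is rejected
  short <- b$truth
  short$true_eos <- short$true_sos + 20
  expect_error(generate_seasonal_curve(short, "ndvi", rate = 0.1),
               "invalid-config")
})

test_that("flux panel encodes the generating causal coefficients", {
  sites <- lapply(1:20, function(i) site_config(paste0("F", i), n_years = 100))
  # gppmax -> sos = -0.5, everything else 0: marginal slope recovers -0.5
  tr <- setNames(rep(0, 11), flux_sem_edges())
  tr["gppmax->sos"] <- -0.5
  p <- generate_flux_site_panel(sites, tr, seed = 5)
  sl <- coef(lm(sos ~ gppmax, data = p))["gppmax"]
  expect_equal(unname(sl), -0.5, tolerance = 3 / sqrt(nrow(p)) / sqrt(0.75))
  # all coefficients and noise 0 -> constants
  sites2 <- lapply(1:2, function(i) site_config(paste0("G", i), n_years = 5))
  p0 <- generate_flux_site_panel(sites2, setNames(rep(0, 11), flux_sem_edges()),
                                 noise_sds = list(gppmax = 0, sos = 0), seed = 1)
  expect_true(all(p0$gppmax == 0) && all(p0$sos == 0))
  # path tracing: +temp->gppmax, -gppmax->sos, no direct edge
  tr2 <- setNames(rep(0, 11), flux_sem_edges())
  tr2["temperature->gppmax"] <- 0.6
  tr2["gppmax->sos"] <- -0.5
  p2 <- generate_flux_site_panel(sites, tr2, seed = 6)
  expect_lt(cor(p2$temperature, p2$sos), -0.2)
  # declared truth matches unit-variance standardized paths
  expect_equal(unname(attr(p2, "true_paths")["temperature->gppmax"]), 0.6)
  expect_error(generate_flux_site_panel(sites, tr2[-1]), "invalid-config")
})

test_that("climate grid holds analytic fields exactly at its nodes", {
  gc_const <- generate_climate_grid(c(40, 41), c(0, 1), 0.25,
                                    field = function(lat, lon, time) 7)
  expect_true(all(gc_const$values == 7))
  gl <- generate_climate_grid(c(40, 41), c(0, 1), 0.25,
                              field = function(lat, lon, time) 2 * lat - lon)
  expect_equal(gl$values[1, 3, 2], 2 * 40.5 - 0.25)
  expect_error(generate_climate_grid(c(40, 40), c(0, 1), 0.25),
               "invalid-config")
})

test_that("every generated site-year appears in exactly one truth record", {
  b <- make_site_bundle(n_years = 7)
  expect_equal(nrow(b$truth), 7L)
  expect_equal(anyDuplicated(b$truth[c("site_id", "year")]), 0L)
  s <- generate_seasonal_curve(b$truth, "gcc", obs_noise_sd = 0)
  expect_setequal(unique(s$year), b$truth$year)
})
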