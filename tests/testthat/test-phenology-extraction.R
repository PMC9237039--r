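test_that("Gcc arithmetic follows the chromatic-coordinate definition", {
  expect_equal(gcc(0, 255, 0), 1)
  expect_equal(gcc(100, 100, 100), 1 / 3)
  expect_equal(gcc(50, 100, 50), 0.5)
  expect_error(gcc(0, 0, 0), "undefined-ratio")
})

test_that("Gcc 50%-amplitude SOS finds threshold crossings", {
  # step from 0.30 to 0.45 on doy 140
  step <- daily_series("A", 2000, 1:365, c(rep(0.30, 139), rep(0.45, 226)))
  expect_equal(gcc_sos(step, 2000), 140L)
  # constant curve has no season
  expect_error(gcc_sos(const_series(0.35), 2000), "no-seasonality")
  # noise-free logistic: extracted within 2 days of the spring inflection
  b <- make_site_bundle(n_years = 2)
  g <- generate_seasonal_curve(b$truth, "gcc", obs_noise_sd = 0)
  for (y in b$truth$year)
    expect_lte(abs(gcc_sos(g, y) - b$truth$true_sos[b$truth$year == y]), 2)
})

test_that("Savitzky-Golay reproduces polynomials and contracts noise", {
  s <- daily_series("A", 2000, 1:31, rnorm(31))
  # interpolating order: output equals input
  out <- savitzky_golay(s, window = 5, polyorder = 4)
  expect_equal(out$value, s$value, tolerance = 1e-8)
  # cubic signal, cubic filter: exact reproduction
  cub <- daily_series("A", 2000, 1:50, (1:50 / 10)^3 - 2 * (1:50 / 10))
  expect_equal(savitzky_golay(cub, 7, 3)$value, cub$value, tolerance = 1e-8)
  # white noise: smoother contracts variance
  set.seed(3)
  vr <- replicate(20, {
    w <- daily_series("A", 2000, 1:200, rnorm(200))
    var(savitzky_golay(w, 7, 2)$value) / var(w$value)
  })
  expect_lt(mean(vr), 1)
  expect_error(savitzky_golay(s, window = 6, polyorder = 2), "invalid-config")
})

test_that("double-logistic fit recovers its own parameters at zero noise", {
  b <- make_site_bundle(n_years = 2)
  nd <- generate_seasonal_curve(b$truth, "ndvi", obs_noise_sd = 0)
  fit <- fit_double_logistic(nd, 2000)
  expect_true(fit$converged)
  truth_params <- c(a = 0.55, b = 0.15, k = 0.1, m = 120, r_autumn = 0.1,
                    n = 280)
  expect_equal(fit$params[names(truth_params)], truth_params,
               tolerance = 1e-3)
  # fitted plateau equals background + amplitude
  p <- fit$params
  plateau <- max(double_logistic(1:365, p["a"], p["b"], p["k"], p["m"],
                                 p["r_autumn"], p["n"]))
  expect_equal(unname(plateau), unname(p["a"] + p["b"]), tolerance = 0.01)
})

test_that("second-derivative extractor matches the closed-form offset", {
  # for a rising logistic the curvature maximum sits at m - log(2+sqrt(3))/k
  for (k in c(0.05, 0.1, 0.2)) {
    p <- c(a = 1, b = 0, k = k, m = 150, r_autumn = 0.2, n = 330)
    ext <- extract_sos_eos_from_fit(p)
    expect_lt(abs(ext$sos_exact - (150 - log(2 + sqrt(3)) / k)), 0.2)
  }
  # symmetric curve: SOS and EOS symmetric about the seasonal midpoint
  p <- c(a = 1, b = 0, k = 0.1, m = 150, r_autumn = 0.1, n = 250)
  ext <- extract_sos_eos_from_fit(p)
  expect_lt(abs((ext$sos_exact + ext$eos_exact) / 2 - 200), 0.5)
  # zero-noise synthetic NDVI ordering and bounds
  b <- make_site_bundle(n_years = 2)
  nd <- generate_seasonal_curve(b$truth, "ndvi", obs_noise_sd = 0)
  fit <- fit_double_logistic(nd, 2000)
  ext2 <- extract_sos_eos_from_fit(fit)
  expect_lte(abs(ext2$sos - 120), 15)
  expect_lte(abs(ext2$eos - 280), 15)
  expect_true(ext2$sos < fit$params["m"] && fit$params["n"] < ext2$eos)
})

test_that("SSA reconstruction is exact at full rank and denoises", {
  t <- 1:400
  s <- daily_series("A", rep(c(2000, 2001), c(365, 35)), c(1:365, 1:35),
                    sin(2 * pi * t / 50))
  # full-rank reconstruction returns the input
  full <- ssa_smooth(s, window_length = 20, n_components = 20)
  expect_equal(full$value, s$value, tolerance = 1e-8)
  # a sinusoid has a rank-2 trajectory: 2 components suffice
  r2 <- ssa_smooth(s, window_length = 20, n_components = 2)
  expect_gt(cor(r2$value, s$value)^2, 0.999)
  # noisy sinusoid: reconstruction closer to clean signal than raw data
  set.seed(8)
  clean <- sin(2 * pi * t / 100)
  noisy <- clean + rnorm(400, 0, sd(clean) / 5)
  sn <- s; sn$value <- noisy
  rec <- ssa_smooth(sn, 40, 4)
  expect_gt(cor(rec$value, clean), cor(noisy, clean))
  expect_error(ssa_smooth(s, window_length = 300, n_components = 2),
               "invalid-config")
  # long internal gap is rejected
  gap <- s; gap$value[100:140] <- NA
  expect_error(ssa_smooth(gap, 20, 4), "gap-error")
})

test_that("GPP threshold SOS applies the 15% rule with persistence", {
  v <- rep(0.5, 365)
  v[115:182] <- 5  # crosses 1.5 upward on doy 115 and stays above
  s <- daily_series("A", 2000, 1:365, v)
  expect_equal(gpp_sos(s, 2000, multi_year_max = 10), 115L)
  # constant 10% of max never reaches the threshold
  low <- const_series(1)
  out <- gpp_sos(low, 2000, multi_year_max = 10)
  expect_true(is.na(out))
  expect_equal(attr(out, "flag"), "no-season")
  # single-day spike is excluded by the persistence rule
  v2 <- rep(0.5, 365)
  v2[80] <- 5
  v2[120:182] <- 5
  s2 <- daily_series("A", 2000, 1:365, v2)
  expect_equal(gpp_sos(s2, 2000, multi_year_max = 10), 120L)
})

test_that("carbon metrics summarise the smoothed GPP curve", {
  cm <- carbon_metrics(const_series(5), 2000)
  expect_equal(cm$gpp_max, 5)
  expect_equal(cm$gpp_mean_gs, 5)
  # triangular peak: closed-form mean of the sampled triangle over doy 121-273
  d <- 1:365
  tri <- pmax(0, 12 * pmin((d - 100) / 80, (260 - d) / 80))
  st <- daily_series("A", 2000, d, tri)
  cmt <- carbon_metrics(st, 2000)
  expect_equal(cmt$gpp_max, 12)
  expect_equal(cmt$gpp_mean_gs, 928.5 / 153)  # arithmetic series sums
  # peak in April only: gpp_max from April exceeds the growing-season mean
  ap <- rep(0.1, 365); ap[91:120] <- 8
  sap <- daily_series("A", 2000, d, ap)
  cma <- carbon_metrics(sap, 2000)
  expect_equal(cma$gpp_max, 8)
  expect_lt(cma$gpp_mean_gs, cma$gpp_max)
  # missing May-September coverage drops the year
  gappy <- st[st$doy < 150 | st$doy > 200, ]
  expect_equal(carbon_metrics(gappy, 2000)$flag, "missing-growing-season")
})

test_that("extractors are shift-equivariant and gpp_sos is scale-free", {
  b1 <- make_site_bundle(n_years = 2)
  b2 <- b1
  b2$truth$true_sos <- b2$truth$true_sos + 12
  b2$truth$true_eos <- b2$truth$true_eos + 12
  for (kind in c("gcc", "gpp")) {
    s1 <- generate_seasonal_curve(b1$truth, kind, obs_noise_sd = 0)
    s2 <- generate_seasonal_curve(b2$truth, kind, obs_noise_sd = 0)
    if (kind == "gcc") {
      d <- gcc_sos(s2, 2000) - gcc_sos(s1, 2000)
    } else {
      sm1 <- ssa_smooth(s1); sm2 <- ssa_smooth(s2)
      d <- gpp_sos(sm2, 2000, max(sm2$value)) -
        gpp_sos(sm1, 2000, max(sm1$value))
    }
    expect_lte(abs(d - 12), 1)
  }
  # NDVI: fitted inflections shift with the curve
  n1 <- generate_seasonal_curve(b1$truth, "ndvi", obs_noise_sd = 0)
  n2 <- generate_seasonal_curve(b2$truth, "ndvi", obs_noise_sd = 0)
  e1 <- extract_sos_eos_from_fit(fit_double_logistic(n1, 2000))
  e2 <- extract_sos_eos_from_fit(fit_double_logistic(n2, 2000))
  expect_lte(abs((e2$sos - e1$sos) - 12), 1)
  # amplitude invariance: scaling curve and multi-year max together
  g <- generate_seasonal_curve(b1$truth, "gpp", obs_noise_sd = 0)
  sm <- ssa_smooth(g)
  sm3 <- sm; sm3$value <- sm3$value * 3.7
  expect_equal(gpp_sos(sm, 2000, max(sm$value)),
               gpp_sos(sm3, 2000, max(sm3$value)))
})
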