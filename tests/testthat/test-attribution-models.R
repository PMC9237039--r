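test_that("SEM specification validates the graph", {
  sp <- sem_spec()
  expect_setequal(sp$exogenous,
                  c("temperature", "radiation", "precipitation",
                    "soil_water", "co2"))
  expect_error(sem_spec(c("a->b", "b->c", "c->a")), "graph-error")
  expect_error(fit_piecewise_sem(data.frame(x = 1:5), sem_spec(c("x->y"))),
               "missing")
})

test_that("piecewise SEM recovers standardized paths on generated data", {
  sites <- lapply(1:40, function(i) site_config(paste0("F", i), n_years = 50))
  panel <- generate_flux_site_panel(sites, seed = 21)
  truth <- attr(panel, "true_paths")
  sem <- fit_piecewise_sem(panel, sem_spec())
  est <- setNames(sem$paths$estimate, paste0(sem$paths$from, "->", sem$paths$to))
  expect_lt(max(abs(est[names(truth)] - truth)), 0.06)
  # saturated graph: no testable independence claims
  expect_equal(sem$fisher_df, 0L)
  expect_true(is.na(sem$fisher_p))
  # single-predictor equation on standardized data equals Pearson r
  sp1 <- sem_spec(c("gppmax->sos"))
  sem1 <- fit_piecewise_sem(panel, sp1)
  expect_equal(sem1$paths$estimate, cor(panel$gppmax, panel$sos),
               tolerance = 1e-10)
})

test_that("d-separation test accepts true graphs and rejects violations", {
  pruned <- sem_spec(c("temperature->gppmax", "radiation->gppmax",
                       "gppmax->sos"))
  gen <- function(n, direct_rad_sos = 0) {
    te <- rnorm(n); ra <- rnorm(n)
    g <- 0.5 * te + 0.3 * ra + rnorm(n, 0, sqrt(1 - 0.25 - 0.09))
    s <- -0.5 * g + direct_rad_sos * ra + rnorm(n, 0, 0.8)
    data.frame(temperature = te, radiation = ra, gppmax = g, sos = s)
  }
  set.seed(22)
  # basis set: temperature-sos and radiation-sos claims -> df = 4
  sem <- fit_piecewise_sem(gen(500), pruned)
  expect_equal(sem$fisher_df, 4L)
  expect_gt(sem$fisher_c, 0)
  # an omitted strong edge is detected
  rej <- replicate(20, fit_piecewise_sem(gen(500, direct_rad_sos = 0.4),
                                         pruned)$fisher_p < 0.05)
  expect_gte(mean(rej), 0.9)
  # under the true graph the test keeps its size approximately
  acc <- replicate(40, fit_piecewise_sem(gen(300), pruned)$fisher_p > 0.05)
  expect_gte(mean(acc), 0.8)
})

test_that("effect decomposition follows the path-tracing rules", {
  paths <- data.frame(
    from = c("temperature", "temperature", "gppmax"),
    to = c("gppmax", "sos", "sos"),
    estimate = c(0.6, 0.2, -0.5), se = 0.01, p_value = 0.001)
  sem <- structure(list(paths = paths), class = "sem_result")
  de <- direct_vs_indirect_effects(sem)
  expect_equal(de$indirect[de$variable == "temperature"], -0.3)
  expect_equal(de$total[de$variable == "temperature"], -0.1)
  # zero mediator path: all indirect effects vanish
  paths0 <- paths; paths0$estimate[3] <- 0
  de0 <- direct_vs_indirect_effects(structure(list(paths = paths0),
                                              class = "sem_result"))
  expect_true(all(de0$indirect == 0))
})

test_that("decomposed totals match marginal regression slopes", {
  sites <- lapply(1:10, function(i) site_config(paste0("F", i), n_years = 500))
  panel <- generate_flux_site_panel(sites, seed = 23)
  sem <- fit_piecewise_sem(panel, sem_spec())
  de <- direct_vs_indirect_effects(sem)
  for (v in c("temperature", "radiation")) {
    marg <- cor(panel[[v]], panel$sos)  # drivers are unit-variance
    expect_equal(de$total[de$variable == v], marg, tolerance = 0.05)
  }
})

test_that("random-forest importance identifies planted drivers", {
  set.seed(24)
  n <- 400
  d <- data.frame(gppmax = rnorm(n), temperature = rnorm(n),
                  radiation = rnorm(n), precipitation = rnorm(n),
                  soil_water = rnorm(n), co2 = rnorm(n))
  d$sos <- 0.9 * d$gppmax + rnorm(n, 0, 0.3)
  rf <- rf_importance(d, ntree = 500, seed = 1)
  expect_equal(rf$ranking[1], "gppmax")
  expect_equal(sum(rf$share), 100, tolerance = 1e-6)
  expect_true(all(rf$share >= 0))
  # determinism under a fixed seed
  rf2 <- rf_importance(d, ntree = 500, seed = 1)
  expect_identical(rf$share, rf2$share)
  expect_error(rf_importance(d, mtry = 10), "invalid-config")
})

test_that("importance shares are invariant to affine predictor rescaling", {
  set.seed(25)
  n <- 300
  d <- data.frame(gppmax = rnorm(n), temperature = rnorm(n),
                  radiation = rnorm(n), precipitation = rnorm(n),
                  soil_water = rnorm(n), co2 = rnorm(n))
  d$sos <- 0.7 * d$gppmax - 0.4 * d$temperature + rnorm(n, 0, 0.4)
  r1 <- rf_importance(d, ntree = 500, seed = 2)
  d2 <- d; d2$temperature <- d2$temperature * 1000 + 55
  r2 <- rf_importance(d2, ntree = 500, seed = 2)
  expect_equal(unname(r1$share["temperature"]),
               unname(r2$share["temperature"]), tolerance = 5)
  expect_equal(r1$ranking[1:2], r2$ranking[1:2])
})

test_that("site-wise standardization yields zero-mean unit-SD columns", {
  sites <- lapply(1:5, function(i) site_config(paste0("F", i), n_years = 20))
  panel <- generate_flux_site_panel(sites, seed = 26)
  std <- standardize_panel(panel)
  for (sid in unique(std$site_id)) {
    v <- std$gppmax[std$site_id == sid]
    expect_equal(mean(v), 0, tolerance = 1e-10)
    expect_equal(sd(v), 1, tolerance = 1e-10)
  }
})
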