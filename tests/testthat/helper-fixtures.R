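# shared fixture builders: one site's zero-noise (or noisy) truth + curves

make_site_bundle <- function(n_years = 6, true_st = -2, sos_noise_sd = 0,
                             temp_noise_sd = 0, seed = 101) {
  sc <- site_config("T1", n_years = n_years, start_year = 2000)
  temp <- generate_temperature(sc, noise_sd = temp_noise_sd, seed = seed)
  truth <- generate_phenology_truth(sc, temp, true_st = true_st,
                                    sos_noise_sd = sos_noise_sd,
                                    seed = seed + 1)
  list(site = sc, temp = temp, truth = truth)
}

# constant-value daily series helper
const_series <- function(value, n_years = 1, site_id = "C1", start_year = 2000) {
  yr <- rep(start_year + seq_len(n_years) - 1L, each = 365L)
  daily_series(site_id, yr, rep(1:365, n_years), rep(value, 365L * n_years))
}
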