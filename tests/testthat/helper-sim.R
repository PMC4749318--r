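# Shared small simulation setups. Kept light: tests that need scale build
# their own configs.

tiny_config <- function(seed = 11, ...) {
  args <- list(
    n_stations = 2, years = 2008:2010,
    station_baselines = c(0.1, 0.2),
    n_recruits_per_station_year = 30,
    true_p_by_year = c(0.5, 0.4),
    n_aged_per_station_year = 40,
    seed = seed
  )
  args[names(list(...))] <- list(...)
  do.call(sim_config, args)
}

# Monthly EVI / rainfall / covariates for the default six-station study.
default_sim_inputs <- function(seed = 5) {
  cfg <- sim_config(seed = seed)
  rain <- sim_rainfall(cfg)
  evi <- sim_evi(rain, cfg)
  covs <- build_covariates(evi, years = (cfg$years[1] - 1L):max(cfg$years))
  list(cfg = cfg, rain = rain, evi = evi, covs = covs)
}

expect_prob <- function(x) {
  expect_true(all(x >= 0 & x <= 1))
}
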