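# Shared fixtures: small designs, quick MCMC settings, a hand-built
# posterior object, and a memoised small fit reused across test files.

tiny_design <- function(n_sites = 4, n_years = 3, n_stations = 4) {
  sampling_design(paste0("S", seq_len(n_sites)),
                  2018L + seq_len(n_years) - 1L,
                  stations_per_site = n_stations)
}

quick_cfg <- function(...) {
  model_config(n_chains = 2L, draws = 400L, warmup = 150L, adapt = 150L,
               ...)
}

# minimal posterior_draws object with hand-set draws, for exercising the
# deterministic post-processing paths without an MCMC run
fake_fit <- function(draws, data, chain = NULL) {
  n <- nrow(draws)
  if (is.null(chain)) chain <- rep(1:2, each = n / 2)
  df <- as.data.frame(data)
  sy <- unique(df[, c("site_id", "year")])
  st <- unique(df[, c("site_id", "station_id")])
  structure(list(draws = draws, chain = chain,
                 iteration = stats::ave(seq_len(n), chain, FUN = seq_along),
                 levels = list(site = sort(unique(df$site_id)),
                               year = sort(unique(df$year)),
                               site_year = sy, station = st),
                 model = "abundance", data = data,
                 config = quick_cfg(), seed = 1L,
                 covariate_scaling = NULL),
            class = "posterior_draws")
}

.fixture_cache <- new.env(parent = emptyenv())

# one small abundance fit shared by inference/indicator tests
small_fit <- function() {
  if (is.null(.fixture_cache$fit)) {
    sim <- simulate_counts(tiny_design(), default_generative_parameters(),
                           seed = 104L)
    .fixture_cache$fit <- fit_abundance_model(sim$table,
                                              quick_cfg(seed = 104L))
    .fixture_cache$sim <- sim
  }
  .fixture_cache$fit
}

small_sim <- function() {
  small_fit()
  .fixture_cache$sim
}
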