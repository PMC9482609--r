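# small deterministic fixtures shared across test files

toy_records <- function() {
  tibble::tibble(
    genotype = rep(c("G1", "G2"), each = 2),
    location = rep(c("L1", "L2"), 2),
    year = 2005L, country = "C1",
    yield = c(95, 98, 101, 99))
}

# two-country system small enough for repeated fitting in tests
small_system <- function(seed = 5, ...) {
  cfg <- trial_system_config(years = 2003:2008, locations_per_group = 3,
                             n_new_per_year = 8, shared_fraction = 0.4,
                             duration_probs = c(0, 1, 0),
                             shared_entry_lag = 0:2, ...)
  simulate_trial_system(cfg, genetic_params(), seed = seed)
}

# base (non-genotype) covariance components used when evaluating the
# restricted likelihood at fixed parameters
base_theta <- function() {
  list(year_group = c(60, 191, 0.8), gy_group = c(5.1, 6.3, 0.13),
       location = c(100, 90), location_year = c(156, 172),
       genotype_location = c(4.4, 8.5), residual = c(27.8, 27.4))
}
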