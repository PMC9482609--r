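test_that("cohort sampling honours durations, sharing and the entry lag", {
  # degenerate duration: everything tested exactly 3 consecutive years
  cfg <- trial_system_config(years = 2001:2010, duration_probs = c(0, 0, 1),
                             shared_entry_lag = 0L)
  set.seed(1)
  co <- sample_variety_cohorts(cfg)
  full <- co[co$entry_year <= 2008, ]
  expect_true(all(full$exit_year - full$entry_year == 2))
  expect_true(all(co$exit_year <= 2010))

  # attrition rates at large n: ~50% one-year, ~30% three-year
  cfg2 <- trial_system_config(years = 2001:2003, n_new_per_year = 5000,
                              shared_fraction = 0,
                              duration_probs = c(0.5, 0.2, 0.3),
                              shared_entry_lag = 0L)
  set.seed(2)
  co2 <- sample_variety_cohorts(cfg2)
  co2 <- co2[co2$entry_year == 2001, ]  # only the first cohort is uncensored
  dur <- co2$exit_year - co2$entry_year + 1
  expect_equal(mean(dur == 1), 0.5, tolerance = 0.04)
  expect_equal(mean(dur == 2), 0.2, tolerance = 0.10)

  # no sharing -> no common genotypes
  cfg3 <- trial_system_config(shared_fraction = 0)
  sim3 <- simulate_trial_system(cfg3, genetic_params(), seed = 3)
  expect_equal(nrow(common_genotypes(sim3$data)), 0)

  # shared varieties can have different windows per country
  cfg4 <- trial_system_config(shared_fraction = 1, shared_entry_lag = 1:3)
  set.seed(4)
  co4 <- sample_variety_cohorts(cfg4)
  entries <- co4 |>
    dplyr::group_by(genotype) |>
    dplyr::summarise(spread = diff(range(entry_year)), n = dplyr::n())
  expect_true(all(entries$n == 2))
  expect_gt(mean(entries$spread > 0), 0.8)
})

test_that("degenerate generating processes are exact", {
  # all variances and slopes zero: yield is mu + country offset everywhere
  p0 <- genetic_params(mu = 87, group_effects = c(0, 4),
                       beta1 = 0, beta2 = 0, beta3 = 0,
                       Sigma_g = diag(0, 2), Sigma_y = diag(0, 2),
                       Sigma_gy = diag(0, 2), s_var = 0, sy_var = 0,
                       gs_var = 0, resid_var = 0)
  cfg <- trial_system_config(years = 2003:2006, locations_per_group = 2,
                             n_new_per_year = 4)
  sim <- simulate_trial_system(cfg, p0, seed = 7)
  expect_equal(unique(sim$data$yield[sim$data$country == "C1"]), 87)
  expect_equal(unique(sim$data$yield[sim$data$country == "C2"]), 91)

  # noise-free trends: OLS on the covariates returns the slopes exactly
  p1 <- genetic_params(beta1 = 3, beta2 = 1.5, beta3 = -0.25,
                       Sigma_g = diag(0, 2), Sigma_y = diag(0, 2),
                       Sigma_gy = diag(0, 2), s_var = 0, sy_var = 0,
                       gs_var = 0, resid_var = 0)
  sim1 <- simulate_trial_system(cfg, p1, seed = 8)
  ols <- stats::lm(yield ~ x1 + x2 + x3, data = sim1$data)
  expect_equal(unname(coef(ols)[c("x2", "x3")]), c(1.5, -0.25),
               tolerance = 1e-9)
})

test_that("simulation is seed-deterministic", {
  cfg <- trial_system_config(years = 2003:2006, locations_per_group = 2,
                             n_new_per_year = 5)
  a <- simulate_trial_system(cfg, genetic_params(), seed = 123)
  b <- simulate_trial_system(cfg, genetic_params(), seed = 123)
  c <- simulate_trial_system(cfg, genetic_params(), seed = 124)
  expect_identical(tibble::as_tibble(a$data), tibble::as_tibble(b$data))
  expect_false(isTRUE(all.equal(a$data$yield,
                                c$data$yield[seq_len(nrow(a$data))])))
  # truth returned verbatim
  expect_identical(a$truth$Sigma_g, genetic_params()$Sigma_g)
})

test_that("generated effects match the configured covariance at large n", {
  # 10,000 genotypes through the full generator, all other variation off
  cfg <- trial_system_config(years = 2001:2002, locations_per_group = 1,
                             n_new_per_year = 5000, shared_fraction = 1,
                             duration_probs = c(1, 0, 0),
                             shared_entry_lag = 0L)
  pars <- genetic_params(beta1 = 0, beta2 = 0, beta3 = 0,
                         Sigma_y = diag(0, 2), Sigma_gy = diag(0, 2),
                         s_var = 0, sy_var = 0, gs_var = 0, resid_var = 0)
  sim <- simulate_trial_system(cfg, pars, seed = 99)
  eff <- tibble::as_tibble(sim$data) |>
    dplyr::group_by(genotype, country) |>
    dplyr::summarise(g = mean(yield) - 100, .groups = "drop") |>
    tidyr::pivot_wider(names_from = country, values_from = g)
  expect_gt(nrow(eff), 9000)
  expect_equal(var(eff$C1), 11.292, tolerance = 0.03 * 11.292)
  expect_equal(var(eff$C2), 15.021, tolerance = 0.03 * 15.021)
  expect_equal(cor(eff$C1, eff$C2), 0.890, tolerance = 0.02)
})

test_that("generated datasets validate cleanly with full within-year balance", {
  for (seed in c(5, 17)) {
    sim <- small_system(seed = seed)
    s <- summarize_trials(sim$data)
    expect_true(all(s$balance$balanced))
    expect_true(all(sim$data$yield > 0))
  }
  # zone systems: every variety appears in every zone
  zcfg <- trial_system_config(years = 2003:2006, groups = paste0("Z", 1:3),
                              group_type = "zone", locations_per_group = 2,
                              n_new_per_year = 4, shared_fraction = 0)
  zsim <- simulate_trial_system(zcfg, zone_genetic_params(zones = paste0("Z", 1:3)),
                                seed = 6)
  per_g <- tibble::as_tibble(zsim$data) |>
    dplyr::distinct(genotype, zone) |>
    dplyr::count(genotype)
  expect_true(all(per_g$n == 3))
  expect_equal(unique(zsim$data$country), "C1")
})

test_that("non-PSD generator parameters are rejected naming the block", {
  bad <- matrix(c(1, 2, 2, 1), 2, 2)  # eigenvalues 3, -1
  expect_error(genetic_params(Sigma_g = bad), "Sigma_g")
  expect_error(genetic_params(Sigma_gy = bad), "Sigma_gy")
  expect_error(genetic_params(resid_var = c(-1, 1)), "resid_var")
})
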