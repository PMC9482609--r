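test_that("balanced one-way REML matches the closed-form ANOVA estimators", {
  toy <- as_trial_data(tibble::tibble(
    genotype = c("g1", "g1", "g2", "g2"),
    location = c("l1", "l2", "l1", "l2"),
    year = 2001L, country = "C1",
    yield = c(1, 2, 3, 4)))
  spec <- model_spec("oneway", group_var = NULL, random = c(genotype = "ID"))
  fit <- fit_model(toy, spec)
  th <- setNames(fit$theta$estimate, fit$theta$term)
  # ANOVA: MSW = 0.5, MSB = 4, n = 2 -> sigma2_e = 0.5, sigma2_g = 1.75
  expect_equal(unname(th["residual"]), 0.5, tolerance = 1e-5)
  expect_equal(unname(th["genotype"]), 1.75, tolerance = 1e-5)

  # same criterion convention as lme4
  skip_if_not_installed("lme4")
  m <- suppressMessages(lme4::lmer(
    yield ~ 1 + (1 | genotype), data = toy, REML = TRUE,
    control = lme4::lmerControl(check.nobs.vs.nlev = "ignore",
                                check.nobs.vs.nRE = "ignore")))
  expect_equal(-2 * fit$loglik_reml, lme4::REMLcrit(m), tolerance = 1e-6)
})

test_that("likelihood agrees with an independent heterogeneous-UN oracle", {
  skip_if_not_installed("glmmTMB")
  pars <- genetic_params(s_var = c(0, 0), sy_var = c(0, 0), gs_var = c(0, 0))
  cfg <- trial_system_config(years = 2001:2006, locations_per_group = 3,
                             n_new_per_year = 10, shared_fraction = 0.6,
                             duration_probs = c(0, 0, 1))
  sim <- simulate_trial_system(cfg, pars, seed = 9)
  d <- tibble::as_tibble(sim$data)
  spec <- model_spec("chk", "country", covariates = FALSE,
                     random = c(genotype_group = "UN", year_group = "UN"))
  f <- fit_model(d, spec)
  m <- suppressWarnings(glmmTMB::glmmTMB(
    yield ~ country + glmmTMB::us(0 + country | genotype) +
      glmmTMB::us(0 + country | year),
    dispformula = ~ 0 + country, data = d, REML = TRUE))
  expect_equal(f$loglik_reml, as.numeric(stats::logLik(m)), tolerance = 1e-4)
  vc <- glmmTMB::VarCorr(m)$cond
  th <- f$theta
  expect_equal(th$estimate[th$term == "genotype_group"][1:2],
               unname(diag(vc$genotype)), tolerance = 1e-3)
  expect_equal(th$estimate[th$term == "genotype_group"][3],
               attr(vc$genotype, "correlation")[1, 2], tolerance = 1e-3)
  expect_equal(th$estimate[th$term == "year_group"][1:2],
               unname(diag(vc$year)), tolerance = 1e-2)
})

test_that("the composite-CS and two-term representations are likelihood-identical", {
  sim <- small_system(seed = 5)
  d <- sim$data
  spec_sep <- model_spec("sep", "country", covariates = TRUE,
                         random = c(genotype = "ID", genotype_by_group = "ID",
                                    year_group = "UN", gy_group = "UN",
                                    location = "DIAG", location_year = "DIAG",
                                    genotype_location = "DIAG"))
  spec_cs <- catalogue_model("RGC", "CS")
  b_sep <- build_design(d, spec_sep)
  b_cs <- build_design(d, spec_cs)
  base <- base_theta()
  for (gg in list(c(7, 4), c(11.292, 3.729), c(0.5, 9))) {
    ll_sep <- restricted_loglik(b_sep, c(list(genotype = gg[1],
                                              genotype_by_group = gg[2]), base))
    ll_cs <- restricted_loglik(b_cs, c(list(genotype_group = gg), base))
    expect_equal(ll_sep, ll_cs, tolerance = 1e-8)
  }
  # and the maximized fits coincide
  f_sep <- fit_model(d, spec_sep)
  f_cs <- fit_model(d, spec_cs)
  expect_equal(f_sep$loglik_reml, f_cs$loglik_reml, tolerance = 1e-5)
})

test_that("likelihood evaluation is invariant under record permutation", {
  sim <- small_system(seed = 13)
  d <- sim$data
  spec <- catalogue_model("RGC", "CS")
  b1 <- build_design(d, spec)
  set.seed(1)
  perm <- sample(nrow(d))
  d2 <- d[perm, ]
  attr(d2, "centering") <- attr(d, "centering")
  b2 <- build_design(d2, spec)
  th <- c(list(genotype_group = c(11.3, 3.7)), base_theta())
  expect_equal(restricted_loglik(b1, th), restricted_loglik(b2, th),
               tolerance = 1e-8)
})

test_that("degenerate data drive variances to the bound and recover the mean", {
  d <- tidyr::crossing(genotype = c("A", "B", "C"), location = c("L1", "L2"),
                       year = c(2001L, 2002L)) |>
    dplyr::mutate(country = "C1", yield = 77)
  spec <- model_spec("flat", NULL, random = c(genotype = "ID"))
  f <- fit_model(as_trial_data(d), spec)
  expect_equal(f$beta$estimate[1], 77, tolerance = 1e-6)
  # no variation at all: every variance is negligible
  expect_true(all(f$theta$estimate < 1e-8))
})

test_that("adding freedom (CS -> UN) never decreases the maximized likelihood", {
  sim <- small_system(seed = 5)
  f_cs <- fit_model(sim$data, catalogue_model("RGC", "CS"))
  f_un <- fit_model(sim$data, catalogue_model("RGC", "UN"))
  expect_gte(f_un$loglik_reml, f_cs$loglik_reml - 1e-6)
  expect_equal(f_un$n_cov, f_cs$n_cov + 1)
})

test_that("BLUPs of every random term centre near zero and are reported", {
  sim <- small_system(seed = 5)
  f <- fit_model(sim$data, catalogue_model("RGC", "UN"))
  sums <- f$blups |>
    dplyr::group_by(term) |>
    dplyr::summarise(s = abs(sum(estimate)), n = dplyr::n(),
                     scale = stats::sd(estimate))
  expect_true(all(sums$s / pmax(sums$n * sums$scale, 1e-6) < 0.35))
  expect_setequal(unique(f$blups$term), names(f$spec$random))
})

test_that("information criteria satisfy the AIC identities", {
  sim <- small_system(seed = 5)
  f <- fit_model(sim$data, catalogue_model("RGC", "CS"),
                 fit_options(compute_ml = TRUE))
  ic <- information_criteria(f)
  expect_equal(ic$aic_reml, -2 * f$loglik_reml + 2 * f$n_cov)
  expect_equal(ic$aic_ml, -2 * f$loglik_ml + 2 * (f$n_cov + f$n_fixed))
  expect_lte(ic$n_cov_nonbounded, ic$n_cov_structural)
  # REML and ML optima are distinct criteria
  expect_false(isTRUE(all.equal(f$loglik_reml, f$loglik_ml)))
  # without ML the criterion is absent, not zero
  f2 <- fit_model(sim$data, catalogue_model("RGC", "CS"))
  expect_true(is.na(information_criteria(f2)$aic_ml))
})

test_that("predicted genotype means are exact for the saturated fixed model", {
  # balanced, noise-free two-country data: FG predictions equal cell means
  d <- tidyr::crossing(genotype = c("A", "B", "C"),
                       location = c("C1_L1", "C1_L2", "C2_L1", "C2_L2"),
                       year = c(2001L, 2002L)) |>
    dplyr::mutate(country = substr(location, 1, 2))
  means <- tidyr::crossing(genotype = c("A", "B", "C"),
                           country = c("C1", "C2")) |>
    dplyr::mutate(mu = c(95, 99, 101, 103, 97, 96))
  d <- dplyr::left_join(d, means, by = c("genotype", "country")) |>
    dplyr::mutate(yield = mu)
  f <- fit_model(as_trial_data(d[, setdiff(names(d), "mu")]), catalogue_model("FG"))
  p <- predict_genotype_means(f)
  p <- dplyr::left_join(p, means, by = c("genotype", "group" = "country"))
  expect_equal(p$predicted, p$mu, tolerance = 1e-6)
})

test_that("standard errors come from the observed information and respect bounds", {
  sim <- small_system(seed = 5)
  f <- fit_model(sim$data, catalogue_model("RGC", "CS"),
                 fit_options(compute_se = TRUE))
  se <- f$theta$se
  est <- f$theta$estimate
  # well-identified interior components get finite positive SEs; components
  # at (or collapsed onto) the boundary are suppressed, mirroring the "-"
  # convention for bounded parameters
  interior <- !f$theta$bounded & est > 1
  expect_true(all(is.finite(se[interior])))
  expect_true(all(se[interior] > 0))
  expect_true(all(is.na(se[f$theta$bounded])))
  # fixed-effect SEs are positive and finite
  expect_true(all(f$beta$se > 0))
  # tidy/glance accessors
  expect_s3_class(tidy(f, "cov_params"), "tbl_df")
  expect_equal(nrow(glance(f)), 1)
})
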