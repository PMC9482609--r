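test_that("the catalogue builds the documented model family", {
  rgc <- catalogue_model("RGC", "UN")
  expect_true(rgc$covariates)
  expect_false(rgc$genotype_fixed)
  expect_equal(rgc$random$genotype_group, "UN")
  expect_setequal(names(rgc$random),
                  c("genotype_group", "year_group", "gy_group", "location",
                    "location_year", "genotype_location"))
  expect_equal(rgc$random$year_group, "UN")

  # FG: genotype effects in the fixed part, no random genotype term
  fg <- catalogue_model("FG")
  expect_true(fg$genotype_fixed)
  expect_false(any(grepl("genotype", names(fg$random)) &
                     !names(fg$random) %in% c("genotype_location")))
  expect_false(fg$covariates)

  # RC2 keeps the genotype main effect as a plain random intercept
  rc2 <- catalogue_model("RC2")
  expect_equal(rc2$random$genotype, "ID")
  expect_equal(rc2$random$rc_genotype_group, "RC")
  expect_null(rc2$random[["rc_genotype"]])

  # RC3 is the mirror image
  rc3 <- catalogue_model("RC3")
  expect_equal(rc3$random$rc_genotype, "RC")
  expect_equal(rc3$random$genotype_by_group, "ID")

  # RC4 uses the Kronecker term
  expect_equal(catalogue_model("RC4")$random$rc_kron, "RC_KRON")

  # zone-level models switch the environmental terms to heterogeneous DIAG
  zr <- catalogue_model("RGC", "UN", group = "zone")
  expect_equal(zr$random$year_group, "DIAG")
  expect_equal(zr$random$gy_group, "DIAG")
  zsep <- catalogue_model("RGC", "SEP", group = "zone")
  expect_equal(zsep$random$genotype, "ID")
  expect_equal(zsep$random$genotype_by_group, "ID")

  expect_error(catalogue_model("XX"), "unknown catalogue model")
  expect_error(catalogue_model("RC1", "CS"), "RG/RGC only")
  expect_error(model_spec(genotype_fixed = TRUE,
                          random = c(genotype = "ID")),
               "both fixed and random")
})

test_that("model specifications survive a JSON round trip", {
  spec <- catalogue_model("RGC", "CS", group = "zone")
  path <- withr::local_tempfile(fileext = ".json")
  write_model_spec(spec, path)
  back <- read_model_spec(path)
  expect_equal(back$random, spec$random)
  expect_equal(back$group_var, spec$group_var)
  expect_equal(back$covariates, spec$covariates)
})

test_that("design dimensions follow the factor levels", {
  d <- tidyr::crossing(genotype = c("A", "B"), location = c("L1", "L2"),
                       year = 2005L) |>
    dplyr::mutate(country = ifelse(location == "L1", "C1", "C2"),
                  yield = 100 + seq_len(4), nitrogen = 150)
  td <- build_covariates(as_trial_data(d))
  spec <- model_spec("toy", "country", covariates = FALSE,
                     random = c(genotype_group = "CS"))
  b <- build_design(td, spec)
  # composite genotype-in-country effect: one column per observed (g, c) pair
  expect_equal(b$terms$genotype_group$q, 4L)
  expect_equal(b$n, 4)

  # random-coefficient genotype-by-group: paired intercept/slope columns
  sim <- small_system(seed = 41)
  b2 <- build_design(sim$data, catalogue_model("RC2"))
  n_gc <- nrow(dplyr::distinct(tibble::as_tibble(sim$data),
                               genotype, country))
  expect_equal(b2$terms$rc_genotype_group$q, 2L * n_gc)
  # slope columns carry x1
  Z <- b2$terms$rc_genotype_group$Z
  slopes <- which(b2$terms$rc_genotype_group$col_slot == 2L)
  expect_equal(sum(Z[, slopes]), sum(sim$data$x1), tolerance = 1e-9)

  # single-level factors are rejected
  one <- toy_records()
  expect_error(build_design(as_trial_data(one[one$genotype == "G1", ]),
                            model_spec("x", NULL, random = c(genotype = "ID"))),
               "design error")
})

test_that("structural parameter counts match the two-country catalogue", {
  sim <- small_system(seed = 43)
  d <- sim$data
  expect_equal(count_parameters(d, catalogue_model("FG"))$n_cov_params, 14)
  expect_equal(count_parameters(d, catalogue_model("FGC"))$n_cov_params, 14)
  expect_equal(count_parameters(d, catalogue_model("RGC", "CS"))$n_cov_params, 16)
  expect_equal(count_parameters(d, catalogue_model("RGC", "UN"))$n_cov_params, 17)
  # covariates change only the fixed part
  expect_equal(count_parameters(d, catalogue_model("RG", "UN"))$n_cov_params,
               count_parameters(d, catalogue_model("RGC", "UN"))$n_cov_params)
  # RGC fixed part with 2 countries: mu, country, beta1, eta, beta2, beta3
  expect_equal(count_parameters(d, catalogue_model("RGC", "UN"))$n_fixed_coefficients,
               6)
  expect_equal(count_parameters(d, catalogue_model("RC1"))$n_cov_params, 20)
  expect_equal(count_parameters(d, catalogue_model("RC4"))$n_cov_params, 19)
})

test_that("aliased fixed columns are dropped deterministically", {
  sim <- small_system(seed = 47)
  b <- build_design(sim$data, catalogue_model("FGC"))
  expect_equal(qr(b$X)$rank, ncol(b$X))
  # x2 is genotype-constant, so one genotype dummy is aliased and dropped,
  # never the covariate itself (earlier columns win)
  expect_true("beta2_x2" %in% colnames(b$X))
  expect_gt(length(b$dropped_fixed), 0)
  b2 <- build_design(sim$data, catalogue_model("FGC"))
  expect_identical(colnames(b$X), colnames(b2$X))
})
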