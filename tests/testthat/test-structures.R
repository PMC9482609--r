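test_that("materialized blocks reproduce the defining arithmetic", {
  # compound symmetry: diagonal sigma2_g + sigma2_gc, off-diagonal sigma2_g
  cs <- cov_structure("CS", c("a", "b"))
  expect_equal(unname(materialize_cov(cs, c(1, 1))),
               matrix(c(2, 1, 1, 2), 2, 2))

  # unstructured with the published operating point
  un <- cov_structure("UN", c("a", "b"))
  M <- materialize_cov(un, c(11.292, 15.021, 0.890))
  expect_equal(M[1, 2], 0.890 * sqrt(11.292 * 15.021), tolerance = 1e-12)
  expect_equal(diag(M), c(a = 11.292, b = 15.021))

  # FA1 with unit loadings and no specific variance: all-ones matrix
  fa1 <- cov_structure("FA1", paste0("z", 1:5))
  expect_equal(unname(materialize_cov(fa1, c(rep(1, 5), rep(0, 5)))),
               matrix(1, 5, 5))

  # FA0 blocks have rank one
  fa0 <- cov_structure("FA0", paste0("z", 1:4))
  B <- materialize_cov(fa0, c(2, -1, 0.5, 3))
  expect_equal(qr(B)$rank, 1L)

  # Kronecker structure: first group diagonal of G_c fixed at 1
  rk <- cov_structure("RC_KRON", c("a", "b"))
  K <- materialize_cov(rk, c(4, 9, -0.2, 1.5, 0.7))
  Sreg <- matrix(c(4, -0.2 * 6, -0.2 * 6, 9), 2, 2)
  Gc <- matrix(c(1, 0.7 * sqrt(1.5), 0.7 * sqrt(1.5), 1.5), 2, 2)
  expect_equal(unname(K), kronecker(Sreg, Gc), tolerance = 1e-12)
})

test_that("implied genetic correlations follow each structure's formula", {
  cs <- cov_structure("CS", c("a", "b"))
  expect_equal(implied_genetic_correlation(cs, c(1, 1))[1, 2], 0.5)
  expect_equal(implied_genetic_correlation(cs, c(3, 1))[1, 2], 0.75)

  un <- cov_structure("UN", c("a", "b"))
  expect_equal(implied_genetic_correlation(un, c(11.292, 15.021, 0.890))[1, 2],
               0.890)

  # rank-1 FA: correlation exactly +-1 by loading signs
  fa0 <- cov_structure("FA0", c("a", "b", "c"))
  R <- implied_genetic_correlation(fa0, c(2, 1, -1))
  expect_equal(R[1, 2], 1)
  expect_equal(R[1, 3], -1)

  fa1 <- cov_structure("FA1", c("a", "b"))
  R1 <- implied_genetic_correlation(fa1, c(2, 3, 1, 4))
  expect_equal(R1[1, 2], (2 * 3) / sqrt((4 + 1) * (9 + 4)), tolerance = 1e-12)

  # zero total variance -> undefined correlation
  expect_error(implied_genetic_correlation(fa1, c(0, 3, 0, 4)),
               "zero total variance")
  expect_error(implied_genetic_correlation(cov_structure("DIAG", c("a", "b")),
                                           c(1, 2)),
               "not a genotype-group structure")
})

test_that("parameter validation rejects out-of-range values", {
  un <- cov_structure("UN", c("a", "b"))
  expect_error(materialize_cov(un, c(1, 1, 1.2)), "correlation")
  expect_error(materialize_cov(un, c(1, 1)), "expects 3 parameters")
  fa1 <- cov_structure("FA1", c("a", "b"))
  expect_error(materialize_cov(fa1, c(1, 1, -0.5, 1)), "psi")
  cs <- cov_structure("CS", c("a", "b"))
  expect_error(materialize_cov(cs, c(-1, 1)), "non-negative")
})

test_that("every structure materializes to a PSD block for random valid parameters", {
  set.seed(42)
  groups <- c("g1", "g2", "g3")
  for (rep in 1:20) {
    cases <- list(
      list(cov_structure("ID"), runif(1, 0.1, 5)),
      list(cov_structure("DIAG", groups), runif(3, 0.1, 5)),
      list(cov_structure("CS", groups), runif(2, 0.1, 5)),
      list(cov_structure("UN", c("a", "b")),
           c(runif(2, 0.1, 5), runif(1, -0.95, 0.95))),
      list(cov_structure("FA1", groups), c(rnorm(3), runif(3, 0.01, 2))),
      list(cov_structure("FA0", groups), rnorm(3)),
      list(cov_structure("RC"), c(runif(2, 0.1, 5), runif(1, -0.9, 0.9))),
      list(cov_structure("RC_KRON", c("a", "b")),
           c(runif(2, 0.1, 5), runif(1, -0.9, 0.9), runif(1, 0.2, 3),
             runif(1, -0.9, 0.9))))
    for (cs in cases) {
      M <- materialize_cov(cs[[1]], cs[[2]])
      ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
      expect_gte(min(ev), -1e-8 * sum(diag(M)))
      expect_equal(M, t(M))
    }
  }
})

test_that("CS is the equal-variance sub-family of UN", {
  cs <- cov_structure("CS", c("a", "b"))
  un <- cov_structure("UN", c("a", "b"))
  s2g <- 3; s2gc <- 2
  Mcs <- materialize_cov(cs, c(s2g, s2gc))
  v <- s2g + s2gc
  Mun <- materialize_cov(un, c(v, v, s2g / v))
  expect_equal(Mcs, Mun, tolerance = 1e-12)
  expect_equal(implied_genetic_correlation(cs, c(s2g, s2gc)),
               implied_genetic_correlation(un, c(v, v, s2g / v)),
               tolerance = 1e-12)
})

test_that("FA1 converges to FA0 as psi -> 0", {
  groups <- paste0("z", 1:4)
  lam <- c(1.5, 2, -0.5, 1)
  fa0 <- materialize_cov(cov_structure("FA0", groups), lam)
  for (psi in c(1e-2, 1e-5, 1e-8)) {
    fa1 <- materialize_cov(cov_structure("FA1", groups), c(lam, rep(psi, 4)))
    expect_lt(max(abs(fa1 - fa0)), 4 * psi + 1e-12)
  }
})

test_that("unconstrained transforms round-trip on the natural scale", {
  cases <- list(
    list(cov_structure("UN", c("a", "b")), c(2, 5, -0.4)),
    list(cov_structure("UN", paste0("z", 1:4)),
         metcor:::st_from_unc(cov_structure("UN", paste0("z", 1:4)),
                              rnorm(10))),
    list(cov_structure("CS", c("a", "b")), c(1.5, 0.5)),
    list(cov_structure("RC"), c(2, 3, 0.6)),
    list(cov_structure("RC_KRON", c("a", "b")), c(2, 3, -0.3, 1.4, 0.8)),
    list(cov_structure("FA1", c("a", "b", "c")), c(1, -2, 0.5, 0.1, 0.2, 0.3)))
  for (cs in cases) {
    phi <- metcor:::st_to_unc(cs[[1]], cs[[2]])
    back <- metcor:::st_from_unc(cs[[1]], phi)
    expect_equal(back, cs[[2]], tolerance = 1e-7)
  }
})

test_that("Kronecker structure with identity group part equals independent per-group RC", {
  rk <- cov_structure("RC_KRON", c("a", "b"))
  K <- materialize_cov(rk, c(4, 9, -0.5, 1, 0))  # G_c = I
  rc <- materialize_cov(cov_structure("RC"), c(4, 9, -0.5))
  # rows ordered (int a, int b, slope a, slope b): per-group 2x2 blocks of rc
  for (g in 1:2) {
    expect_equal(unname(K[c(g, g + 2), c(g, g + 2)]), unname(rc),
                 tolerance = 1e-12)
  }
  # cross-group entries vanish
  expect_equal(K[1, 2], 0)
  expect_equal(K[3, 4], 0)
})
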