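#' Parametric covariance structures for genotype-group and related terms
#'
#' A covariance structure is a parametric family for the joint distribution of
#' one random term across countries or agroecological zones (or across the
#' intercept/slope pair of a random-coefficient regression).  The available
#' kinds are:
#'
#' * `"ID"` -- a single variance shared by all levels.
#' * `"DIAG"` -- one variance per group, no covariances (heterogeneous
#'   group-specific structure; also used for every residual).
#' * `"CS"` -- compound symmetry: within-group variance
#'   \eqn{\sigma^2_g + \sigma^2_{gc}} and between-group covariance
#'   \eqn{\sigma^2_g}, so that the implied genetic correlation is
#'   \eqn{\sigma^2_g / (\sigma^2_g + \sigma^2_{gc})}.
#' * `"UN"` -- unstructured: free variances per group and free pairwise
#'   correlations.
#' * `"FA1"` -- factor analytic of order one, \eqn{\Lambda \Lambda^\top + \Psi}
#'   with one loading and one specific variance per group.
#' * `"FA0"` -- reduced-rank factor analytic (\eqn{\Psi} omitted); the
#'   materialised block has rank one and implied correlations of \eqn{\pm 1}.
#' * `"RC"` -- random-coefficient regression: an unstructured 2x2 covariance
#'   for the (intercept, slope) pair of each unit.  The full 2x2 matrix is
#'   required for invariance of the fit under translation and rescaling of
#'   the covariate.
#' * `"RC_KRON"` -- a Kronecker product `Sigma_reg (x) G_c` combining the
#'   intercept/slope covariance with a group covariance matrix whose first
#'   diagonal element is fixed at 1 for identifiability (two groups).
#'
#' @param kind One of `"ID"`, `"DIAG"`, `"CS"`, `"UN"`, `"FA1"`, `"FA0"`,
#'   `"RC"`, `"RC_KRON"`.
#' @param groups Character vector of group labels (countries or zones).
#'   Ignored for `"ID"` and `"RC"`; must have length 2 for `"RC_KRON"`.
#' @return An object of class `cov_structure`.
#' @examples
#' st <- cov_structure("CS", groups = c("C1", "C2"))
#' materialize_cov(st, c(sigma2_g = 1, sigma2_gc = 1))
#' @export
cov_structure <- function(kind, groups = NULL) {
  kind <- match.arg(kind, c("ID", "DIAG", "CS", "UN", "FA1", "FA0", "RC", "RC_KRON"))
  if (kind %in% c("ID", "RC")) {
    groups <- NULL
  } else {
    if (is.null(groups) || length(groups) < 1) {
      abort(sprintf("structure '%s' needs a vector of group labels", kind))
    }
    groups <- as.character(groups)
  }
  if (kind == "RC_KRON" && length(groups) != 2) {
    abort("RC_KRON is defined for exactly two groups")
  }
  L <- if (is.null(groups)) 1L else length(groups)
  structure(
    list(kind = kind, groups = groups, L = L,
         dim = switch(kind, ID = 1L, RC = 2L, RC_KRON = 2L * L, L)),
    class = "cov_structure"
  )
}

#' @export
#' @method print cov_structure
print.cov_structure <- function(x, ...) {
  cat(sprintf("<cov_structure %s, %d group(s), %d parameter(s)>\n",
              x$kind, x$L, n_par(x)))
  invisible(x)
}

un_rho_pairs <- function(L) {
  if (L < 2) return(matrix(integer(0), nrow = 2))
  utils::combn(L, 2)
}

#' Number of free parameters of a covariance structure
#'
#' @param st A [cov_structure()].
#' @return Integer count of free parameters.
#' @export
n_par <- function(st) {
  L <- st$L
  switch(st$kind,
    ID = 1L,
    DIAG = L,
    CS = 2L,
    UN = L + ncol(un_rho_pairs(L)),
    FA1 = 2L * L,
    FA0 = L,
    RC = 3L,
    # Sigma_reg free (3) + G_c with first diagonal fixed to 1 (L = 2: 2 free)
    RC_KRON = 3L + (L - 1L) + ncol(un_rho_pairs(L))
  )
}

#' Parameter names of a covariance structure
#'
#' @inheritParams n_par
#' @return Character vector, in the order expected by [materialize_cov()].
#' @export
par_names <- function(st) {
  L <- st$L
  g <- st$groups
  pr <- un_rho_pairs(L)
  rho_nm <- if (ncol(pr)) {
    vapply(seq_len(ncol(pr)), function(k) {
      sprintf("rho_%s_%s", g[pr[1, k]], g[pr[2, k]])
    }, character(1))
  } else character(0)
  switch(st$kind,
    ID = "sigma2",
    DIAG = sprintf("sigma2_%s", g),
    CS = c("sigma2_g", "sigma2_gc"),
    UN = c(sprintf("sigma2_%s", g), rho_nm),
    FA1 = c(sprintf("lambda_%s", g), sprintf("psi_%s", g)),
    FA0 = sprintf("lambda_%s", g),
    RC = c("sigma2_int", "sigma2_slope", "rho_int_slope"),
    RC_KRON = c("sigma2_int", "sigma2_slope", "rho_int_slope",
                sprintf("gvar_%s", g[-1]), rho_nm)
  )
}

check_par_length <- function(st, params) {
  if (length(params) != n_par(st)) {
    abort(sprintf("structure %s expects %d parameters, got %d",
                  st$kind, n_par(st), length(params)))
  }
  if (any(!is.finite(params))) abort("non-finite covariance parameters")
  invisible(params)
}

psd_check <- function(M, label = "covariance block", tol = 1e-8) {
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -tol * max(sum(diag(M)), 1e-12)) {
    abort(sprintf("%s is not positive semi-definite (min eigenvalue %.3g)",
                  label, min(ev)))
  }
  invisible(M)
}

un_from_pars <- function(vars, rhos, L) {
  if (any(vars < 0)) abort("variances must be non-negative")
  if (length(rhos) && any(abs(rhos) > 1)) abort("|correlation| must be <= 1")
  sd <- sqrt(vars)
  M <- diag(vars, nrow = L)
  pr <- un_rho_pairs(L)
  for (k in seq_len(ncol(pr))) {
    i <- pr[1, k]; j <- pr[2, k]
    M[i, j] <- M[j, i] <- rhos[k] * sd[i] * sd[j]
  }
  M
}

#' Materialise a covariance structure as a matrix
#'
#' Builds the full covariance block implied by a structure and a parameter
#' vector: the group-by-group genetic covariance for `CS`/`UN`/`FA1`/`FA0`,
#' the 2x2 intercept/slope covariance for `RC`, and the Kronecker product
#' `Sigma_reg (x) G_c` (rows ordered intercept-by-group then slope-by-group)
#' for `RC_KRON`.  The result is checked for symmetry and positive
#' semi-definiteness.
#'
#' @inheritParams n_par
#' @param params Numeric vector of parameters in the order of [par_names()].
#' @return A symmetric positive semi-definite matrix with labelled rows.
#' @examples
#' materialize_cov(cov_structure("UN", c("a", "b")), c(11.292, 15.021, 0.890))
#' @export
materialize_cov <- function(st, params) {
  check_par_length(st, params)
  params <- unname(as.numeric(params))
  L <- st$L
  M <- switch(st$kind,
    ID = matrix(params[1], 1, 1),
    DIAG = diag(params, nrow = L),
    CS = {
      if (any(params < 0)) abort("CS variances must be non-negative")
      matrix(params[1], L, L) + diag(params[2], nrow = L)
    },
    UN = un_from_pars(params[1:L], params[-(1:L)], L),
    FA1 = {
      lam <- params[1:L]; psi <- params[-(1:L)]
      if (any(psi < 0)) abort("FA1 specific variances psi must be non-negative")
      tcrossprod(lam) + diag(psi, nrow = L)
    },
    FA0 = tcrossprod(params),
    RC = un_from_pars(params[1:2], params[3], 2L),
    RC_KRON = {
      sreg <- un_from_pars(params[1:2], params[3], 2L)
      gv <- c(1, params[3 + seq_len(L - 1)])
      gc <- un_from_pars(gv, params[(3 + L - 1 + 1):length(params)], L)
      kronecker(sreg, gc)
    }
  )
  nm <- switch(st$kind,
    ID = "u",
    RC = c("int", "slope"),
    RC_KRON = as.vector(outer(st$groups, c("int", "slope"),
                              function(g, c) paste(c, g, sep = ":"))),
    st$groups
  )
  dimnames(M) <- list(nm, nm)
  psd_check(M, sprintf("%s block", st$kind))
  M
}

#' Genetic correlation matrix implied by a genotype-group structure
#'
#' Converts the materialised genotype-group covariance into a correlation
#' matrix between countries/zones.  For `CS` every off-diagonal entry equals
#' \eqn{\sigma^2_g/(\sigma^2_g+\sigma^2_{gc})}; for `UN` the fitted
#' correlations are returned unchanged; for `FA1` the correlation is
#' \eqn{\lambda_l\lambda_{l'}/\sqrt{(\lambda_l^2+\psi_l)(\lambda_{l'}^2+\psi_{l'})}};
#' for `FA0` it is \eqn{\pm 1} according to the loading signs.  For
#' `RC_KRON` the correlation of the group part `G_c` is returned.
#'
#' @inheritParams materialize_cov
#' @return Correlation matrix with group labels.
#' @export
implied_genetic_correlation <- function(st, params) {
  if (!st$kind %in% c("CS", "UN", "FA1", "FA0", "RC_KRON")) {
    abort(sprintf("'%s' is not a genotype-group structure", st$kind))
  }
  check_par_length(st, params)
  params <- unname(as.numeric(params))
  L <- st$L
  M <- if (st$kind == "RC_KRON") {
    gv <- c(1, params[3 + seq_len(L - 1)])
    un_from_pars(gv, params[(3 + L):length(params)], L)
  } else {
    materialize_cov(st, params)
  }
  v <- diag(M)
  if (any(v <= 0)) {
    abort(sprintf("zero total variance in group(s) %s: correlation undefined",
                  paste(st$groups[v <= 0], collapse = ", ")))
  }
  R <- M / sqrt(outer(v, v))
  diag(R) <- 1
  dimnames(R) <- list(st$groups, st$groups)
  R
}

## ---- unconstrained parameterisation used by the optimizer ----------------
## variances on log scale, pairwise correlations via atanh (L = 2 and RC),
## log-Cholesky for UN with 3+ groups, free loadings with log psi for FA.

RHO_CAP <- 0.999

st_to_unc <- function(st, nat) {
  L <- st$L
  nat <- unname(as.numeric(nat))
  clip <- function(r) pmin(pmax(r, -RHO_CAP), RHO_CAP)
  switch(st$kind,
    ID = log(nat),
    DIAG = log(nat),
    CS = log(pmax(nat, 1e-12)),
    UN = {
      if (L <= 2) {
        c(log(nat[1:L]), if (L == 2) atanh(clip(nat[3])))
      } else {
        M <- un_from_pars(nat[1:L], nat[-(1:L)], L)
        Ch <- t(chol(M + diag(1e-10 * mean(diag(M)), L)))
        mask <- lower.tri(Ch, diag = TRUE)
        phi <- Ch[mask]
        didx <- which((row(Ch) == col(Ch))[mask])
        phi[didx] <- log(diag(Ch))
        phi
      }
    },
    FA1 = c(nat[1:L], log(pmax(nat[-(1:L)], 1e-12))),
    FA0 = nat,
    RC = c(log(nat[1:2]), atanh(clip(nat[3]))),
    RC_KRON = c(log(nat[1:2]), atanh(clip(nat[3])),
                log(nat[3 + seq_len(L - 1)]),
                atanh(clip(nat[(3 + L):length(nat)])))
  )
}

st_from_unc <- function(st, phi) {
  L <- st$L
  switch(st$kind,
    ID = exp(phi),
    DIAG = exp(phi),
    CS = exp(phi),
    UN = {
      if (L <= 2) {
        c(exp(phi[1:L]), if (L == 2) tanh(phi[3]))
      } else {
        Ch <- matrix(0, L, L)
        Ch[lower.tri(Ch, diag = TRUE)] <- phi
        diag(Ch) <- exp(diag(Ch))
        M <- tcrossprod(Ch)
        v <- diag(M)
        pr <- un_rho_pairs(L)
        rho <- vapply(seq_len(ncol(pr)), function(k) {
          M[pr[1, k], pr[2, k]] / sqrt(v[pr[1, k]] * v[pr[2, k]])
        }, numeric(1))
        c(v, rho)
      }
    },
    FA1 = c(phi[1:L], exp(phi[-(1:L)])),
    FA0 = phi,
    RC = c(exp(phi[1:2]), tanh(phi[3])),
    RC_KRON = c(exp(phi[1:2]), tanh(phi[3]),
                exp(phi[3 + seq_len(L - 1)]),
                tanh(phi[(3 + L):length(phi)]))
  )
}

# box bounds in the unconstrained space; `logb` is log of the variance floor
st_bounds <- function(st, logb) {
  L <- st$L
  rcap <- atanh(RHO_CAP)
  big <- 50
  bnd <- function(lower, upper) list(lower = lower, upper = upper)
  switch(st$kind,
    ID = bnd(logb, big),
    DIAG = bnd(rep(logb, L), rep(big, L)),
    CS = bnd(rep(logb, 2), rep(big, 2)),
    UN = {
      if (L <= 2) {
        bnd(c(rep(logb, L), if (L == 2) -rcap),
            c(rep(big, L), if (L == 2) rcap))
      } else {
        lo <- rep(-big, L * (L + 1) / 2)
        hi <- rep(big, L * (L + 1) / 2)
        Ch <- matrix(0, L, L)
        mask <- lower.tri(Ch, diag = TRUE)
        lo[which((row(Ch) == col(Ch))[mask])] <- logb / 2
        bnd(lo, hi)
      }
    },
    FA1 = bnd(c(rep(-1e3, L), rep(logb, L)), c(rep(1e3, L), rep(big, L))),
    FA0 = bnd(rep(-1e3, L), rep(1e3, L)),
    RC = bnd(c(logb, logb, -rcap), c(big, big, rcap)),
    RC_KRON = {
      npr <- ncol(un_rho_pairs(L))
      bnd(c(logb, logb, -rcap, rep(logb, L - 1), rep(-rcap, npr)),
          c(big, big, rcap, rep(big, L - 1), rep(rcap, npr)))
    }
  )
}

# heuristic natural starting values given a variance share for this term
st_start <- function(st, share) {
  L <- st$L
  switch(st$kind,
    ID = share,
    DIAG = rep(share, L),
    CS = c(share / 2, share / 2),
    UN = c(rep(share, L), rep(0.3, ncol(un_rho_pairs(L)))),
    FA1 = c(rep(sqrt(share / 2), L), rep(share / 2, L)),
    FA0 = rep(sqrt(share), L),
    RC = c(share, share, 0),
    RC_KRON = c(share, share, 0, rep(1, L - 1), rep(0.3, ncol(un_rho_pairs(L))))
  )
}

# which natural parameters are variances (candidates for boundary flags)
st_var_flags <- function(st) {
  L <- st$L
  switch(st$kind,
    ID = TRUE,
    DIAG = rep(TRUE, L),
    CS = rep(TRUE, 2),
    UN = c(rep(TRUE, L), rep(FALSE, ncol(un_rho_pairs(L)))),
    FA1 = c(rep(FALSE, L), rep(TRUE, L)),
    FA0 = rep(FALSE, L),
    RC = c(TRUE, TRUE, FALSE),
    RC_KRON = c(TRUE, TRUE, FALSE, rep(TRUE, L - 1),
                rep(FALSE, ncol(un_rho_pairs(L))))
  )
}

# sign convention applied when reporting FA estimates
st_canonicalize <- function(st, nat) {
  if (st$kind %in% c("FA1", "FA0")) {
    L <- st$L
    lam <- nat[1:L]
    nz <- which(abs(lam) > 1e-12)
    if (length(nz) && lam[nz[1]] < 0) nat[1:L] <- -lam
  }
  nat
}
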