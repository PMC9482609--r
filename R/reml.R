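## REML / ML engine.
##
## The restricted log-likelihood is evaluated through the mixed-model
## equations: with V = sum_t Z_t G_t Z_t' + R and
## C = [X Z]' R^-1 [X Z] + blockdiag(0, G^-1),
##   -2 l_R = (n - p) log 2pi + log|R| + log|G| + log|C| + y' P y,
## where y'Py = y'R^-1 y - r' C^-1 r with r = [X Z]' R^-1 y.  For full ML
## with the fixed effects profiled out,
##   -2 l_ML = n log 2pi + log|R| + log|G| + log|C_uu| + y' P y,
## with C_uu the random-effect block of C.  All cross-products are computed
## once per design; each likelihood evaluation only refills the numeric
## values of C (whose sparsity pattern is fixed) and reuses the cached
## symbolic Cholesky factorisation.

# covariance block without the validation overhead of materialize_cov()
st_block <- function(st, nat) {
  L <- st$L
  switch(st$kind,
    ID = matrix(nat[1], 1, 1),
    DIAG = diag(nat, nrow = L),
    CS = matrix(nat[1], L, L) + diag(nat[2], nrow = L),
    UN = un_from_pars(nat[1:L], nat[-(1:L)], L),
    FA1 = tcrossprod(nat[1:L]) + diag(nat[-(1:L)], nrow = L),
    FA0 = tcrossprod(nat[1:L]),
    RC = un_from_pars(nat[1:2], nat[3], 2L),
    RC_KRON = {
      sreg <- un_from_pars(nat[1:2], nat[3], 2L)
      gv <- c(1, nat[3 + seq_len(L - 1)])
      gc <- un_from_pars(gv, nat[(3 + L):length(nat)], L)
      kronecker(sreg, gc)
    }
  )
}

make_evaluator <- function(bundle, structs) {
  n <- bundle$n
  p <- bundle$p
  L <- length(bundle$groups)
  terms <- bundle$terms
  Xs <- as(as(bundle$X, "CsparseMatrix"), "generalMatrix")
  W <- do.call(cbind, c(list(Xs), lapply(terms, `[[`, "Z")))
  N <- ncol(W)
  offs <- cumsum(c(p, vapply(terms, function(t) as.numeric(t$q), numeric(1))))
  rg <- bundle$resid_group
  y <- bundle$y

  Mx <- vector("list", L); vl <- matrix(0, N, L)
  yyl <- numeric(L); nl <- integer(L); mkey <- vector("list", L)
  for (l in seq_len(L)) {
    rows <- which(rg == l)
    Wl <- W[rows, , drop = FALSE]
    M <- forceSymmetric(crossprod(Wl))
    Mx[[l]] <- M@x
    mkey[[l]] <- (rep(seq_len(N), diff(M@p)) - 1) * N + (M@i + 1)
    vl[, l] <- as.numeric(crossprod(Wl, y[rows]))
    yyl[l] <- sum(y[rows]^2)
    nl[l] <- length(rows)
  }

  # G^-1 triplets: per term, per slot-pattern, per unit, upper-triangle
  g_i <- integer(0); g_j <- integer(0)
  g_plan <- list()
  for (t in seq_along(terms)) {
    tm <- terms[[t]]
    off <- offs[t]
    plans <- list()
    for (pt in tm$patterns) {
      k <- length(pt$slots)
      li <- row(matrix(0, k, k))[upper.tri(diag(k), diag = TRUE)]
      lj <- col(matrix(0, k, k))[upper.tri(diag(k), diag = TRUE)]
      cols <- vapply(tm$col_of_unit[pt$units], identity,
                     numeric(k))  # k x n_units
      cols <- matrix(cols, nrow = k)
      ii <- off + as.vector(cols[li, , drop = FALSE])
      jj <- off + as.vector(cols[lj, , drop = FALSE])
      g_i <- c(g_i, ii); g_j <- c(g_j, jj)
      plans[[length(plans) + 1]] <- list(slots = pt$slots,
                                         n_units = length(pt$units),
                                         li = li, lj = lj)
    }
    g_plan[[t]] <- plans
  }
  gkey <- (g_j - 1) * N + g_i

  ukey <- sort(unique(c(unlist(mkey), gkey)))
  nnz <- length(ukey)
  ui <- as.integer((ukey - 1) %% N + 1)
  uj <- as.integer((ukey - 1) %/% N + 1)
  C0 <- new("dsCMatrix", i = ui - 1L,
            p = c(0L, cumsum(tabulate(uj, N))),
            x = numeric(nnz), Dim = c(N, N), uplo = "U")
  midx <- lapply(mkey, match, ukey)
  gidx <- match(gkey, ukey)

  # random-effect sub-block pattern, for the profiled full-ML likelihood
  sel_u <- which(ui > p)
  q_all <- N - p
  Cu0 <- new("dsCMatrix", i = ui[sel_u] - p - 1L,
             p = c(0L, cumsum(tabulate(uj[sel_u] - p, q_all))),
             x = numeric(length(sel_u)), Dim = c(q_all, q_all), uplo = "U")

  ch <- NULL
  chu <- NULL
  resid_struct <- cov_structure(if (L == 1) "ID" else "DIAG", bundle$groups)

  # theta: list of natural parameter vectors, one per term plus 'residual'
  eval_fn <- function(theta, ml = FALSE, want_solution = FALSE) {
    s2r <- theta$residual
    if (any(s2r <= 0)) return(list(ok = FALSE))
    xvec <- numeric(nnz)
    for (l in seq_len(L)) {
      xvec[midx[[l]]] <- xvec[midx[[l]]] + Mx[[l]] / s2r[l]
    }
    logdetG <- 0
    gvals <- numeric(length(gkey))
    pos <- 0L
    for (t in seq_along(terms)) {
      Tm <- st_block(structs[[t]], theta[[t]])
      for (pl in g_plan[[t]]) {
        B <- Tm[pl$slots, pl$slots, drop = FALSE]
        R <- tryCatch(chol(B), error = function(e) NULL)
        if (is.null(R)) return(list(ok = FALSE))
        Binv <- chol2inv(R)
        vals <- Binv[cbind(pl$li, pl$lj)]
        nv <- length(vals) * pl$n_units
        gvals[pos + seq_len(nv)] <- rep(vals, pl$n_units)
        pos <- pos + nv
        logdetG <- logdetG + 2 * pl$n_units * sum(log(diag(R)))
      }
    }
    xvec[gidx] <- xvec[gidx] + gvals
    C0@x <- xvec
    if (is.null(ch)) {
      ch <<- tryCatch(Cholesky(C0, LDL = FALSE, perm = TRUE),
                      error = function(e) NULL)
      if (is.null(ch)) return(list(ok = FALSE))
    }
    chl <- tryCatch(update(ch, C0), error = function(e) NULL)
    if (is.null(chl)) return(list(ok = FALSE))
    ch <<- chl
    rhs <- as.numeric(vl %*% (1 / s2r))
    sol <- as.numeric(solve(chl, rhs, system = "A"))
    quad <- sum(yyl / s2r) - sum(rhs * sol)
    logdetR <- sum(nl * log(s2r))
    logdetC <- as.numeric(determinant(chl, sqrt = FALSE)$modulus)
    out <- list(ok = TRUE,
                m2llR = (n - p) * log(2 * pi) + logdetR + logdetG +
                  logdetC + quad)
    if (ml) {
      Cu0@x <- xvec[sel_u]
      if (is.null(chu)) {
        chu <<- tryCatch(Cholesky(Cu0, LDL = FALSE, perm = TRUE),
                         error = function(e) NULL)
        if (is.null(chu)) return(list(ok = FALSE))
      }
      chul <- tryCatch(update(chu, Cu0), error = function(e) NULL)
      if (is.null(chul)) return(list(ok = FALSE))
      chu <<- chul
      logdetCu <- as.numeric(determinant(chul, sqrt = FALSE)$modulus)
      out$m2llML <- n * log(2 * pi) + logdetR + logdetG + logdetCu + quad
    }
    if (want_solution) {
      out$sol <- sol
      # GLS covariance of the fixed effects: leading p x p block of C^-1
      Ei <- sparseMatrix(i = seq_len(p), j = seq_len(p), x = 1,
                         dims = c(N, p))
      CB <- solve(chl, Ei, system = "A")
      out$beta_cov <- as.matrix(CB[seq_len(p), , drop = FALSE])
    }
    out
  }
  list(eval = eval_fn, offs = offs, N = N, p = p, resid_struct = resid_struct)
}

pack_info <- function(bundle, structs, logb, share) {
  L <- length(bundle$groups)
  resid_struct <- cov_structure(if (L == 1) "ID" else "DIAG", bundle$groups)
  all_structs <- c(structs, list(resid_struct))
  names(all_structs) <- c(names(bundle$terms), "residual")
  starts <- lapply(all_structs, st_start, share = share)
  phi0 <- unlist(lapply(seq_along(all_structs), function(i) {
    st_to_unc(all_structs[[i]], starts[[i]])
  }))
  bb <- lapply(all_structs, st_bounds, logb = logb)
  lower <- unlist(lapply(bb, `[[`, "lower"))
  upper <- unlist(lapply(bb, `[[`, "upper"))
  lens <- vapply(seq_along(all_structs), function(i) {
    length(st_to_unc(all_structs[[i]], starts[[i]]))
  }, numeric(1))
  splits <- rep(seq_along(all_structs), lens)
  list(structs = all_structs, phi0 = phi0, lower = lower, upper = upper,
       splits = splits)
}

phi_to_theta <- function(phi, info) {
  parts <- split(phi, info$splits)
  th <- lapply(seq_along(info$structs), function(i) {
    st_from_unc(info$structs[[i]], parts[[i]])
  })
  names(th) <- names(info$structs)
  th
}

#' Fitting options for the REML/ML engine
#'
#' @param max_iterations Iteration cap of the quasi-Newton optimizer.
#' @param reltol Relative convergence tolerance on the objective
#'   (-2 log-likelihood).
#' @param var_bound_frac Variance lower bound as a fraction of the response
#'   variance (the boundary at which components are flagged "bounded").
#' @param restarts Number of optimizer starts.  `NULL` (default) uses 3
#'   random restarts for specifications containing factor-analytic or
#'   random-coefficient structures and a single deterministic start
#'   otherwise.
#' @param compute_ml Also maximise the full (profiled) ML likelihood?
#' @param compute_se Compute standard errors of the covariance parameters
#'   from the inverse numerical Hessian of the restricted likelihood?
#'   (Fixed-effect standard errors are always computed, from the GLS
#'   covariance.)
#' @param seed Seed for the random restarts.
#' @param start Optional warm start: a named list of natural-scale parameter
#'   vectors (as in [restricted_loglik()]'s `theta`), e.g. the `theta_list`
#'   of a previous fit of the same specification.
#' @return A list of class `fit_options`.
#' @export
fit_options <- function(max_iterations = 200, reltol = 1e-8,
                        var_bound_frac = 1e-8, restarts = NULL,
                        compute_ml = FALSE, compute_se = FALSE, seed = 1,
                        start = NULL) {
  stopifnot(reltol > 0, var_bound_frac > 0)
  structure(list(max_iterations = max_iterations, reltol = reltol,
                 var_bound_frac = var_bound_frac, restarts = restarts,
                 compute_ml = compute_ml, compute_se = compute_se,
                 seed = seed, start = start),
            class = "fit_options")
}

#' Restricted log-likelihood of a design bundle at given parameters
#'
#' Evaluates the restricted (REML) log-likelihood of the Gaussian mixed
#' model at a fixed covariance parameter value.  The constant convention
#' includes the full Gaussian constant, i.e.
#' \eqn{-2\ell_R = (n-p)\log 2\pi + \log|V| + \log|X'V^{-1}X| + y'Py}
#' (the same convention as the REML criterion of lme4).
#'
#' @param bundle A [build_design()] result.
#' @param theta Named list of natural-scale parameter vectors, one entry
#'   per random term of the specification (in [par_names()] order for its
#'   structure) plus `residual` (per-group residual variances).
#' @return The restricted log-likelihood (scalar).
#' @export
restricted_loglik <- function(bundle, theta) {
  structs <- lapply(bundle$terms, `[[`, "struct")
  ev <- make_evaluator(bundle, structs)
  need <- c(names(bundle$terms), "residual")
  if (!all(need %in% names(theta))) {
    abort(sprintf("theta must have entries: %s", paste(need, collapse = ", ")))
  }
  res <- ev$eval(theta[need])
  if (!res$ok) abort("covariance matrix not positive definite at theta")
  -res$m2llR / 2
}

#' AIC conventions
#'
#' `reml_aic(ll, n_cov)` is the REML-based criterion
#' \eqn{-2\ell_R + 2 p_{cov}} used to compare covariance structures under a
#' common fixed part; `ml_aic(ll, n_cov, n_fixed)` is the full-ML criterion
#' \eqn{-2\ell_{ML} + 2 (p_{cov} + p_{fix})} used to compare fixed parts.
#'
#' @param ll Log-likelihood (restricted or full).
#' @param n_cov Number of covariance parameters.
#' @param n_fixed Number of fixed-effect coefficients.
#' @return The criterion value.
#' @export
reml_aic <- function(ll, n_cov) -2 * ll + 2 * n_cov

#' @rdname reml_aic
#' @export
ml_aic <- function(ll, n_cov, n_fixed) -2 * ll + 2 * (n_cov + n_fixed)

#' Fit a mixed model by REML (and optionally full ML)
#'
#' Maximises the restricted likelihood over the covariance parameters of a
#' [model_spec()] by quasi-Newton iteration on a transformed scale (log
#' variances, atanh correlations, log-Cholesky for unstructured blocks of
#' three or more groups, free loadings with log specific variances for
#' factor-analytic structures).  Fixed effects are the GLS solution at the
#' optimum and random effects are BLUPs from the mixed-model equations.
#' Reduced-rank FA (`FA0`) terms are fitted as FA1 with the specific
#' variances pinned at the variance floor.
#'
#' Non-convergence (iteration cap) is reported in the `converged` /
#' `ml_converged` fields, never raised as an error.
#'
#' @param data A `trial_data` / `covariate_set` tibble.
#' @param spec A [model_spec()].
#' @param options A [fit_options()].
#' @return An object of class `met_fit`: a list with covariance-parameter
#'   estimates (`theta`, tibble), fixed effects with standard errors
#'   (`beta`), BLUPs (`blups`), restricted and optional full log-likelihoods
#'   and AICs, parameter counts, boundary flags and convergence status.
#' @export
fit_model <- function(data, spec, options = fit_options()) {
  bundle <- build_design(data, spec)
  fit_bundle(bundle, options)
}

fit_bundle <- function(bundle, options = fit_options()) {
  spec <- bundle$spec
  vy <- max(var(bundle$y), 1e-10)  # guard for constant responses
  bound <- options$var_bound_frac * vy
  logb <- log(bound)
  orig_structs <- lapply(bundle$terms, `[[`, "struct")
  # FA0 is singular: fit as FA1 with the specific variances pinned at the floor
  fit_structs <- lapply(orig_structs, function(st) {
    if (st$kind == "FA0") cov_structure("FA1", st$groups) else st
  })
  fa0_swap <- vapply(orig_structs, function(st) st$kind == "FA0", logical(1))

  n_terms <- length(bundle$terms)
  share <- vy / (n_terms + 1)
  info <- pack_info(bundle, fit_structs, logb, share)
  if (any(fa0_swap)) {
    for (t in which(fa0_swap)) {
      idx <- which(info$splits == t)
      Lg <- fit_structs[[t]]$L
      psi_pos <- idx[(Lg + 1):(2 * Lg)]
      info$lower[psi_pos] <- logb
      info$upper[psi_pos] <- logb
      info$phi0[psi_pos] <- logb
    }
  }
  if (!is.null(options$start)) {
    st_names <- names(info$structs)
    if (all(st_names %in% names(options$start))) {
      phi_start <- unlist(lapply(seq_along(info$structs), function(i) {
        st_to_unc(info$structs[[i]], options$start[[st_names[i]]])
      }))
      info$phi0 <- pmin(pmax(phi_start, info$lower), info$upper)
    }
  }
  ev <- make_evaluator(bundle, fit_structs)

  obj <- function(phi, ml = FALSE) {
    th <- phi_to_theta(phi, info)
    r <- ev$eval(th, ml = ml)
    if (!r$ok || !is.finite(if (ml) r$m2llML else r$m2llR)) return(1e10)
    if (ml) r$m2llML else r$m2llR
  }

  kinds <- vapply(fit_structs, `[[`, character(1), "kind")
  n_starts <- options$restarts %||%
    (if (any(kinds %in% c("FA1", "RC", "RC_KRON"))) 3L else 1L)
  starts <- list(info$phi0)
  if (n_starts > 1) {
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv())
    set.seed(options$seed)
    for (s in seq_len(n_starts - 1)) {
      jit <- info$phi0 + rnorm(length(info$phi0), 0, 0.5)
      starts[[s + 1]] <- pmin(pmax(jit, info$lower), info$upper)
    }
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }

  best <- NULL
  for (phi0 in starts) {
    opt <- nlminb(phi0, obj, lower = info$lower, upper = info$upper,
                  control = list(iter.max = options$max_iterations,
                                 eval.max = 20 * options$max_iterations,
                                 rel.tol = options$reltol))
    if (is.null(best) || opt$objective < best$objective - 1e-9) best <- opt
  }
  converged <- best$convergence == 0 ||
    grepl("relative convergence|both X.*converge|singular convergence",
          best$message %||% "")

  theta_hat <- phi_to_theta(best$par, info)
  theta_hat <- lapply(seq_along(info$structs), function(i) {
    st_canonicalize(info$structs[[i]], theta_hat[[i]])
  })
  names(theta_hat) <- names(info$structs)
  fin <- ev$eval(theta_hat, want_solution = TRUE)
  llR <- -best$objective / 2

  # ML stage, started from the REML optimum
  llML <- NA_real_
  ml_converged <- NA
  if (options$compute_ml) {
    optm <- nlminb(best$par, obj, ml = TRUE,
                   lower = info$lower, upper = info$upper,
                   control = list(iter.max = options$max_iterations,
                                  eval.max = 20 * options$max_iterations,
                                  rel.tol = options$reltol))
    ml_converged <- optm$convergence == 0 ||
      grepl("relative convergence", optm$message %||% "")
    llML <- -optm$objective / 2
  }

  # parameter table with boundary flags
  theta_rows <- list()
  for (i in seq_along(info$structs)) {
    st <- info$structs[[i]]
    nat <- theta_hat[[i]]
    vflag <- st_var_flags(st)
    bounded <- (vflag & nat <= 10 * bound) |
      (!vflag & st$kind %in% c("UN", "RC", "RC_KRON") &
         abs(nat) >= RHO_CAP - 1e-6)
    term_nm <- names(info$structs)[i]
    kind_lab <- if (i <= n_terms && fa0_swap[i]) "FA0" else st$kind
    theta_rows[[i]] <- tibble::tibble(
      term = term_nm, structure = kind_lab, parameter = par_names(st),
      estimate = nat, bounded = bounded)
  }
  theta_tab <- dplyr::bind_rows(theta_rows)
  if (any(fa0_swap)) {
    # pinned psi rows are reporting artefacts of the FA0 floor, keep flagged
    theta_tab$bounded[theta_tab$structure == "FA0" &
                        grepl("^psi_", theta_tab$parameter)] <- TRUE
  }

  n_cov_structural <- sum(vapply(orig_structs, function(s) as.numeric(n_par(s)),
                                 numeric(1))) + length(bundle$groups)
  n_cov_nonbounded <- n_cov_structural -
    sum(theta_tab$bounded & !(theta_tab$structure == "FA0" &
                                grepl("^psi_", theta_tab$parameter)))

  p <- bundle$p
  beta_hat <- fin$sol[seq_len(p)]
  beta_cov <- fin$beta_cov
  beta_tab <- tibble::tibble(
    term = colnames(bundle$X), estimate = beta_hat,
    se = sqrt(pmax(diag(beta_cov), 0)))

  blup_rows <- list()
  for (t in seq_along(bundle$terms)) {
    tm <- bundle$terms[[t]]
    cols <- (ev$offs[t] + 1):(ev$offs[t + 1])
    blup_rows[[t]] <- tibble::tibble(
      term = names(bundle$terms)[t],
      unit = tm$units[tm$col_unit],
      slot = tm$slot_labels[tm$col_slot],
      estimate = fin$sol[cols])
  }
  blups <- dplyr::bind_rows(blup_rows)

  fit <- list(
    spec = spec, theta = theta_tab, theta_list = theta_hat,
    beta = beta_tab, blups = blups,
    loglik_reml = llR, loglik_ml = llML,
    aic_reml = reml_aic(llR, n_cov_structural),
    aic_ml = if (is.na(llML)) NA_real_ else
      ml_aic(llML, n_cov_structural, p),
    n_cov = n_cov_structural, n_cov_nonbounded = n_cov_nonbounded,
    n_fixed = p, n_obs = bundle$n, groups = bundle$groups,
    genotype_groups = bundle$genotype_groups,
    dropped_fixed = bundle$dropped_fixed,
    centering = bundle$centering, var_bound = bound,
    converged = converged, ml_converged = ml_converged,
    message = best$message, options = options)
  class(fit) <- "met_fit"

  if (options$compute_se) {
    fit$theta$se <- theta_se_transformed(obj, best$par, info, theta_tab$bounded)
  }
  fit
}

# Covariance-parameter standard errors: observed information (numerical
# Hessian of l_R) on the transformed scale, where steps are well-scaled and
# cannot leave the parameter space, mapped back to the natural scale by the
# delta method.  Directions pinned at a box bound are excluded; parameters
# flagged at the boundary report NA (as their Wald theory breaks down).
theta_se_transformed <- function(obj, phi_hat, info, bounded_flags) {
  nat_of <- function(phi) unlist(phi_to_theta(phi, info))
  n_phi <- length(phi_hat)
  free <- phi_hat > info$lower + 1e-8 & phi_hat < info$upper - 1e-8
  se <- rep(NA_real_, length(nat_of(phi_hat)))
  if (!any(free)) return(se)
  H <- tryCatch(optimHess(phi_hat, obj), error = function(e) NULL)
  if (is.null(H)) return(se)
  covf <- tryCatch(2 * solve(H[free, free, drop = FALSE]),
                   error = function(e) NULL)
  if (is.null(covf)) return(se)
  h <- 1e-5
  J <- vapply(seq_len(n_phi), function(j) {
    e <- numeric(n_phi); e[j] <- h
    (nat_of(phi_hat + e) - nat_of(phi_hat - e)) / (2 * h)
  }, numeric(length(se)))
  Vn <- J[, free, drop = FALSE] %*% covf %*% t(J[, free, drop = FALSE])
  d <- diag(Vn)
  ok <- is.finite(d) & d > 0
  se[ok] <- sqrt(d[ok])
  se[bounded_flags] <- NA_real_
  se
}

#' @export
#' @method print met_fit
print.met_fit <- function(x, ...) {
  cat(sprintf("<met_fit %s>  n = %d, groups: %s\n", x$spec$name, x$n_obs,
              paste(x$groups, collapse = ", ")))
  cat(sprintf("  logLik(REML) = %.3f  AIC(REML) = %.3f  [%d cov. parameters]\n",
              x$loglik_reml, x$aic_reml, x$n_cov))
  if (!is.na(x$loglik_ml)) {
    cat(sprintf("  logLik(ML)   = %.3f  AIC(ML)   = %.3f\n",
                x$loglik_ml, x$aic_ml))
  }
  cat(sprintf("  converged: %s%s\n", x$converged,
              if (any(x$theta$bounded)) sprintf(" | %d parameter(s) at boundary",
                                                sum(x$theta$bounded)) else ""))
  invisible(x)
}

#' Information criteria of a fitted model
#'
#' @param fit A [fit_model()] result.
#' @return List with `aic_reml`, `aic_ml` (`NA` when full ML was not
#'   computed), `n_cov_structural` and `n_cov_nonbounded` (structural count
#'   minus parameters estimated at the boundary).
#' @export
information_criteria <- function(fit) {
  stopifnot(inherits(fit, "met_fit"))
  list(aic_reml = fit$aic_reml, aic_ml = fit$aic_ml,
       n_cov_structural = fit$n_cov, n_cov_nonbounded = fit$n_cov_nonbounded)
}

#' Genetic correlation between groups implied by a fitted model
#'
#' Reads the genotype-group covariance structure off the fit and returns
#' the implied between-country (or between-zone) genetic correlation
#' matrix.  For separate identity-structured genotype and genotype-by-group
#' terms the compound-symmetry correlation
#' \eqn{\sigma^2_g/(\sigma^2_g+\sigma^2_{gz})} is returned.
#'
#' @param fit A `met_fit`.
#' @return Correlation matrix over groups.
#' @export
genetic_correlation <- function(fit) {
  th <- fit$theta
  if ("genotype_group" %in% th$term) {
    row <- th[th$term == "genotype_group", ]
    kind <- row$structure[1]
    st <- cov_structure(if (kind == "FA0") "FA0" else kind, fit$groups)
    est <- row$estimate
    if (kind == "FA0") est <- est[seq_len(st$L)]
    return(implied_genetic_correlation(st, est))
  }
  if ("rc_kron" %in% th$term) {
    row <- th[th$term == "rc_kron", ]
    st <- cov_structure("RC_KRON", fit$groups)
    return(implied_genetic_correlation(st, row$estimate))
  }
  if (all(c("genotype", "genotype_by_group") %in% th$term)) {
    s2g <- th$estimate[th$term == "genotype"]
    s2gc <- th$estimate[th$term == "genotype_by_group"]
    st <- cov_structure("CS", fit$groups)
    return(implied_genetic_correlation(st, c(s2g, s2gc)))
  }
  abort("fit has no random genotype-group structure")
}

#' Predicted genotype means per group
#'
#' Predicted mean yield of each genotype in each country/zone at a
#' reference covariate setting (by default the dataset means: all centred
#' covariates at zero).  For fixed-genotype models this is the BLUE
#' \eqn{\hat\mu + \hat c_l + \hat g_i + \widehat{(gc)}_{il}}; for
#' random-genotype models the genotype terms are BLUPs, so predictions
#' shrink towards the group mean and borrow strength across correlated
#' groups.
#'
#' @param fit A `met_fit`.
#' @param common_only Restrict to genotypes observed in 2 or more groups?
#' @return Tibble with columns `genotype`, `group`, `predicted`.
#' @export
predict_genotype_means <- function(fit, common_only = FALSE) {
  gg <- fit$genotype_groups
  if (common_only) {
    keep <- gg |>
      dplyr::count(.data$genotype) |>
      dplyr::filter(.data$n >= 2)
    gg <- dplyr::semi_join(gg, keep, by = "genotype")
    if (nrow(gg) == 0) abort("no genotype is observed in 2 or more groups")
  }
  beta <- setNames(fit$beta$estimate, fit$beta$term)
  bval <- function(nm) if (nm %in% names(beta)) beta[[nm]] else 0
  base <- vapply(gg$group, function(l) {
    bval("(Intercept)") + bval(paste0("group=", l))
  }, numeric(1))

  pick <- function(term_nm, unit, slot = NULL) {
    b <- fit$blups
    sel <- b$term == term_nm & b$unit == unit
    if (!is.null(slot)) sel <- sel & b$slot == slot
    s <- b$estimate[sel]
    if (length(s)) sum(s) else 0
  }
  gval <- numeric(nrow(gg))
  th_terms <- unique(fit$blups$term)
  for (r in seq_len(nrow(gg))) {
    g <- gg$genotype[r]; l <- gg$group[r]
    v <- 0
    if (fit$spec$genotype_fixed) {
      v <- v + bval(paste0("g=", g)) + bval(paste0("gc=", g, unit_sep, l))
    }
    if ("genotype_group" %in% th_terms) v <- v + pick("genotype_group", g, l)
    if ("genotype" %in% th_terms) v <- v + pick("genotype", g)
    if ("genotype_by_group" %in% th_terms) {
      v <- v + pick("genotype_by_group", paste(g, l, sep = unit_sep))
    }
    if ("rc_genotype" %in% th_terms) v <- v + pick("rc_genotype", g, "int")
    if ("rc_genotype_group" %in% th_terms) {
      v <- v + pick("rc_genotype_group", paste(g, l, sep = unit_sep), "int")
    }
    if ("rc_kron" %in% th_terms) {
      v <- v + pick("rc_kron", g, paste("int", l, sep = unit_sep))
    }
    gval[r] <- v
  }
  tibble::tibble(genotype = gg$genotype, group = gg$group,
                 predicted = unname(base) + gval)
}

#' @export
tidy.met_fit <- function(x, effects = c("fixed", "cov_params", "ran_vals"),
                         ...) {
  effects <- match.arg(effects)
  switch(effects,
    fixed = dplyr::mutate(x$beta,
                          statistic = .data$estimate / .data$se,
                          p.value = 2 * pnorm(-abs(.data$statistic))),
    cov_params = x$theta,
    ran_vals = x$blups)
}

#' @export
glance.met_fit <- function(x, ...) {
  tibble::tibble(
    model = x$spec$name, nobs = x$n_obs,
    logLik_REML = x$loglik_reml, AIC_REML = x$aic_reml,
    logLik_ML = x$loglik_ml, AIC_ML = x$aic_ml,
    n_cov = x$n_cov, n_cov_nonbounded = x$n_cov_nonbounded,
    n_fixed = x$n_fixed, converged = x$converged)
}

#' Serialise a fitted model to JSON / BLUPs to CSV
#'
#' @param fit A `met_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit <- function(fit, path) {
  obj <- list(
    spec = unclass(fit$spec), theta = fit$theta, beta = fit$beta,
    loglik_reml = fit$loglik_reml, loglik_ml = fit$loglik_ml,
    aic_reml = fit$aic_reml, aic_ml = fit$aic_ml,
    n_cov = fit$n_cov, n_cov_nonbounded = fit$n_cov_nonbounded,
    n_fixed = fit$n_fixed, converged = fit$converged,
    centering = fit$centering)
  jsonlite::write_json(obj, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(path)
}

#' @rdname write_fit
#' @export
write_blups <- function(fit, path) {
  readr::write_csv(fit$blups, path, progress = FALSE)
  invisible(path)
}
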