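#' Configuration of a synthetic official trial system
#'
#' Describes the design side of a two-country (or multi-zone) official
#' variety testing system: yearly cohorts of new varieties, testing
#' durations of 1-3 consecutive years, a shared-variety fraction, and a
#' fixed location set per country/zone at which every active variety is
#' grown each year (so generated data are always balanced for varieties and
#' locations within a year).
#'
#' The default cohort dynamics follow the attrition typical of official
#' testing: about half of the candidates are withdrawn after the first
#' year and roughly a quarter reach a third year
#' (`duration_probs = c(0.50, 0.225, 0.275)`).
#'
#' @param years Integer vector of consecutive calendar years.
#' @param groups Character labels of the countries (or zones).
#' @param group_type `"country"` or `"zone"`.  A zone system is generated as
#'   a single country whose locations are stratified into zones.
#' @param locations_per_group Integer, recycled over groups.
#' @param n_new_per_year New varieties entering the whole system each year.
#' @param shared_fraction Probability that a new variety is entered in both
#'   countries (two-country systems only).
#' @param duration_probs Probabilities that a variety is tested 1, 2 or 3
#'   consecutive years (drawn independently per country); must sum to 1.
#' @param shared_entry_lag Integer vector of candidate entry-year lags for
#'   the second country of a shared variety (drawn uniformly).  Shared
#'   varieties enter one country in their cohort year and the other
#'   country `lag` years later, so testing windows differ between
#'   countries, as observed for common varieties in official lists.
#' @param nitrogen List with elements `mean` (kg/ha, location-level mean),
#'   `loc_sd` (between-location sd), `year_sd` (year-to-year sd) and `drift`
#'   (kg/ha per year linear drift, 0 for the default stationary model).
#' @return A list of class `trial_system_config`.
#' @export
trial_system_config <- function(years = 2001:2010,
                                groups = c("C1", "C2"),
                                group_type = c("country", "zone"),
                                locations_per_group = 6,
                                n_new_per_year = 15,
                                shared_fraction = 0.3,
                                duration_probs = c(0.50, 0.225, 0.275),
                                shared_entry_lag = 0:4,
                                nitrogen = list(mean = 150, loc_sd = 20,
                                                year_sd = 10, drift = 0)) {
  group_type <- match.arg(group_type)
  years <- sort(as.integer(years))
  if (length(years) < 1) abort("config error: at least one year required")
  locations_per_group <- rep_len(as.integer(locations_per_group), length(groups))
  if (any(locations_per_group < 1)) abort("config error: zero locations in a group")
  if (abs(sum(duration_probs) - 1) > 1e-8 || any(duration_probs < 0)) {
    abort("duration_probs must be non-negative and sum to 1")
  }
  if (shared_fraction < 0 || shared_fraction > 1) {
    abort("shared_fraction must be in [0, 1]")
  }
  nitrogen <- modifyList(list(mean = 150, loc_sd = 20, year_sd = 10, drift = 0),
                         nitrogen)
  structure(list(years = years, groups = as.character(groups),
                 group_type = group_type,
                 locations_per_group = locations_per_group,
                 n_new_per_year = as.integer(n_new_per_year),
                 shared_fraction = shared_fraction,
                 duration_probs = duration_probs,
                 shared_entry_lag = as.integer(shared_entry_lag),
                 nitrogen = nitrogen),
            class = "trial_system_config")
}

un2 <- function(v1, v2, rho) {
  matrix(c(v1, rho * sqrt(v1 * v2), rho * sqrt(v1 * v2), v2), 2, 2)
}

#' Ground-truth parameters of the synthetic data-generating process
#'
#' Holds every parameter of the trend model with composite genotype-group,
#' year-group and genotype-by-year-group effects: the fixed part (intercept,
#' group offsets, nitrogen slopes, genetic and non-genetic trends) and the
#' group-level covariance matrices of all random terms.  Defaults reproduce
#' the fitted two-country analysis that motivates the package: genotype
#' variances 11.292 and 15.021 with genetic correlation 0.890, year-group
#' variances 59.706/191.284 (correlation 0.812), genotype-by-year
#' 5.144/6.269 (correlation 0.126), location 99.976/89.923, location-year
#' 155.660/172.154, genotype-location 4.356/8.462, residuals 27.775/27.359,
#' nitrogen slope 14.7611 (per 500 kg/ha), genetic trend 1.4695 dt/ha/year
#' and non-genetic trend -0.2882 dt/ha/year.
#'
#' The group intercepts `mu` and `group_effects` are not identified by the
#' published analysis and default to 100 dt/ha and zero offsets.
#'
#' Optionally, `rc` supplies a Kronecker random-coefficient generating
#' process for the genotype-group term: a list with `Sigma_reg` (2x2
#' intercept/slope covariance) and `G_c` (group covariance, first diagonal
#' 1); intercepts and slopes on x1 are then drawn jointly and `Sigma_g` is
#' ignored.
#'
#' @param groups Group labels (must match the config).
#' @param mu Intercept, dt/ha.
#' @param group_effects Additive group offsets, dt/ha.
#' @param beta1 Common nitrogen slope on the x1 scale (dt/ha per `scale` kg/ha).
#' @param eta Group-specific nitrogen slope deviations.
#' @param beta2 Genetic trend, dt/ha per year of first-trial-year.
#' @param beta3 Non-genetic trend, dt/ha per calendar year.
#' @param Sigma_g,Sigma_y,Sigma_gy Group-level covariance matrices (LxL) of
#'   the genotype-group, year-group and genotype-year-group effects.
#' @param s_var,sy_var,gs_var,resid_var Per-group variances of location,
#'   location-year, genotype-location and residual effects.
#' @param rc Optional random-coefficient block, see Details.
#' @return A list of class `genetic_params`.
#' @export
genetic_params <- function(groups = c("C1", "C2"),
                           mu = 100, group_effects = NULL,
                           beta1 = 14.7611, eta = NULL,
                           beta2 = 1.4695, beta3 = -0.2882,
                           Sigma_g = un2(11.292, 15.021, 0.890),
                           Sigma_y = un2(59.706, 191.284, 0.812),
                           Sigma_gy = un2(5.144, 6.269, 0.126),
                           s_var = c(99.976, 89.923),
                           sy_var = c(155.660, 172.154),
                           gs_var = c(4.356, 8.462),
                           resid_var = c(27.775, 27.359),
                           rc = NULL) {
  L <- length(groups)
  if (is.null(group_effects)) group_effects <- rep(0, L)
  if (is.null(eta)) eta <- rep(0, L)
  for (nm in c("Sigma_g", "Sigma_y", "Sigma_gy")) {
    M <- get(nm)
    if (!is.matrix(M) || nrow(M) != L || ncol(M) != L) {
      abort(sprintf("parameter error: %s must be a %dx%d matrix", nm, L, L))
    }
    psd_check(M, sprintf("parameter error: %s", nm))
  }
  for (nm in c("s_var", "sy_var", "gs_var", "resid_var")) {
    v <- rep_len(get(nm), L)
    if (any(v < 0)) abort(sprintf("parameter error: %s must be >= 0", nm))
    assign(nm, v)
  }
  if (!is.null(rc)) {
    if (!all(c("Sigma_reg", "G_c") %in% names(rc))) {
      abort("rc must be a list with Sigma_reg and G_c")
    }
    psd_check(rc$Sigma_reg, "parameter error: rc$Sigma_reg")
    psd_check(rc$G_c, "parameter error: rc$G_c")
  }
  structure(list(groups = as.character(groups), mu = mu,
                 group_effects = rep_len(group_effects, L),
                 beta1 = beta1, eta = rep_len(eta, L),
                 beta2 = beta2, beta3 = beta3,
                 Sigma_g = Sigma_g, Sigma_y = Sigma_y, Sigma_gy = Sigma_gy,
                 s_var = s_var, sy_var = sy_var, gs_var = gs_var,
                 resid_var = resid_var, rc = rc),
            class = "genetic_params")
}

#' Ground-truth preset for a four-zone single-country system
#'
#' Zone-level analogue of [genetic_params()]: a genotype main variance
#' shared by all zones (`g_var`), an optional genotype-by-zone variance
#' (`gz_var`, zero by default so that genotype rankings are identical across
#' zones), and zone-heterogeneous year, location and interaction variances
#' in the range reported for a four-zone national system.
#'
#' @param zones Zone labels.
#' @param g_var Genotype main-effect variance shared across zones.
#' @param gz_var Genotype-by-zone interaction variance.
#' @param ... Passed on to [genetic_params()] to override other components.
#' @return A `genetic_params` object whose `Sigma_g` is the compound-symmetry
#'   matrix `J g_var + I gz_var`.
#' @export
zone_genetic_params <- function(zones = c("Z1", "Z2", "Z3", "Z4"),
                                g_var = 19, gz_var = 0, ...) {
  L <- length(zones)
  Sg <- matrix(g_var, L, L) + diag(gz_var, L)
  defaults <- list(
    groups = zones, Sigma_g = Sg,
    Sigma_y = diag(rep_len(c(196.33, 258.45, 271.25, 49.80), L)),
    Sigma_gy = diag(rep_len(c(4.29, 7.01, 5.08, 8.63), L)),
    s_var = rep_len(c(68.10, 114.26, 35.32, 97.64), L),
    sy_var = rep_len(c(140.17, 226.10, 140.61, 152.76), L),
    gs_var = rep_len(c(7.57, 6.48, 9.36, 6.23), L),
    resid_var = rep(27, L)
  )
  do.call(genetic_params, modifyList(defaults, list(...)))
}

#' Sample yearly variety cohorts
#'
#' Draws the entry/exit pattern of varieties: each year `n_new_per_year`
#' varieties enter; in a two-country system each is entered in both
#' countries with probability `shared_fraction` and otherwise in one country
#' chosen at random; each (variety, country) draws its testing duration from
#' `duration_probs` independently (so shared varieties can have different
#' testing windows per country).  Testing is over consecutive years and is
#' truncated at the final year of the system.
#'
#' Uses the current RNG state; seed upstream (or via
#' [simulate_trial_system()]) for reproducibility.
#'
#' @param cfg A [trial_system_config()].
#' @return Tibble with columns `genotype`, `group`, `entry_year`, `exit_year`.
#' @export
sample_variety_cohorts <- function(cfg) {
  stopifnot(inherits(cfg, "trial_system_config"))
  L <- length(cfg$groups)
  rows <- list()
  idx <- 0L
  for (yr in cfg$years) {
    for (v in seq_len(cfg$n_new_per_year)) {
      idx <- idx + 1L
      gname <- sprintf("G%04d", idx)
      if (cfg$group_type == "zone") {
        # one country: every variety is grown at all locations, hence in
        # every zone, over a single testing window
        dur <- sample.int(3L, 1L, prob = cfg$duration_probs)
        for (grp in cfg$groups) {
          rows[[length(rows) + 1L]] <- list(
            genotype = gname, group = grp, entry_year = yr,
            exit_year = min(yr + dur - 1L, max(cfg$years)))
        }
        next
      }
      shared <- L > 1 && runif(1) < cfg$shared_fraction
      in_groups <- if (L == 1) cfg$groups else
        if (shared) sample(cfg$groups) else sample(cfg$groups, 1)
      for (k in seq_along(in_groups)) {
        # shared varieties enter their second country with a lag, so the
        # two countries' testing windows differ (independent windows)
        lag <- if (k == 1L) 0L else
          cfg$shared_entry_lag[sample.int(length(cfg$shared_entry_lag), 1L)]
        entry <- min(yr + lag, max(cfg$years))
        dur <- sample.int(3L, 1L, prob = cfg$duration_probs)
        rows[[length(rows) + 1L]] <- list(
          genotype = gname, group = in_groups[k], entry_year = entry,
          exit_year = min(entry + dur - 1L, max(cfg$years))
        )
      }
    }
  }
  dplyr::bind_rows(rows)
}

# Draw n iid rows from N(0, Sigma), tolerating singular Sigma (eigen sampler).
rmvn <- function(n, Sigma) {
  L <- nrow(Sigma)
  e <- eigen(Sigma, symmetric = TRUE)
  ev <- pmax(e$values, 0)
  Z <- matrix(rnorm(n * L), n, L)
  Z %*% (e$vectors %*% diag(sqrt(ev), L) %*% t(e$vectors))
}

#' Simulate a trial system with known ground truth
#'
#' Generates a complete synthetic dataset from the trend model: cohorts are
#' sampled, nitrogen is assigned per (location, year), the trend covariates
#' are built exactly as the analysis rebuilds them, and yields are the fixed
#' part plus draws of all random effects from the configured group-level
#' covariance structures.  Draw order is fixed (cohorts, nitrogen, genotype
#' effects, year effects, genotype-year, location, location-year,
#' genotype-location, residual) so a seed fully determines the dataset.
#'
#' Genotype-group effects are drawn for every genotype in all groups, i.e.
#' they exist latently for the group(s) where a genotype is never tested;
#' only tested combinations produce records.
#'
#' @param cfg A [trial_system_config()].
#' @param params A [genetic_params()] with matching groups.
#' @param seed Integer seed; the same seed reproduces the dataset exactly.
#' @param scale Nitrogen covariate divisor used in the generating model.
#' @return List with elements `data` (a `covariate_set` trial dataset),
#'   `truth` (the `genetic_params`, returned verbatim, plus the realised
#'   cohort table as attribute `cohorts`) and `config`.
#' @export
simulate_trial_system <- function(cfg, params = NULL, seed = 1, scale = 500) {
  stopifnot(inherits(cfg, "trial_system_config"))
  if (is.null(params)) {
    params <- if (length(cfg$groups) == 2 && cfg$group_type == "country") {
      genetic_params(groups = cfg$groups)
    } else {
      zone_genetic_params(zones = cfg$groups)
    }
  }
  if (!identical(params$groups, cfg$groups)) {
    abort("parameter error: params$groups must match cfg$groups")
  }
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(as.integer(seed))
  }
  L <- length(cfg$groups)
  zone_system <- cfg$group_type == "zone"

  cohorts <- sample_variety_cohorts(cfg)

  loc_tab <- dplyr::bind_rows(lapply(seq_len(L), function(l) {
    tibble::tibble(
      location = sprintf("%s_L%02d", cfg$groups[l], seq_len(cfg$locations_per_group[l])),
      group = cfg$groups[l]
    )
  }))

  # nitrogen per (location, year): location mean + drift + yearly noise
  nit <- cfg$nitrogen
  loc_mean <- rnorm(nrow(loc_tab), nit$mean, nit$loc_sd)
  nit_tab <- tidyr::crossing(location = loc_tab$location, year = cfg$years) |>
    dplyr::arrange(.data$location, .data$year)
  nit_tab$nitrogen <- pmax(
    0,
    loc_mean[match(nit_tab$location, loc_tab$location)] +
      nit$drift * (nit_tab$year - min(cfg$years)) +
      rnorm(nrow(nit_tab), 0, nit$year_sd)
  )

  # expand cohorts to records: every active variety at every location of its group
  recs <- cohorts |>
    dplyr::rowwise() |>
    dplyr::mutate(year = list(seq(.data$entry_year, .data$exit_year))) |>
    dplyr::ungroup() |>
    tidyr::unnest("year") |>
    dplyr::inner_join(loc_tab, by = "group", relationship = "many-to-many") |>
    dplyr::arrange(.data$genotype, .data$group, .data$year, .data$location)
  recs$country <- if (zone_system) "C1" else recs$group
  recs$zone <- if (zone_system) recs$group else recs$group
  recs <- dplyr::left_join(recs, nit_tab, by = c("location", "year"))

  genos <- sort(unique(cohorts$genotype))
  years <- cfg$years
  gidx <- match(recs$group, cfg$groups)

  # random effects, drawn in fixed order
  if (is.null(params$rc)) {
    g_eff <- rmvn(length(genos), params$Sigma_g)
    g_val <- g_eff[cbind(match(recs$genotype, genos), gidx)]
    slope_val <- 0
  } else {
    Sig <- kronecker(params$rc$Sigma_reg, params$rc$G_c)
    pq <- rmvn(length(genos), Sig)  # columns: int x groups, slope x groups
    g_val <- pq[cbind(match(recs$genotype, genos), gidx)]
    slope_val <- pq[cbind(match(recs$genotype, genos), L + gidx)]
  }
  y_eff <- rmvn(length(years), params$Sigma_y)
  gy_keys <- tidyr::crossing(genotype = genos, year = years)
  gy_eff <- rmvn(nrow(gy_keys), params$Sigma_gy)
  s_eff <- rnorm(nrow(loc_tab), 0,
                 sqrt(params$s_var[match(loc_tab$group, cfg$groups)]))
  sy_keys <- tidyr::crossing(location = loc_tab$location, year = years) |>
    dplyr::arrange(.data$location, .data$year)
  sy_keys$group <- loc_tab$group[match(sy_keys$location, loc_tab$location)]
  sy_eff <- rnorm(nrow(sy_keys), 0,
                  sqrt(params$sy_var[match(sy_keys$group, cfg$groups)]))
  gs_keys <- recs |> dplyr::distinct(.data$genotype, .data$location, .data$group) |>
    dplyr::arrange(.data$genotype, .data$location)
  gs_eff <- rnorm(nrow(gs_keys), 0,
                  sqrt(params$gs_var[match(gs_keys$group, cfg$groups)]))
  eps <- rnorm(nrow(recs), 0, sqrt(params$resid_var[gidx]))

  base <- recs |>
    dplyr::transmute(.data$genotype, .data$location, .data$year,
                     .data$country, .data$zone, .data$nitrogen,
                     yield = 1)  # placeholder, replaced below

  # covariates exactly as the analysis builds them
  cov <- build_covariates(base, scale = scale, nitrogen_key = "location_year")
  x1 <- cov$x1; x2 <- cov$x2; x3 <- cov$x3

  yield <- params$mu + params$group_effects[gidx] +
    (params$beta1 + params$eta[gidx]) * x1 +
    params$beta2 * x2 + params$beta3 * x3 +
    g_val + slope_val * x1 +
    y_eff[cbind(match(recs$year, years), gidx)] +
    gy_eff[cbind(match(paste(recs$genotype, recs$year),
                       paste(gy_keys$genotype, gy_keys$year)), gidx)] +
    s_eff[match(recs$location, loc_tab$location)] +
    sy_eff[match(paste(recs$location, recs$year),
                 paste(sy_keys$location, sy_keys$year))] +
    gs_eff[match(paste(recs$genotype, recs$location),
                 paste(gs_keys$genotype, gs_keys$location))] +
    eps

  dat <- base
  # Gaussian draws can in principle dip below zero; floor at a token positive
  # yield so the dataset invariants hold (probability ~1e-6 per record at the
  # default means, see methods vignette)
  dat$yield <- pmax(yield, 0.1)
  dat <- as_trial_data(dat)
  dat <- build_covariates(dat, scale = scale, nitrogen_key = "location_year")

  truth <- params
  attr(truth, "cohorts") <- cohorts
  list(data = dat, truth = truth, config = cfg)
}

#' Write ground-truth parameters as JSON
#'
#' @param params A `genetic_params` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_true_parameters <- function(params, path) {
  obj <- lapply(unclass(params), function(x) {
    if (is.matrix(x)) unclass(as.data.frame(x)) else x
  })
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
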