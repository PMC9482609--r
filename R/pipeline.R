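#' Country-level model comparison and trend analysis
#'
#' Fits a list of catalogue models to one dataset and assembles the model
#' comparison: restricted and (optionally) full log-likelihoods, both AICs,
#' parameter counts, convergence per model, the implied between-country
#' genetic correlation, the trend estimates of the selected model and the
#' predicted means of common varieties per country from every fitted model.
#' Individual fit failures are recorded per row and the pipeline continues.
#'
#' @param data A `trial_data` tibble with at least two countries.
#' @param models Data frame with columns `name` and `gc_structure` (ignored
#'   for models that do not take one), or `NULL` for the full catalogue
#'   (FG, FGC, RG and RGC with CS/FA01/UN, RC1-RC4).
#' @param options A [fit_options()]; `compute_ml = TRUE` is the default
#'   here so that fixed parts can be compared.
#' @param scale Nitrogen covariate divisor passed to [build_covariates()].
#' @return A list of class `country_analysis` with elements `comparison`
#'   (tibble), `fits` (named list of `met_fit`), `best_reml`, `best_ml`,
#'   `trends` (tibble, from the best-fitting covariate model, named in
#'   `trend_model`), `correlation` (matrix, from the best-fitting
#'   random-genotype model, named in `correlation_model`) and
#'   `predictions` (common-variety predicted means per model).
#' @export
run_country_analysis <- function(data, models = NULL,
                                 options = fit_options(compute_ml = TRUE),
                                 scale = 500) {
  df <- tibble::as_tibble(data)
  if (dplyr::n_distinct(df$country) < 2) {
    abort("country analysis requires at least 2 countries")
  }
  if (nrow(common_genotypes(df)) == 0) {
    warn("no genotype is tested in both countries; between-country genetic correlation is not estimable")
  }
  if (is.null(models)) {
    models <- tibble::tibble(
      name = c("FG", "FGC", "RG", "RG", "RG", "RGC", "RGC", "RGC",
               "RC1", "RC2", "RC3", "RC4"),
      gc_structure = c(NA, NA, "CS", "FA01", "UN", "CS", "FA01", "UN",
                       NA, NA, NA, NA))
  }
  models <- tibble::as_tibble(models)
  if (!"gc_structure" %in% names(models)) models$gc_structure <- NA_character_

  cov <- if (all(c("x1", "x2", "x3") %in% names(df))) data else
    build_covariates(data, scale = scale)

  fits <- list()
  rows <- list()
  for (i in seq_len(nrow(models))) {
    nm <- models$name[i]
    gs <- models$gc_structure[i]
    label <- if (is.na(gs)) nm else paste0(nm, "-", gs)
    spec <- if (nm %in% c("RG", "RGC")) {
      catalogue_model(nm, gs, group = "country")
    } else {
      catalogue_model(nm, group = "country")
    }
    fit <- tryCatch(fit_model(cov, spec, options), error = function(e) e)
    if (inherits(fit, "error")) {
      rows[[i]] <- tibble::tibble(
        model = nm, gc_structure = gs, label = label,
        error = conditionMessage(fit),
        n_fixed = NA_integer_, n_cov = NA_integer_,
        n_cov_nonbounded = NA_integer_,
        loglik_reml = NA_real_, aic_reml = NA_real_,
        loglik_ml = NA_real_, aic_ml = NA_real_, converged = FALSE)
      next
    }
    fits[[label]] <- fit
    rows[[i]] <- tibble::tibble(
      model = nm, gc_structure = gs, label = label, error = NA_character_,
      n_fixed = fit$n_fixed, n_cov = fit$n_cov,
      n_cov_nonbounded = fit$n_cov_nonbounded,
      loglik_reml = fit$loglik_reml, aic_reml = fit$aic_reml,
      loglik_ml = fit$loglik_ml, aic_ml = fit$aic_ml,
      converged = fit$converged)
  }
  comparison <- dplyr::bind_rows(rows)
  pickmin <- function(v) {
    if (all(is.na(v))) NULL else comparison$label[which.min(replace(v, is.na(v), Inf))]
  }
  best_reml <- pickmin(comparison$aic_reml)
  best_ml <- pickmin(comparison$aic_ml)
  # trend estimates need the covariates; the genetic correlation needs a
  # random genotype-group structure -- use the best-fitting model having each
  has_cov <- vapply(fits, function(f) f$spec$covariates, logical(1))
  has_rand <- vapply(fits, function(f) !f$spec$genotype_fixed, logical(1))
  best_of <- function(keep) {
    if (!any(keep)) return(NULL)
    aics <- vapply(fits[keep], `[[`, numeric(1), "aic_reml")
    names(fits)[keep][which.min(aics)]
  }
  trend_model <- best_of(has_cov)
  corr_model <- best_of(has_rand)
  trends <- if (!is.null(trend_model)) trend_estimates(fits[[trend_model]])
  corr <- if (!is.null(corr_model)) {
    tryCatch(genetic_correlation(fits[[corr_model]]), error = function(e) NULL)
  }
  preds <- purrr::imap_dfr(fits, function(f, lab) {
    p <- tryCatch(predict_genotype_means(f, common_only = TRUE),
                  error = function(e) NULL)
    if (is.null(p)) return(NULL)
    p$model <- lab
    p
  })
  structure(list(comparison = comparison, fits = fits,
                 best_reml = best_reml, best_ml = best_ml,
                 trends = trends, trend_model = trend_model,
                 correlation = corr, correlation_model = corr_model,
                 predictions = preds),
            class = "country_analysis")
}

#' @export
#' @method print country_analysis
print.country_analysis <- function(x, ...) {
  cat("Country-level model comparison\n")
  print(dplyr::select(x$comparison, -"error"))
  cat(sprintf("\nBest model by REML-AIC: %s; by ML-AIC: %s\n",
              x$best_reml %||% "(none)", x$best_ml %||% "(none)"))
  if (!is.null(x$correlation)) {
    cat(sprintf("Between-country genetic correlation (%s):\n", x$correlation_model))
    print(round(x$correlation, 3))
  }
  if (!is.null(x$trends)) {
    cat("\nTrend estimates:\n")
    print(x$trends)
  }
  invisible(x)
}

#' @export
tidy.country_analysis <- function(x, ...) x$comparison

#' Trend and nitrogen-slope estimates of a fitted model
#'
#' Extracts the covariate coefficients: the nitrogen slope (reported both
#' on the analysis scale, dt/ha per `scale` kg N/ha, and per 100 kg N/ha),
#' its group-specific deviations, the genetic trend (dt/ha per year of
#' first-trial-year) and the non-genetic trend (dt/ha per calendar year),
#' with Wald standard errors, two-sided p-values and a significance flag at
#' 0.05 (no multiplicity adjustment).
#'
#' @param fit A `met_fit` whose specification includes the covariates.
#' @return Tibble with columns `term`, `label`, `estimate`, `se`,
#'   `statistic`, `p.value`, `signif`, `per_100kg` (nitrogen rows only).
#' @export
trend_estimates <- function(fit) {
  if (!fit$spec$covariates) {
    abort("model was fitted without trend covariates")
  }
  scale <- fit$centering$scale %||% 500
  b <- fit$beta
  lab <- dplyr::case_when(
    b$term == "beta1_x1" ~ "nitrogen",
    grepl("^eta_", b$term) ~ sub("^eta_", "nitrogen_dev:", b$term),
    b$term == "beta2_x2" ~ "genetic_trend",
    b$term == "beta3_x3" ~ "nongenetic_trend",
    TRUE ~ NA_character_)
  out <- b[!is.na(lab), ]
  out$label <- lab[!is.na(lab)]
  out$statistic <- out$estimate / out$se
  out$p.value <- 2 * pnorm(-abs(out$statistic))
  out$signif <- ifelse(out$p.value < 0.05, "*", "ns")
  out$per_100kg <- ifelse(grepl("nitrogen", out$label),
                          out$estimate / (scale / 100), NA_real_)
  dplyr::select(out, "term", "label", "estimate", "se", "statistic",
                "p.value", "signif", "per_100kg")
}

#' Merge under-represented zones into their most correlated neighbour
#'
#' Iteratively merges every zone represented by fewer than `min_locations`
#' locations into the adjacent zone with which its estimated genetic
#' correlation is highest (ties broken by the neighbour with more
#' locations, then lexicographically).  The zone with the fewest locations
#' (then lexicographically first) is processed first.  Merged zones pool
#' their locations and adjacency; their correlation with the remaining
#' zones is the location-weighted mean of the constituents'.  The procedure
#' is deterministic and logged, and running it on its own output changes
#' nothing.
#'
#' @param data A `trial_data` tibble (used to count locations per zone).
#' @param correlation Square genetic-correlation matrix with zone labels,
#'   e.g. from a zone-level fit's [genetic_correlation()].
#' @param adjacency Named list: for each zone, the character vector of its
#'   neighbouring zones (symmetric).
#' @param min_locations Minimum number of locations a zone must keep.
#' @return List with `zone_map` (tibble `zone`, `merged_zone`), `history`
#'   (tibble of merge steps) and `n_locations` (per merged zone).
#' @export
merge_zones <- function(data, correlation, adjacency, min_locations = 4) {
  zl <- tibble::as_tibble(data) |>
    dplyr::distinct(.data$zone, .data$location) |>
    dplyr::count(.data$zone, name = "n_locations")
  zones <- sort(unique(zl$zone))
  if (!all(zones %in% rownames(correlation))) {
    abort("correlation matrix must cover every zone in the data")
  }
  nl <- setNames(zl$n_locations, zl$zone)[zones]
  corr <- correlation[zones, zones, drop = FALSE]
  adj <- lapply(setNames(zones, zones), function(z) {
    intersect(as.character(adjacency[[z]] %||% character(0)), zones)
  })
  members <- lapply(setNames(zones, zones), identity)
  history <- list()

  repeat {
    small <- names(nl)[nl < min_locations]
    if (!length(small)) break
    z <- small[order(nl[small], small)][1]
    nb <- setdiff(adj[[z]], z)
    if (!length(nb)) {
      abort(sprintf("merge error: zone '%s' has fewer than %d locations and no neighbour",
                    z, min_locations))
    }
    sc <- corr[z, nb]
    best <- nb[order(-sc, -nl[nb], nb)][1]
    new_name <- paste(sort(c(members[[z]], members[[best]])), collapse = "+")
    history[[length(history) + 1]] <- tibble::tibble(
      merged = z, into = best, correlation = unname(corr[z, best]),
      new_zone = new_name)
    # weighted correlation of the merged zone with the others
    others <- setdiff(names(nl), c(z, best))
    w <- c(nl[z], nl[best])
    newcor <- if (length(others)) {
      (w[1] * corr[z, others] + w[2] * corr[best, others]) / sum(w)
    } else numeric(0)
    keep <- c(others, new_name)
    corr2 <- matrix(1, length(keep), length(keep),
                    dimnames = list(keep, keep))
    if (length(others)) {
      corr2[others, others] <- corr[others, others]
      corr2[new_name, others] <- newcor
      corr2[others, new_name] <- newcor
    }
    corr <- corr2
    members[[new_name]] <- sort(c(members[[z]], members[[best]]))
    adj[[new_name]] <- setdiff(union(adj[[z]], adj[[best]]), c(z, best))
    for (o in names(adj)) {
      if (any(c(z, best) %in% adj[[o]])) {
        adj[[o]] <- union(setdiff(adj[[o]], c(z, best)), new_name)
      }
    }
    nl[new_name] <- sum(w)
    nl <- nl[keep]
    members <- members[keep]
    adj <- adj[keep]
  }
  zone_map <- dplyr::bind_rows(lapply(names(members), function(m) {
    tibble::tibble(zone = members[[m]], merged_zone = m)
  })) |> dplyr::arrange(.data$zone)
  list(zone_map = zone_map,
       history = if (length(history)) dplyr::bind_rows(history) else
         tibble::tibble(merged = character(0), into = character(0),
                        correlation = numeric(0), new_zone = character(0)),
       n_locations = nl)
}

#' Apply a merged zoning to a dataset
#'
#' @param data A `trial_data` tibble.
#' @param zone_map Tibble `zone` -> `merged_zone` from [merge_zones()].
#' @return The dataset with `zone` replaced by the merged zoning.
#' @export
apply_zoning <- function(data, zone_map) {
  df <- tibble::as_tibble(data)
  m <- setNames(zone_map$merged_zone, zone_map$zone)
  unknown <- setdiff(unique(df$zone), names(m))
  if (length(unknown)) {
    abort(sprintf("zones not covered by zone_map: %s",
                  paste(unknown, collapse = ", ")))
  }
  df$zone <- unname(m[df$zone])
  out <- as_trial_data(df)
  cent <- attr(data, "centering", exact = TRUE)
  if (!is.null(cent)) {
    attr(out, "centering") <- cent
    class(out) <- unique(c("covariate_set", class(out)))
  }
  out
}

#' Zone-level analysis: variance components and between-zone correlations
#'
#' Fits the zone-level random-genotype trend model twice: once in the
#' variance-component parameterisation (separate identity-structured
#' genotype and genotype-by-zone terms, heterogeneous diagonal year-zone
#' and genotype-year-zone structures) to report per-zone variance
#' components, and once with a genotype-zone covariance structure
#' (unstructured up to 4 zones, factor-analytic beyond, with an automatic
#' UN-to-FA1 fallback when the unstructured fit does not converge) to
#' report the between-zone genetic correlation matrix.
#'
#' When the genotype-by-zone variance is estimated at the boundary the
#' result carries a single-zone recommendation: genotype rankings do not
#' change across zones, so there is no necessity for agroecological
#' zonation.
#'
#' @param data A `trial_data` tibble with a zone column (2+ zones).
#' @param options A [fit_options()].
#' @param correlation Also fit the correlation model? (Skipping it halves
#'   the cost when only variance components are needed.)
#' @param scale Nitrogen covariate divisor.
#' @return A list of class `zone_analysis` with `components` (tibble),
#'   `gz_variance`, `single_zone_recommended`, `correlation` (matrix or
#'   `NULL`), `correlation_structure`, and the underlying fits.
#' @export
run_zone_analysis <- function(data, options = fit_options(),
                              correlation = TRUE, scale = 500) {
  df <- tibble::as_tibble(data)
  zones <- sort(unique(df$zone))
  if (length(zones) < 2) abort("zone analysis requires at least 2 zones")
  cov <- if (all(c("x1", "x2", "x3") %in% names(df))) data else
    build_covariates(data, scale = scale)

  spec_vc <- catalogue_model("RGC", "SEP", group = "zone")
  fit_vc <- fit_model(cov, spec_vc, options)
  th <- fit_vc$theta
  gz <- th$estimate[th$term == "genotype_by_group"]
  # "at the boundary" for the zonation call: within 1e-3 dt^2/ha^2 of the
  # variance floor (a negligible interaction on the yield scale)
  single <- gz <= fit_vc$var_bound + 1e-3
  components <- th |>
    dplyr::mutate(zone = dplyr::if_else(
      .data$structure == "DIAG" | .data$term == "residual",
      sub("^sigma2_", "", .data$parameter), NA_character_)) |>
    dplyr::select("term", "zone", "parameter", "estimate", "bounded")

  corr <- NULL
  fit_corr <- NULL
  corr_structure <- NULL
  if (correlation) {
    corr_structure <- if (length(zones) <= 4) "UN" else "FA1"
    spec_corr <- catalogue_model("RGC", corr_structure, group = "zone")
    fit_corr <- tryCatch(fit_model(cov, spec_corr, options),
                         error = function(e) NULL)
    if ((is.null(fit_corr) || !fit_corr$converged) && corr_structure == "UN") {
      corr_structure <- "FA1"
      spec_corr <- catalogue_model("RGC", "FA1", group = "zone")
      fit_corr <- tryCatch(fit_model(cov, spec_corr, options),
                           error = function(e) NULL)
    }
    if (!is.null(fit_corr)) corr <- genetic_correlation(fit_corr)
  }
  structure(list(components = components, gz_variance = gz,
                 single_zone_recommended = isTRUE(single),
                 correlation = corr, correlation_structure = corr_structure,
                 fit_components = fit_vc, fit_correlation = fit_corr),
            class = "zone_analysis")
}

#' @export
#' @method print zone_analysis
print.zone_analysis <- function(x, ...) {
  cat("Zone-level analysis\n")
  cat(sprintf("  genotype-by-zone variance: %.4g%s\n", x$gz_variance,
              if (x$single_zone_recommended)
                "  (at boundary: no necessity for agroecological zonation)"
              else ""))
  if (!is.null(x$correlation)) {
    cat(sprintf("  between-zone genetic correlation (%s):\n",
                x$correlation_structure))
    print(round(x$correlation, 3))
  }
  invisible(x)
}

#' @export
tidy.zone_analysis <- function(x, ...) x$components

#' Scatterplot of common-variety predictions between two groups
#'
#' One panel per model: predicted means of the varieties tested in both
#' groups, first group on the x axis, second on the y axis, with the
#' identity line.  Random-genotype models shrink predictions towards each
#' other, so their panels hug the identity line more tightly than the
#' fixed-genotype panels.
#'
#' @param object A `country_analysis`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.country_analysis <- function(object, ...) {
  pr <- object$predictions
  if (is.null(pr) || nrow(pr) == 0) abort("no common-variety predictions")
  gr <- sort(unique(pr$group))[1:2]
  wide <- pr |>
    dplyr::filter(.data$group %in% gr) |>
    tidyr::pivot_wider(names_from = "group", values_from = "predicted")
  ggplot2::ggplot(wide, ggplot2::aes(.data[[gr[1]]], .data[[gr[2]]])) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::facet_wrap(~model) +
    ggplot2::labs(x = sprintf("Predicted mean, %s (dt/ha)", gr[1]),
                  y = sprintf("Predicted mean, %s (dt/ha)", gr[2])) +
    ggplot2::theme_bw()
}

#' Heatmap of between-zone genetic correlations
#'
#' @param object A `zone_analysis` with a correlation matrix.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.zone_analysis <- function(object, ...) {
  if (is.null(object$correlation)) abort("no correlation matrix in this result")
  m <- object$correlation
  df <- tibble::as_tibble(as.data.frame(as.table(m)), .name_repair = "minimal")
  names(df) <- c("zone1", "zone2", "correlation")
  ggplot2::ggplot(df, ggplot2::aes(.data$zone1, .data$zone2,
                                   fill = .data$correlation)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.2f", .data$correlation)), size = 3) +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", midpoint = 0.5,
                                  limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "genetic\ncorrelation") +
    ggplot2::theme_minimal()
}

#' Write a model-comparison report as CSV
#'
#' @param x A `country_analysis`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_comparison <- function(x, path) {
  readr::write_csv(x$comparison, path, progress = FALSE)
  invisible(path)
}

#' Reproducibility manifest of an analysis run
#'
#' Captures everything needed to re-execute a run bit-identically: the
#' command parameters, the seed, the fitting options, the package version
#' and a timestamp.
#'
#' @param ... Named run parameters (paths, model list, seed, ...).
#' @param options A [fit_options()] to record.
#' @param path Optional path; when given the manifest is written as JSON.
#' @return The manifest list, invisibly when written.
#' @export
run_manifest <- function(..., options = fit_options(), path = NULL) {
  man <- list(parameters = list(...), options = unclass(options),
              package_version = as.character(utils::packageVersion("metcor")),
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  if (!is.null(path)) {
    jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
    return(invisible(man))
  }
  man
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Write a correlation matrix as square CSV / a merge history as JSON
#'
#' @param x A correlation matrix with zone labels, or a [merge_zones()]
#'   result for [write_merge_history()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_correlation <- function(x, path) {
  df <- tibble::as_tibble(as.data.frame(x), rownames = "zone")
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_correlation
#' @export
write_merge_history <- function(x, path) {
  jsonlite::write_json(list(history = x$history, zone_map = x$zone_map,
                            n_locations = as.list(x$n_locations)),
                       path, dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(path)
}
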