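#' Coerce a data frame of trial-mean yield records to a trial dataset
#'
#' A trial dataset holds one row per (genotype, location, year, country)
#' trial mean: the yield of one variety averaged over replicates of one
#' trial.  Mandatory columns are `genotype`, `location`, `year`, `country`
#' and `yield` (dt/ha); optional columns are `zone` (agroecological zone of
#' the location; defaults to the country when absent), `nitrogen` (location
#' nitrogen application in kg/ha) and `series` (e.g. a VCU/PDO tag).
#'
#' Validation enforces the record invariants: finite positive yields,
#' 4-digit integer years, non-negative nitrogen, uniqueness of the
#' (genotype, location, year, country) key, and a location-to-zone/country
#' map in which every location belongs to exactly one zone and one country.
#'
#' @param x A data frame.
#' @return A tibble of class `trial_data` with a `zone_map` attribute
#'   (tibble with columns `location`, `zone`, `country`).
#' @examples
#' toy <- tibble::tibble(
#'   genotype = rep(c("G1", "G2"), each = 2),
#'   location = rep(c("L1", "L2"), 2),
#'   year = 2005L, country = "C1", yield = c(95, 98, 101, 99)
#' )
#' td <- as_trial_data(toy)
#' @export
as_trial_data <- function(x) {
  x <- tibble::as_tibble(x)
  needed <- c("genotype", "location", "year", "country", "yield")
  missing_cols <- setdiff(needed, names(x))
  if (length(missing_cols)) {
    abort(sprintf("schema error: missing mandatory column(s): %s",
                  paste(missing_cols, collapse = ", ")),
          class = "metcor_schema_error")
  }
  if (!is.numeric(x$yield)) {
    suppressWarnings(yv <- as.numeric(x$yield))
    bad <- which(is.na(yv) & !is.na(x$yield))
    if (length(bad)) {
      abort(sprintf("parse error: non-numeric yield at row %d ('%s')",
                    bad[1], x$yield[bad[1]]),
            class = "metcor_parse_error")
    }
    x$yield <- yv
  }
  if (any(!is.finite(x$yield)) || any(x$yield <= 0)) {
    abort("yield must be finite and > 0 for every record",
          class = "metcor_integrity_error")
  }
  x$year <- as.integer(x$year)
  if (any(is.na(x$year)) || any(x$year < 1000L | x$year > 9999L)) {
    abort("year must be a 4-digit integer", class = "metcor_integrity_error")
  }
  if (!"zone" %in% names(x)) x$zone <- x$country
  if ("nitrogen" %in% names(x)) {
    x$nitrogen <- as.numeric(x$nitrogen)
    if (any(!is.na(x$nitrogen) & x$nitrogen < 0)) {
      abort("nitrogen must be >= 0", class = "metcor_integrity_error")
    }
  }
  for (col in c("genotype", "location", "country", "zone")) {
    x[[col]] <- as.character(x[[col]])
  }
  key <- paste(x$genotype, x$location, x$year, x$country, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup)) {
    d <- x[dup[1], ]
    abort(sprintf(
      "integrity error: duplicate record key (genotype=%s, location=%s, year=%d, country=%s)",
      d$genotype, d$location, d$year, d$country),
      class = "metcor_integrity_error")
  }
  zmap <- dplyr::distinct(x, .data$location, .data$zone, .data$country)
  multi <- zmap$location[duplicated(zmap$location)]
  if (length(multi)) {
    abort(sprintf("location(s) mapped to more than one zone/country: %s",
                  paste(unique(multi), collapse = ", ")),
          class = "metcor_integrity_error")
  }
  attr(x, "zone_map") <- zmap
  class(x) <- c("trial_data", class(x))
  x
}

#' Read trial-mean records from a delimited file
#'
#' Reads a CSV/TSV file with a header row and returns a validated
#' [as_trial_data()] tibble.  `schema` renames non-standard columns, e.g.
#' `c(genotype = "variety", yield = "yld")` maps the file's `variety` column
#' onto `genotype`.
#'
#' @param path Path to a UTF-8 delimited text file.
#' @param schema Optional named character vector `c(standard = "file_column")`.
#' @param delim Field delimiter; `","` by default, use `"\t"` for TSV.
#' @return A `trial_data` tibble.
#' @export
read_trials <- function(path, schema = NULL, delim = ",") {
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE, col_types = readr::cols())
  if (!is.null(schema)) {
    for (std in names(schema)) {
      src <- schema[[std]]
      if (!src %in% names(raw)) {
        abort(sprintf("schema error: column '%s' (mapped to '%s') not in file",
                      src, std), class = "metcor_schema_error")
      }
      names(raw)[names(raw) == src] <- std
    }
  }
  as_trial_data(raw)
}

#' Write trial records as CSV
#'
#' @param data A `trial_data` tibble (or plain data frame with its columns).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(data, path) {
  readr::write_csv(tibble::as_tibble(data), path, progress = FALSE)
  invisible(path)
}

#' Per-year within-country balance report
#'
#' In an official testing system every variety active in a year is grown at
#' every location of that year, so within a (year, country) cell the set of
#' genotypes must be identical across locations.  Violations are reported,
#' never dropped.
#'
#' @param data A `trial_data` tibble.
#' @return Tibble with one row per (year, country): `n_locations`,
#'   `n_genotypes`, `balanced`, and `missing_pairs` (count of absent
#'   genotype-location pairs).
#' @export
balance_report <- function(data) {
  tibble::as_tibble(data) |>
    dplyr::group_by(.data$country, .data$year) |>
    dplyr::summarise(
      n_locations = dplyr::n_distinct(.data$location),
      n_genotypes = dplyr::n_distinct(.data$genotype),
      missing_pairs = .data$n_locations * .data$n_genotypes - dplyr::n(),
      balanced = .data$missing_pairs == 0L,
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$country, .data$year)
}

#' Genotypes tested in two or more countries
#'
#' @param data A `trial_data` tibble.
#' @return Tibble with one row per (genotype, country) for genotypes present
#'   in at least two countries, listing the testing years.
#' @export
common_genotypes <- function(data) {
  tab <- tibble::as_tibble(data) |>
    dplyr::distinct(.data$genotype, .data$country, .data$year)
  multi <- tab |>
    dplyr::group_by(.data$genotype) |>
    dplyr::summarise(n_countries = dplyr::n_distinct(.data$country)) |>
    dplyr::filter(.data$n_countries >= 2)
  tab |>
    dplyr::semi_join(multi, by = "genotype") |>
    dplyr::group_by(.data$genotype, .data$country) |>
    dplyr::summarise(years = list(sort(.data$year)), .groups = "drop") |>
    dplyr::arrange(.data$genotype, .data$country)
}

#' Summarise a trial dataset
#'
#' Computes the descriptive report of a testing system: per country the
#' number of observations, varieties, locations, environments
#' (year-location combinations) and zones; the within-year balance flags;
#' and the list of genotypes tested in more than one country.
#'
#' @param data A `trial_data` tibble.
#' @return A list of class `trial_summary` with elements `countries`
#'   (tibble), `balance` (tibble from [balance_report()]) and `common`
#'   (tibble from [common_genotypes()]).
#' @export
summarize_trials <- function(data) {
  if (nrow(data) == 0) abort("empty trial dataset")
  countries <- tibble::as_tibble(data) |>
    dplyr::group_by(.data$country) |>
    dplyr::summarise(
      observations = dplyr::n(),
      varieties = dplyr::n_distinct(.data$genotype),
      locations = dplyr::n_distinct(.data$location),
      environments = dplyr::n_distinct(paste(.data$location, .data$year)),
      zones = dplyr::n_distinct(.data$zone),
      years = paste0(min(.data$year), "-", max(.data$year)),
      .groups = "drop"
    )
  out <- list(countries = countries,
              balance = balance_report(data),
              common = common_genotypes(data))
  class(out) <- "trial_summary"
  out
}

#' @export
#' @method print trial_summary
print.trial_summary <- function(x, ...) {
  cat("Trial system summary\n--------------------\n")
  print(x$countries)
  nb <- sum(!x$balance$balanced)
  cat(sprintf("\nWithin-year balance: %d of %d (year, country) cells unbalanced\n",
              nb, nrow(x$balance)))
  if (nb > 0) print(dplyr::filter(x$balance, !.data$balanced))
  ng <- dplyr::n_distinct(x$common$genotype)
  cat(sprintf("Genotypes tested in 2+ countries: %d\n", ng))
  invisible(x)
}

#' Serialise a trial summary to JSON
#'
#' @param x A `trial_summary`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summary <- function(x, path) {
  obj <- list(
    countries = x$countries,
    balance = x$balance,
    common = dplyr::mutate(x$common,
                           years = vapply(.data$years, paste, character(1),
                                          collapse = ","))
  )
  jsonlite::write_json(obj, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Build the trend and nitrogen covariates
#'
#' Constructs the three covariates of the trend model:
#' * `x1` -- nitrogen application, mean-centred over the records used for
#'   the analysis and divided by `scale` (500 by default, so that variance
#'   estimates of random nitrogen slopes stay on a workable scale),
#' * `x2` -- the first trial year of each variety (its minimum calendar year
#'   over all records, both countries pooled), centred on the mean over
#'   varieties; this is the genetic-trend covariate,
#' * `x3` -- the calendar year of each record, mean-centred; the
#'   non-genetic-trend covariate.
#'
#' Centering constants are stored in the `centering` attribute so that the
#' transformation is invertible and can be re-applied to new data
#' (`constants =` a previous covariate set's attribute gives bit-identical
#' covariates).
#'
#' @param data A `trial_data` tibble.  `nitrogen` must be present for all
#'   records unless `nitrogen_key = "none"`.
#' @param scale Positive divisor for the centred nitrogen covariate.
#' @param nitrogen_key `"location_year"` (default) lets x1 vary by location
#'   and year; `"location"` uses the per-location mean nitrogen for all of a
#'   location's records; `"none"` skips x1 (sets it to 0).
#' @param constants Optional stored `centering` attribute from a previous
#'   call, reused instead of recomputing means.
#' @return The data with columns `x1`, `x2`, `x3` added, class
#'   `covariate_set`, and attribute `centering`.
#' @export
build_covariates <- function(data, scale = 500,
                             nitrogen_key = c("location_year", "location", "none"),
                             constants = NULL) {
  nitrogen_key <- match.arg(nitrogen_key)
  if (!is.null(constants)) {
    scale <- constants$scale
    nitrogen_key <- constants$nitrogen_key
  }
  if (!is.numeric(scale) || scale <= 0) abort("scale must be a positive number")
  x <- tibble::as_tibble(data)

  if (nitrogen_key != "none") {
    if (!"nitrogen" %in% names(x) || any(is.na(x$nitrogen))) {
      bad <- if ("nitrogen" %in% names(x)) {
        unique(x$location[is.na(x$nitrogen)])
      } else unique(x$location)
      abort(sprintf("nitrogen missing for location(s): %s",
                    paste(utils::head(bad, 8), collapse = ", ")),
            class = "metcor_coverage_error")
    }
    nval <- if (nitrogen_key == "location") {
      ave_by <- stats::ave(x$nitrogen, x$location)
      ave_by
    } else {
      stats::ave(x$nitrogen, paste(x$location, x$year, sep = "\r"))
    }
  } else {
    nval <- rep(0, nrow(x))
  }

  first_year <- tibble::as_tibble(x) |>
    dplyr::group_by(.data$genotype) |>
    dplyr::summarise(first_year = min(.data$year), .groups = "drop")

  if (is.null(constants)) {
    constants <- list(
      nitrogen_mean = mean(nval),
      first_year_mean = mean(first_year$first_year),
      year_mean = mean(x$year),
      scale = scale,
      nitrogen_key = nitrogen_key
    )
  }
  fy <- setNames(first_year$first_year, first_year$genotype)
  x$x1 <- (nval - constants$nitrogen_mean) / constants$scale
  x$x2 <- unname(fy[x$genotype]) - constants$first_year_mean
  x$x3 <- x$year - constants$year_mean

  attr(x, "zone_map") <- attr(data, "zone_map", exact = TRUE)
  attr(x, "centering") <- constants
  class(x) <- unique(c("covariate_set", "trial_data", class(x)))
  x
}
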