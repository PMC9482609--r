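## Model specifications: the catalogue of fixed/random-genotype models and
## the vocabulary of random terms.
##
## Term keys (unit factor x within-unit slots):
##   genotype_group   composite genotype-within-group effect; CS/UN/FA1/FA0
##   genotype         genotype main effect; ID (or RC via rc_genotype)
##   genotype_by_group  genotype x group interaction; ID
##   year_group       year effects per group; UN (countries) or DIAG (zones)
##   gy_group         genotype x year effects per group; UN or DIAG
##   location         location main effects; DIAG by group
##   location_year    location x year; DIAG by group
##   genotype_location  genotype x location; DIAG by group
##   rc_genotype      random intercept+slope (on x1) per genotype; RC
##   rc_genotype_group  random intercept+slope per genotype x group; RC
##   rc_kron          joint intercept/slope x group effect; RC_KRON
## The residual is always present, DIAG by group (the three-way interaction
## is absorbed into the residual for trial-mean data).

TERM_KINDS <- list(
  genotype_group = c("CS", "UN", "FA1", "FA0"),
  genotype = "ID",
  genotype_by_group = "ID",
  year_group = c("UN", "DIAG"),
  gy_group = c("UN", "DIAG"),
  location = "DIAG",
  location_year = "DIAG",
  genotype_location = "DIAG",
  rc_genotype = "RC",
  rc_genotype_group = "RC",
  rc_kron = "RC_KRON"
)

#' Construct a model specification
#'
#' Lower-level constructor behind [catalogue_model()]: chooses the fixed
#' part (intercept, group main effect, optional trend/nitrogen covariates,
#' optional fixed genotype and genotype-by-group effects) and a named list
#' of random terms, each bound to a covariance-structure kind.
#'
#' @param name Label for reports.
#' @param group_var Grouping column: `"country"`, `"zone"`, or `NULL` for a
#'   single-population model (no group effect, pooled residual).
#' @param covariates Include the fixed covariate slopes (nitrogen `beta1`
#'   and its group-specific deviations `eta`, genetic trend `beta2`,
#'   non-genetic trend `beta3`)?
#' @param genotype_fixed Put genotype and genotype-by-group in the fixed part?
#' @param random Named character vector/list mapping term keys to structure
#'   kinds, e.g. `c(genotype_group = "UN", year_group = "UN")`.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(name = "custom", group_var = "country",
                       covariates = FALSE, genotype_fixed = FALSE,
                       random = c(year_group = "UN")) {
  random <- as.list(random)
  for (term in names(random)) {
    if (!term %in% names(TERM_KINDS)) {
      abort(sprintf("unknown random term '%s'", term))
    }
    if (!random[[term]] %in% TERM_KINDS[[term]]) {
      abort(sprintf("structure '%s' not allowed for term '%s' (allowed: %s)",
                    random[[term]], term,
                    paste(TERM_KINDS[[term]], collapse = ", ")))
    }
  }
  if (genotype_fixed &&
      any(c("genotype_group", "genotype", "genotype_by_group",
            "rc_genotype", "rc_genotype_group", "rc_kron") %in% names(random))) {
    abort("genotype effects cannot be both fixed and random")
  }
  if (!is.null(group_var)) group_var <- match.arg(group_var, c("country", "zone"))
  structure(list(name = name, group_var = group_var,
                 covariates = isTRUE(covariates),
                 genotype_fixed = isTRUE(genotype_fixed),
                 random = random),
            class = "model_spec")
}

#' @export
#' @method print model_spec
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec %s>\n", x$name))
  cat(sprintf("  group: %s | covariates: %s | fixed genotype: %s\n",
              x$group_var %||% "(none)", x$covariates, x$genotype_fixed))
  for (term in names(x$random)) {
    cat(sprintf("  random %-18s %s\n", term, x$random[[term]]))
  }
  cat("  residual            DIAG (by group)\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' The model catalogue
#'
#' Builds the named models of the two-country / multi-zone analysis:
#'
#' * `FG` -- fixed genotype and genotype-by-group effects, no covariates.
#' * `FGC` -- `FG` plus the nitrogen and trend covariates.
#' * `RG` -- random composite genotype-group effect with a `CS`, `UN` or
#'   `FA01` structure; no covariates.
#' * `RGC` -- `RG` plus covariates.
#' * `RC1` -- `RGC` fixed part; random-coefficient regressions (intercept +
#'   nitrogen slope) for both the genotype and the genotype-by-group terms.
#' * `RC2` -- drops the genotype-level random regression (genotype main
#'   effect stays as a random intercept).
#' * `RC3` -- drops the genotype-by-group random regression.
#' * `RC4` -- a single Kronecker term `Sigma_reg (x) G_c` combining the
#'   genotype and genotype-by-group random regressions.
#'
#' All models share random year-group, genotype-year-group, location,
#' location-year and genotype-location effects and a group-heterogeneous
#' residual.  For zone-level analyses (`group = "zone"`) the year-group and
#' genotype-year-group terms use heterogeneous diagonal structures instead
#' of unstructured ones, and `gc_structure = "SEP"` requests separate
#' identity-structured genotype and genotype-by-zone terms (the
#' variance-component parameterisation of the zone analysis).
#'
#' @param name One of `"FG"`, `"FGC"`, `"RG"`, `"RGC"`, `"RC1"`..`"RC4"`.
#' @param gc_structure Genotype-group structure for `RG`/`RGC`: `"CS"`,
#'   `"UN"`, `"FA01"`, `"FA1"` or `"SEP"`.
#' @param group `"country"` or `"zone"`.
#' @return A [model_spec()].
#' @examples
#' catalogue_model("RGC", "UN")
#' @export
catalogue_model <- function(name, gc_structure = "UN",
                            group = c("country", "zone")) {
  group <- match.arg(group)
  if (!name %in% c("FG", "FGC", "RG", "RGC", "RC1", "RC2", "RC3", "RC4")) {
    abort(sprintf("unknown catalogue model '%s'", name))
  }
  if (!missing(gc_structure) && !name %in% c("RG", "RGC")) {
    abort("gc_structure applies to RG/RGC only")
  }
  zone <- group == "zone"
  env_struct <- if (zone) "DIAG" else "UN"
  base_random <- list(year_group = env_struct, gy_group = env_struct,
                      location = "DIAG", location_year = "DIAG",
                      genotype_location = "DIAG")
  gterm <- function(structure) {
    if (!name %in% c("RG", "RGC")) {
      abort("gc_structure applies to RG/RGC only")
    }
    switch(structure,
      CS = list(genotype_group = "CS"),
      UN = list(genotype_group = "UN"),
      FA01 = list(genotype_group = "FA0"),
      FA1 = list(genotype_group = "FA1"),
      SEP = list(genotype = "ID", genotype_by_group = "ID"),
      abort(sprintf("unknown gc_structure '%s'", structure))
    )
  }
  spec <- switch(name,
    FG = model_spec("FG", group, covariates = FALSE, genotype_fixed = TRUE,
                    random = base_random),
    FGC = model_spec("FGC", group, covariates = TRUE, genotype_fixed = TRUE,
                     random = base_random),
    RG = model_spec(paste0("RG-", gc_structure), group, covariates = FALSE,
                    random = c(gterm(gc_structure), base_random)),
    RGC = model_spec(paste0("RGC-", gc_structure), group, covariates = TRUE,
                     random = c(gterm(gc_structure), base_random)),
    RC1 = model_spec("RC1", group, covariates = TRUE,
                     random = c(list(rc_genotype = "RC",
                                     rc_genotype_group = "RC"), base_random)),
    RC2 = model_spec("RC2", group, covariates = TRUE,
                     random = c(list(genotype = "ID",
                                     rc_genotype_group = "RC"), base_random)),
    RC3 = model_spec("RC3", group, covariates = TRUE,
                     random = c(list(rc_genotype = "RC",
                                     genotype_by_group = "ID"), base_random)),
    RC4 = model_spec("RC4", group, covariates = TRUE,
                     random = c(list(rc_kron = "RC_KRON"), base_random))
  )
  spec
}

#' Serialise / deserialise a model specification as JSON
#'
#' @param spec A `model_spec`.
#' @param path Output path for [write_model_spec()]; input path for
#'   [read_model_spec()].
#' @return `write_model_spec()` returns `path` invisibly;
#'   `read_model_spec()` returns the `model_spec`.
#' @export
write_model_spec <- function(spec, path) {
  jsonlite::write_json(unclass(spec), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_model_spec
#' @export
read_model_spec <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  model_spec(name = obj$name, group_var = obj$group_var,
             covariates = obj$covariates, genotype_fixed = obj$genotype_fixed,
             random = obj$random)
}

spec_uses_covariates <- function(spec) {
  spec$covariates ||
    any(c("rc_genotype", "rc_genotype_group", "rc_kron") %in% names(spec$random))
}
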