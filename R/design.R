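## Design construction: response, fixed design matrix with deterministic
## aliasing removal, and one sparse design block per random term together
## with the bookkeeping the likelihood evaluator needs (unit/slot map and
## slot-pattern groups for block-diagonal G inversion).

unit_sep <- ":"

term_layout <- function(key, kind, df, groups, group_idx) {
  L <- length(groups)
  n <- nrow(df)
  x1 <- if ("x1" %in% names(df)) df$x1 else NULL
  two_col <- function(unit) {
    # random-coefficient pair: intercept + slope on x1 per unit
    list(rec = rep(seq_len(n), 2L),
         unit = rep(unit, 2L),
         slot = rep(1:2, each = n),
         val = c(rep(1, n), x1),
         struct = cov_structure(kind),
         slot_labels = c("int", "slope"))
  }
  switch(key,
    genotype_group = list(rec = seq_len(n), unit = df$genotype,
                          slot = group_idx, val = rep(1, n),
                          struct = cov_structure(kind, groups),
                          slot_labels = groups),
    genotype = list(rec = seq_len(n), unit = df$genotype,
                    slot = rep(1L, n), val = rep(1, n),
                    struct = cov_structure("ID"), slot_labels = "u"),
    genotype_by_group = list(rec = seq_len(n),
                             unit = paste(df$genotype, df$group, sep = unit_sep),
                             slot = rep(1L, n), val = rep(1, n),
                             struct = cov_structure("ID"), slot_labels = "u"),
    year_group = list(rec = seq_len(n), unit = as.character(df$year),
                      slot = group_idx, val = rep(1, n),
                      struct = cov_structure(kind, groups),
                      slot_labels = groups),
    gy_group = list(rec = seq_len(n),
                    unit = paste(df$genotype, df$year, sep = unit_sep),
                    slot = group_idx, val = rep(1, n),
                    struct = cov_structure(kind, groups),
                    slot_labels = groups),
    location = list(rec = seq_len(n), unit = df$location,
                    slot = group_idx, val = rep(1, n),
                    struct = cov_structure("DIAG", groups),
                    slot_labels = groups),
    location_year = list(rec = seq_len(n),
                         unit = paste(df$location, df$year, sep = unit_sep),
                         slot = group_idx, val = rep(1, n),
                         struct = cov_structure("DIAG", groups),
                         slot_labels = groups),
    genotype_location = list(rec = seq_len(n),
                             unit = paste(df$genotype, df$location, sep = unit_sep),
                             slot = group_idx, val = rep(1, n),
                             struct = cov_structure("DIAG", groups),
                             slot_labels = groups),
    rc_genotype = two_col(df$genotype),
    rc_genotype_group = two_col(paste(df$genotype, df$group, sep = unit_sep)),
    rc_kron = list(rec = rep(seq_len(n), 2L),
                   unit = rep(df$genotype, 2L),
                   slot = c(group_idx, L + group_idx),
                   val = c(rep(1, n), x1),
                   struct = cov_structure("RC_KRON", groups),
                   slot_labels = as.vector(outer(groups, c("int", "slope"),
                                                 function(g, c) paste(c, g, sep = unit_sep)))),
    abort(sprintf("unknown term key '%s'", key))
  )
}

build_term <- function(key, kind, df, groups, group_idx) {
  lay <- term_layout(key, kind, df, groups, group_idx)
  col_key <- paste(lay$unit, lay$slot, sep = "\r")
  u_units <- sort(unique(lay$unit))
  # columns ordered by unit then slot
  cols <- unique(data.frame(unit = lay$unit, slot = lay$slot,
                            key = col_key, stringsAsFactors = FALSE))
  cols <- cols[order(match(cols$unit, u_units), cols$slot), , drop = FALSE]
  jidx <- match(col_key, cols$key)
  Z <- sparseMatrix(i = lay$rec, j = jidx, x = lay$val,
                    dims = c(nrow(df), nrow(cols)))
  # slot patterns per unit, for block-wise G inversion
  slot_by_unit <- split(cols$slot, factor(cols$unit, levels = u_units))
  sig <- vapply(slot_by_unit, paste, character(1), collapse = ",")
  patt <- lapply(split(seq_along(u_units), sig), function(uix) {
    list(slots = slot_by_unit[[uix[1]]], units = uix)
  })
  col_of_unit <- split(seq_len(nrow(cols)), factor(cols$unit, levels = u_units))
  list(key = key, struct = lay$struct, Z = Z,
       units = u_units, col_unit = match(cols$unit, u_units),
       col_slot = cols$slot, slot_labels = lay$slot_labels,
       patterns = patt, col_of_unit = col_of_unit, q = nrow(cols))
}

fixed_design <- function(df, spec, groups) {
  n <- nrow(df)
  X <- list(`(Intercept)` = rep(1, n))
  L <- length(groups)
  if (!is.null(spec$group_var) && L > 1) {
    for (l in groups[-1]) {
      X[[paste0("group=", l)]] <- as.numeric(df$group == l)
    }
  }
  if (spec$covariates) {
    X[["beta1_x1"]] <- df$x1
    if (L > 1) {
      for (l in groups[-1]) {
        X[[paste0("eta_", l)]] <- df$x1 * (df$group == l)
      }
    }
    X[["beta2_x2"]] <- df$x2
    X[["beta3_x3"]] <- df$x3
  }
  if (spec$genotype_fixed) {
    gl <- sort(unique(df$genotype))
    for (g in gl[-1]) {
      X[[paste0("g=", g)]] <- as.numeric(df$genotype == g)
    }
    if (L > 1) {
      combos <- unique(df[df$genotype != gl[1] & df$group != groups[1],
                          c("genotype", "group")])
      combos <- combos[order(combos$genotype, combos$group), , drop = FALSE]
      for (r in seq_len(nrow(combos))) {
        g <- combos$genotype[r]; l <- combos$group[r]
        X[[paste0("gc=", g, unit_sep, l)]] <-
          as.numeric(df$genotype == g & df$group == l)
      }
    }
  }
  Xm <- do.call(cbind, X)
  colnames(Xm) <- names(X)
  # deterministic aliasing removal: earlier columns are kept preferentially
  qrx <- qr(Xm)
  keep <- sort(qrx$pivot[seq_len(qrx$rank)])
  dropped <- colnames(Xm)[setdiff(seq_len(ncol(Xm)), keep)]
  list(X = Xm[, keep, drop = FALSE], dropped = dropped)
}

#' Build the design bundle for a model specification
#'
#' Assembles everything the REML engine needs: the response vector, a
#' full-column-rank fixed design matrix (aliased columns removed
#' deterministically, preferring earlier columns; reference levels are the
#' lexicographically first genotype/group), one sparse design block with
#' unit/slot bookkeeping per random term, and the residual group index.
#'
#' @param data A `trial_data` tibble; must be a [build_covariates()] result
#'   when the specification uses covariates or random-coefficient terms.
#' @param spec A [model_spec()].
#' @return A list of class `design_bundle`.
#' @export
build_design <- function(data, spec) {
  df <- tibble::as_tibble(data)
  if (spec_uses_covariates(spec) && !all(c("x1", "x2", "x3") %in% names(df))) {
    abort("specification uses covariates: run build_covariates() first")
  }
  df$group <- if (is.null(spec$group_var)) "all" else df[[spec$group_var]]
  if (is.null(df$group)) {
    abort(sprintf("grouping column '%s' not found", spec$group_var))
  }
  groups <- sort(unique(df$group))
  group_idx <- match(df$group, groups)
  for (term in names(spec$random)) {
    fac_levels <- switch(term,
      genotype_group = , genotype = , rc_genotype = , rc_kron =
        dplyr::n_distinct(df$genotype),
      year_group = dplyr::n_distinct(df$year),
      location = dplyr::n_distinct(df$location),
      2L)
    if (fac_levels < 2L) {
      abort(sprintf("design error: term '%s' needs >= 2 levels of its factor",
                    term))
    }
  }
  terms <- lapply(names(spec$random), function(k) {
    build_term(k, spec$random[[k]], df, groups, group_idx)
  })
  names(terms) <- names(spec$random)
  fx <- fixed_design(df, spec, groups)
  bundle <- list(
    y = df$yield, X = fx$X, dropped_fixed = fx$dropped, terms = terms,
    resid_group = group_idx, groups = groups, n = nrow(df),
    p = ncol(fx$X), spec = spec,
    genotype_groups = dplyr::distinct(df, .data$genotype, .data$group) |>
      dplyr::arrange(.data$genotype, .data$group),
    centering = attr(data, "centering", exact = TRUE)
  )
  class(bundle) <- "design_bundle"
  bundle
}

#' Structural parameter counts of a specification on a dataset
#'
#' Counts the fixed coefficients (columns of the full-rank fixed design) and
#' the structural covariance parameters: the sum of free parameters over the
#' random-term structures plus one residual variance per group.  The
#' structural count is defined by the model; the post-fit "non-bounded"
#' count (structural minus parameters estimated at the boundary) is
#' reported by [information_criteria()].
#'
#' @inheritParams build_design
#' @return Named list with `n_fixed_coefficients` and `n_cov_params`.
#' @export
count_parameters <- function(data, spec) {
  b <- build_design(data, spec)
  n_cov <- sum(vapply(b$terms, function(t) n_par(t$struct), integer(1))) +
    length(b$groups)
  list(n_fixed_coefficients = b$p, n_cov_params = n_cov)
}
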