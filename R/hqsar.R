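#' Fit a hologram QSAR model at one configuration
#'
#' Builds the hologram block for the training molecules, fits NIPALS PLS
#' (centering only — hologram bins are counts on a common scale), and scores
#' every latent-variable count from 1 up to `max_components` by leave-one-out
#' Q^2. The component cap is additionally limited to `floor(n/5)` to guard
#' against overfitting. The reported model uses the Q^2-maximizing component
#' number; `se_cv = sqrt(PRESS / (n - c - 1))` and `se = sqrt(RSS /
#' (n - c - 1))` with `c` components.
#'
#' @param mols List of [parse_smiles()] molecules.
#' @param y Activity (pIC50) vector.
#' @param flags A [distinction_flags()] object.
#' @param fragment_size Length-2 integer vector `c(min_atoms, max_atoms)`.
#' @param length Hologram length.
#' @param max_components Upper bound on latent variables (before the n/5
#'   cap).
#' @return An object of class `hqsar_model`: the PLS fit plus `q2`, `se_cv`,
#'   `r2`, `se`, `n_components`, `q2_by_components`, the configuration, and
#'   the training molecules.
#' @export
hqsar_fit <- function(mols, y, flags = distinction_flags(A = TRUE, DA = TRUE),
                      fragment_size = c(4L, 7L), length = 83L,
                      max_components = 6L) {
  n <- base::length(mols)
  stopifnot(n >= 8L, base::length(y) == n, all(is.finite(y)))
  X <- hologram_matrix(mols, length, flags, fragment_size[1L], fragment_size[2L])
  if (all(apply(X, 2, stats::var) == 0))
    stop("degenerate holograms: no bin varies across the training set")
  cap <- max(1L, min(as.integer(max_components), n %/% 5L,
                     qr(scale(X, scale = FALSE))$rank, n - 2L))
  q2s <- se_cvs <- numeric(cap)
  for (k in seq_len(cap)) {
    cv <- pls_loo_q2(X, y, k, scale = FALSE)
    q2s[k] <- cv$q2
    se_cvs[k] <- cv$se_cv
  }
  best_k <- which.max(q2s)
  pm <- pls_fit(X, y, best_k, scale = FALSE)
  fitted <- predict(pm, X)
  rss <- sum((y - fitted)^2)
  tss <- sum((y - mean(y))^2)
  structure(
    list(pls = pm, n_components = best_k,
         q2 = q2s[best_k], se_cv = se_cvs[best_k],
         q2_by_components = stats::setNames(q2s, seq_len(cap)),
         r2 = 1 - rss / tss, se = sqrt(rss / max(1, n - best_k - 1)),
         flags = flags, fragment_size = as.integer(fragment_size),
         hologram_length = as.integer(length),
         mols = mols, y = y),
    class = "hqsar_model"
  )
}

#' @export
print.hqsar_model <- function(x, ...) {
  cat(sprintf("HQSAR: %s, size %d-%d, length %d, %d LV | Q2 = %.3f, SEcv = %.3f, R2 = %.3f\n",
              format(x$flags), x$fragment_size[1L], x$fragment_size[2L],
              x$hologram_length, x$n_components, x$q2, x$se_cv, x$r2))
  invisible(x)
}

#' Predict activities from an HQSAR model
#'
#' @param object An [hqsar_fit()] model.
#' @param mols List of molecules.
#' @param ... Unused.
#' @return Numeric pIC50 predictions.
#' @export
predict.hqsar_model <- function(object, mols, ...) {
  X <- hologram_matrix(mols, object$hologram_length, object$flags,
                       object$fragment_size[1L], object$fragment_size[2L])
  predict(object$pls, X)
}

#' Select the best row of an HQSAR grid-statistics table
#'
#' The pure selection rule applied at each stage of the grid search: highest
#' Q^2, ties broken by lowest SEcv, then by smallest hologram length. Works
#' equally on freshly computed grids and on previously reported statistics
#' tables used as inputs.
#'
#' @param stats A data.frame with columns `q2`, `se_cv`, and (optionally)
#'   `length`.
#' @return The index of the selected row.
#' @export
hqsar_select <- function(stats) {
  stopifnot(is.data.frame(stats), all(c("q2", "se_cv") %in% names(stats)))
  len <- if ("length" %in% names(stats)) stats$length else rep(0, nrow(stats))
  order(-stats$q2, stats$se_cv, len)[1L]
}

#' Staged HQSAR grid search
#'
#' Reproduces the staged model-selection procedure: (1) with the default
#' fragment size, evaluate every fragment-distinction combination over the
#' hologram-length grid and keep the best by [hqsar_select()]; (2) holding
#' the winning flags, choose the fragment size the same way; (3) holding
#' both, choose the hologram length. Returns the final refitted model and
#' the three per-stage statistics tables.
#'
#' @param mols List of molecules (>= 8).
#' @param y Activity vector.
#' @param flag_sets Named list of [distinction_flags()] candidates.
#' @param sizes List of length-2 size ranges.
#' @param lengths Integer vector of hologram lengths.
#' @param default_size Size range used during flag selection.
#' @param max_components Upper bound on latent variables.
#' @return List with `model` (the final [hqsar_fit()]), `flags_grid`,
#'   `size_grid`, `length_grid` (data.frames), and the selected
#'   `flags`/`size`/`length`.
#' @export
hqsar_grid_train <- function(mols, y,
                             flag_sets = list(
                               "A/C"   = distinction_flags(A = TRUE, C = TRUE),
                               "A/D&A" = distinction_flags(A = TRUE, DA = TRUE),
                               "A/B/C" = distinction_flags(A = TRUE, B = TRUE, C = TRUE),
                               "A/B/H" = distinction_flags(A = TRUE, B = TRUE, H = TRUE)),
                             sizes = list(c(4L, 7L), c(4L, 9L), c(5L, 8L), c(6L, 9L)),
                             lengths = c(53L, 83L, 199L, 307L),
                             default_size = c(4L, 7L),
                             max_components = 6L) {
  eval_cfg <- function(flags, size, len) {
    m <- hqsar_fit(mols, y, flags, size, len, max_components)
    data.frame(q2 = m$q2, se_cv = m$se_cv, r2 = m$r2, se = m$se,
               n_components = m$n_components, length = len)
  }
  best_over_lengths <- function(flags, size) {
    rows <- do.call(rbind, lapply(lengths, function(L) eval_cfg(flags, size, L)))
    rows[hqsar_select(rows), , drop = FALSE]
  }

  flags_grid <- do.call(rbind, lapply(names(flag_sets), function(nm) {
    row <- best_over_lengths(flag_sets[[nm]], default_size)
    cbind(data.frame(flags = nm, stringsAsFactors = FALSE), row)
  }))
  rownames(flags_grid) <- NULL
  best_flags_name <- flags_grid$flags[hqsar_select(flags_grid)]
  best_flags <- flag_sets[[best_flags_name]]

  size_grid <- do.call(rbind, lapply(sizes, function(sz) {
    row <- best_over_lengths(best_flags, sz)
    cbind(data.frame(size = sprintf("%d-%d", sz[1L], sz[2L]),
                     stringsAsFactors = FALSE), row)
  }))
  rownames(size_grid) <- NULL
  best_size <- sizes[[hqsar_select(size_grid)]]

  length_grid <- do.call(rbind, lapply(lengths, function(L)
    eval_cfg(best_flags, best_size, L)))
  rownames(length_grid) <- NULL
  best_length <- lengths[hqsar_select(length_grid)]

  model <- hqsar_fit(mols, y, best_flags, best_size, best_length,
                     max_components)
  list(model = model, flags = best_flags_name, size = best_size,
       length = best_length, flags_grid = flags_grid,
       size_grid = size_grid, length_grid = length_grid)
}

#' Latent-variable selection by the 5% rule
#'
#' Given Q^2 values for an increasing series of component counts, computes
#' the percent increase between consecutive entries,
#' `100 (Q2_high - Q2_low) / Q2_low`, and selects the largest component
#' count whose step gains at least 5%; when no step qualifies, the smallest
#' listed count is kept. Steps with a non-positive Q^2 in the denominator
#' are undefined and flagged `NA`.
#'
#' @param q2_by_components Named numeric vector: component count -> Q^2, in
#'   increasing component order (at least 2 entries).
#' @return List with `chosen` (component count) and `percent_increase`
#'   (named vector, one entry per step).
#' @export
five_percent_rule <- function(q2_by_components) {
  stopifnot(length(q2_by_components) >= 2L, !is.null(names(q2_by_components)))
  comps <- as.integer(names(q2_by_components))
  stopifnot(!anyNA(comps), all(diff(comps) > 0))
  q <- as.numeric(q2_by_components)
  steps <- vapply(seq_len(length(q) - 1L), function(i) {
    if (q[i] <= 0) return(NA_real_)
    100 * (q[i + 1L] - q[i]) / q[i]
  }, numeric(1))
  names(steps) <- comps[-1L]
  qualifying <- which(!is.na(steps) & steps >= 5)
  chosen <- if (length(qualifying)) comps[max(qualifying) + 1L] else comps[1L]
  list(chosen = chosen, percent_increase = steps)
}

#' Per-atom contribution map for an HQSAR prediction
#'
#' Decomposes a molecule's predicted activity over its atoms: each fragment
#' occurrence contributes its bin's PLS regression coefficient, shared
#' equally among the fragment's atoms. Atom contributions therefore sum to
#' `prediction - model intercept` exactly. Atoms are colour-binned from
#' strongly unfavourable to strongly favourable (`red`, `red-orange`,
#' `white`, `yellow`, `green`); default thresholds are the quintiles of the
#' training-set atom-contribution distribution.
#'
#' @param model An [hqsar_fit()] model.
#' @param mol A [parse_smiles()] molecule.
#' @param thresholds Optional increasing numeric vector of 4 cut points.
#' @return An object of class `contribution_map`: data.frame with `atom`,
#'   `element`, `contribution` (pIC50 units), `color`; attributes
#'   `prediction` and `intercept`.
#' @export
contribution_map <- function(model, mol, thresholds = NULL) {
  stopifnot(inherits(model, "hqsar_model"), inherits(mol, "molecule"))
  contrib <- atom_contributions(model, mol)
  if (is.null(thresholds)) thresholds <- default_color_thresholds(model)
  stopifnot(length(thresholds) == 4L, !is.unsorted(thresholds))
  bins <- c("red", "red-orange", "white", "yellow", "green")
  color <- bins[findInterval(contrib, thresholds) + 1L]
  out <- data.frame(atom = seq_along(contrib),
                    element = mol$atoms$element,
                    contribution = contrib, color = color,
                    stringsAsFactors = FALSE)
  attr(out, "prediction") <- model$pls$intercept + sum(contrib)
  attr(out, "intercept") <- model$pls$intercept
  class(out) <- c("contribution_map", "data.frame")
  out
}

# quintile cut points of the training-set atom-contribution distribution
default_color_thresholds <- function(model) {
  train_contrib <- unlist(lapply(model$mols, function(m)
    atom_contributions(model, m)), use.names = FALSE)
  stats::quantile(train_contrib, c(0.2, 0.4, 0.6, 0.8), names = FALSE)
}

atom_contributions <- function(model, mol) {
  occ <- fragment_occurrences(mol, model$flags, model$fragment_size[1L],
                              model$fragment_size[2L])
  beta <- model$pls$coefficients
  contrib <- numeric(nrow(mol$atoms))
  for (i in seq_along(occ$frags)) {
    f <- occ$frags[[i]]
    bin <- as.integer(crc32_cached(occ$keys[i]) %% model$hologram_length) + 1L
    contrib[f] <- contrib[f] + beta[bin] / length(f)
  }
  contrib
}
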