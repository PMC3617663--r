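#' Construct a basis term
#'
#' A model basis term is either the raw descriptor (`form = "linear"`) or a
#' truncated-power spline of it: `<x - a> = max(0, x - a)` (orientation
#' `"x_minus_knot"`) or `<a - x> = max(0, a - x)` (`"knot_minus_x"`). Spline
#' terms are zero on one side of the knot, so a compound below (or above) the
#' knot contributes nothing through that term.
#'
#' @param descriptor Descriptor column name.
#' @param form `"linear"` or `"spline"`.
#' @param knot Knot value in descriptor units (spline only).
#' @param orientation `"x_minus_knot"` or `"knot_minus_x"` (spline only).
#' @return An object of class `basis_term`.
#' @export
basis_term <- function(descriptor,
                       form = c("linear", "spline"),
                       knot = NULL,
                       orientation = c("x_minus_knot", "knot_minus_x")) {
  form <- match.arg(form)
  if (form == "spline") {
    orientation <- match.arg(orientation)
    if (is.null(knot) || !is.finite(knot)) stop("spline term needs a finite knot")
  } else {
    knot <- NULL
    orientation <- NULL
  }
  structure(list(descriptor = as.character(descriptor), form = form,
                 knot = knot, orientation = orientation),
            class = "basis_term")
}

#' @export
format.basis_term <- function(x, ...) {
  if (x$form == "linear") return(x$descriptor)
  if (x$orientation == "x_minus_knot")
    sprintf("<%s-%g>", x$descriptor, x$knot)
  else
    sprintf("<%g-%s>", x$knot, x$descriptor)
}

#' @export
print.basis_term <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Evaluate a basis term on descriptor values
#'
#' @param term A [basis_term()].
#' @param values Named numeric vector (one compound) or a numeric matrix with
#'   descriptor column names (many compounds).
#' @return Numeric vector of term values; spline terms are never negative.
#' @export
eval_term <- function(term, values) {
  stopifnot(inherits(term, "basis_term"))
  if (is.matrix(values)) {
    if (!term$descriptor %in% colnames(values))
      stop(sprintf("descriptor '%s' missing from table", term$descriptor))
    x <- values[, term$descriptor]
  } else {
    if (!term$descriptor %in% names(values))
      stop(sprintf("descriptor '%s' missing from row", term$descriptor))
    x <- values[[term$descriptor]]
  }
  if (term$form == "linear") return(as.numeric(x))
  if (term$orientation == "x_minus_knot") pmax(0, x - term$knot)
  else pmax(0, term$knot - x)
}

#' Construct a linear QSAR model
#'
#' An intercept plus weighted basis terms (linear or spline), e.g. the
#' published five-term GFA spline model [gfa_spline_model()].
#'
#' @param intercept Intercept (pIC50 units).
#' @param terms List of [basis_term()] objects.
#' @param coefficients Numeric vector, one per term.
#' @param fitted_on Optional compound ids the model was fitted on.
#' @return An object of class `qsar_lm`.
#' @export
linear_model <- function(intercept, terms, coefficients, fitted_on = NULL) {
  if (length(terms) != length(coefficients))
    stop("one coefficient per term required")
  stopifnot(all(vapply(terms, inherits, logical(1), "basis_term")))
  structure(list(intercept = as.numeric(intercept), terms = terms,
                 coefficients = as.numeric(coefficients),
                 fitted_on = fitted_on),
            class = "qsar_lm")
}

#' @export
print.qsar_lm <- function(x, digits = 4, ...) {
  rhs <- if (length(x$terms)) {
    paste(sprintf("%+g*%s", signif(x$coefficients, digits),
                  vapply(x$terms, format, character(1))), collapse = " ")
  } else ""
  cat(sprintf("pIC50 = %g %s\n", signif(x$intercept, digits), rhs))
  invisible(x)
}

#' Design matrix for a set of basis terms
#'
#' @param table A [descriptor_table()] or a descriptor matrix.
#' @param terms List of [basis_term()] objects.
#' @return Numeric matrix, one column per term (no intercept column).
#' @export
term_matrix <- function(table, terms) {
  values <- if (inherits(table, "descriptor_table")) table$values else table
  cols <- lapply(terms, eval_term, values = values)
  X <- do.call(cbind, c(cols, list(deparse.level = 0)))
  if (is.null(X)) X <- matrix(numeric(0), nrow = nrow(values), ncol = 0)
  colnames(X) <- vapply(terms, format, character(1))
  X
}

#' Predict activities from a linear QSAR model
#'
#' @param object A `qsar_lm` model.
#' @param table A [descriptor_table()] or named descriptor matrix. All term
#'   descriptors must be present.
#' @param ... Unused.
#' @return Numeric pIC50 vector.
#' @export
predict.qsar_lm <- function(object, table, ...) {
  values <- if (inherits(table, "descriptor_table")) table$values else table
  need <- unique(vapply(object$terms, `[[`, character(1), "descriptor"))
  missing <- setdiff(need, colnames(values))
  if (length(missing))
    stop("missing descriptor column(s): ", paste(missing, collapse = ", "))
  if (!length(object$terms))
    return(rep(object$intercept, nrow(values)))
  X <- term_matrix(values, object$terms)
  drop(object$intercept + X %*% object$coefficients)
}

#' Fit an ordinary least-squares model on basis terms
#'
#' Least-squares fit (via base QR) of activity on the given basis terms plus
#' an intercept.
#'
#' @param table A [descriptor_table()].
#' @param terms List of [basis_term()] objects.
#' @return A `qsar_lm` with extra fields `fitted`, `residuals`, `rss`, `r2`.
#' @export
fit_ols <- function(table, terms) {
  stopifnot(inherits(table, "descriptor_table"))
  n <- nrow(table$values)
  if (n <= length(terms) + 1L)
    stop("not enough compounds for the number of terms")
  X <- cbind(`(Intercept)` = 1, term_matrix(table, terms))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    keep <- qrX$pivot[seq_len(qrX$rank)]
    dropped <- setdiff(colnames(X), colnames(X)[keep])
    stop("rank-deficient design; collinear term(s): ",
         paste(dropped, collapse = ", "))
  }
  fit <- lm.fit(X, table$activity)
  coefs <- fit$coefficients
  fitted <- drop(X %*% coefs)
  rss <- sum((table$activity - fitted)^2)
  tss <- sum((table$activity - mean(table$activity))^2)
  m <- linear_model(intercept = coefs[1L], terms = terms,
                    coefficients = if (length(terms)) coefs[-1L] else numeric(0),
                    fitted_on = table$compound_ids)
  m$fitted <- fitted
  m$residuals <- table$activity - fitted
  m$rss <- rss
  m$r2 <- if (tss > 0) 1 - rss / tss else NA_real_
  m
}

#' Friedman lack-of-fit score
#'
#' The GFA fitness: `LOF = (RSS/m) / (1 - (c + d*p)/m)^2`, where `c` is the
#' number of basis functions, `p` the total number of model parameters, `m`
#' the number of samples, and `d` the smoothness penalty. When the penalty
#' term reaches or exceeds 1 the score is `Inf`, so the genetic search
#' rejects such over-parameterized models.
#'
#' @param rss Residual sum of squares.
#' @param c Basis-function count (non-intercept terms).
#' @param p Total parameter count (typically `c + 1` for the intercept).
#' @param m Sample count.
#' @param d Smoothness factor (default 1).
#' @return The LOF score (lower is better).
#' @export
lof_score <- function(rss, c, p, m, d = 1) {
  pen <- 1 - (c + d * p) / m
  if (pen <= 0) return(Inf)
  (rss / m) / pen^2
}
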