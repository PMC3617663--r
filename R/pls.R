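#' NIPALS partial least squares regression (single response)
#'
#' Iterative NIPALS extraction of latent components from a column-centered
#' (optionally unit-variance scaled) predictor block. With `n_components`
#' equal to the rank of the centered predictor matrix, predictions coincide
#' with ordinary least squares. Scaling defaults off, which suits
#' fragment-count holograms; heterogeneous-unit descriptor blocks should be
#' fitted with `scale = TRUE`.
#'
#' @param X Numeric predictor matrix (n x d).
#' @param y Numeric response vector, length n.
#' @param n_components Number of latent variables, between 1 and
#'   `min(n - 1, d)`.
#' @param scale Scale columns to unit variance (constant columns are left
#'   unscaled)?
#' @return An object of class `pls_model` holding weights, loadings, the
#'   regression vector on the original scale, and centering/scaling
#'   parameters.
#' @export
pls_fit <- function(X, y, n_components, scale = FALSE) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); d <- ncol(X)
  stopifnot(length(y) == n, n >= 2, d >= 1)
  if (stats::var(y) == 0) stop("zero-variance response")
  if (n_components < 1 || n_components > min(n - 1, d))
    stop("n_components must be in [1, min(n-1, d)]")
  x_center <- colMeans(X)
  x_scale <- rep(1, d)
  if (scale) {
    sds <- apply(X, 2, stats::sd)
    x_scale <- ifelse(sds > 0, sds, 1)
  }
  Xc <- sweep(sweep(X, 2, x_center), 2, x_scale, "/")
  y_center <- mean(y)
  u <- y - y_center

  W <- P <- matrix(0, d, n_components)
  Tm <- matrix(0, n, n_components)
  q <- numeric(n_components)
  Xr <- Xc; yr <- u
  a <- 0L
  for (k in seq_len(n_components)) {
    w <- drop(crossprod(Xr, yr))
    wn <- sqrt(sum(w^2))
    if (wn < 1e-12) break   # residual X carries no covariance with y
    w <- w / wn
    t <- drop(Xr %*% w)
    tt <- sum(t^2)
    if (tt < 1e-12) break
    p <- drop(crossprod(Xr, t)) / tt
    qk <- sum(yr * t) / tt
    W[, k] <- w; P[, k] <- p; Tm[, k] <- t; q[k] <- qk
    Xr <- Xr - tcrossprod(t, p)
    yr <- yr - qk * t
    a <- k
  }
  if (a == 0L) stop("no extractable PLS component (X orthogonal to y)")
  W <- W[, seq_len(a), drop = FALSE]
  P <- P[, seq_len(a), drop = FALSE]
  q <- q[seq_len(a)]
  # regression vector in the centered/scaled frame: B = W (P'W)^-1 q
  B <- drop(W %*% solve(crossprod(P, W), q))
  structure(
    list(n_components = a, weights = W, loadings = P, q = q,
         scores = Tm[, seq_len(a), drop = FALSE],
         coefficients = B / x_scale,
         x_center = x_center, x_scale = x_scale, y_center = y_center,
         intercept = y_center - sum((B / x_scale) * x_center)),
    class = "pls_model"
  )
}

#' Predict from a NIPALS PLS model
#'
#' @param object A [pls_fit()] model.
#' @param X New predictor matrix with the same columns as the training block.
#' @param ... Unused.
#' @return Numeric prediction vector.
#' @export
predict.pls_model <- function(object, X, ...) {
  X <- as.matrix(X)
  drop(object$intercept + X %*% object$coefficients)
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("NIPALS PLS: %d component(s), %d predictors\n",
              x$n_components, length(x$coefficients)))
  invisible(x)
}

#' Leave-one-out Q^2 of a PLS model at a fixed component number
#'
#' Refits the PLS model with each sample deleted in turn and accumulates the
#' deletion residuals. Also reports `SEcv = sqrt(PRESS / (n - c - 1))` with
#' `c` components.
#'
#' @inheritParams pls_fit
#' @return List with `q2`, `press`, `se_cv`, `loo_predictions`.
#' @export
pls_loo_q2 <- function(X, y, n_components, scale = FALSE) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  loo <- numeric(n)
  for (i in seq_len(n)) {
    m <- pls_fit(X[-i, , drop = FALSE], y[-i],
                 n_components = min(n_components, n - 2L), scale = scale)
    loo[i] <- predict(m, X[i, , drop = FALSE])
  }
  press <- sum((y - loo)^2)
  tss <- sum((y - mean(y))^2)
  list(q2 = 1 - press / tss, press = press,
       se_cv = sqrt(press / max(1, n - n_components - 1)),
       loo_predictions = loo)
}
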