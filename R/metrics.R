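#' Validation metrics for QSAR models
#'
#' The metric family used to judge internal and external predictive ability:
#' squared correlation with and without intercept, the r_m^2 metrics (mean
#' and delta forms over both axis orientations), predictive R^2 against the
#' training-mean baseline, leave-one-out PRESS/Q^2, classical regression
#' statistics (s, F, adjusted R^2), and Y-randomization with the cR_p^2
#' chance-correlation parameter.
#'
#' @name qsar-metrics
NULL

check_pairs <- function(observed, predicted) {
  if (length(observed) != length(predicted))
    stop("observed and predicted must have equal length")
  if (length(observed) < 2L) stop("need at least 2 pairs")
  if (anyNA(observed) || anyNA(predicted) ||
      any(!is.finite(observed)) || any(!is.finite(predicted)))
    stop("observed/predicted must be finite")
  invisible(TRUE)
}

#' Squared Pearson correlation between observed and predicted activity
#'
#' @param observed Observed pIC50 vector.
#' @param predicted Predicted pIC50 vector, same length.
#' @return r^2 in \[0, 1\]; symmetric in its arguments.
#' @export
pearson_r2 <- function(observed, predicted) {
  check_pairs(observed, predicted)
  if (stats::var(observed) == 0 || stats::var(predicted) == 0)
    stop("undefined metric: zero variance in observed or predicted values")
  stats::cor(observed, predicted)^2
}

#' Squared correlation coefficient without intercept
#'
#' Coefficient of determination of the least-squares fit through the origin,
#' `r0^2 = 1 - sum((y - k x)^2) / sum((y - mean(y))^2)` with slope
#' `k = sum(x y) / sum(x^2)`. Unlike `r^2` it is not symmetric in the axes
#' and may be negative.
#'
#' @param x Values on the first axis.
#' @param y Values on the second axis.
#' @return The through-origin r0^2.
#' @export
r0_squared <- function(x, y) {
  check_pairs(x, y)
  if (sum(x^2) == 0) stop("all-zero x: through-origin slope undefined")
  if (stats::var(y) == 0) stop("zero variance in y")
  k <- sum(x * y) / sum(x^2)
  1 - sum((y - k * x)^2) / sum((y - mean(y))^2)
}

#' r_m^2 metric family
#'
#' Computes `r_m^2 = r^2 * (1 - sqrt(r^2 - r0^2))` with observed on the first
#' axis and predicted on the second, the reversed variant with the axes
#' interchanged, and the summary forms: their mean and absolute difference.
#' The difference `r^2 - r0^2` is clamped at zero before the square root so
#' the radical stays real in the rare case `r0^2 > r^2`. Activities enter
#' unscaled (no 0-1 normalization).
#'
#' @param observed Observed pIC50 vector.
#' @param predicted Predicted pIC50 vector.
#' @return An object of class `rm2_result`: list with `r2`, `r0_sq`,
#'   `r0_sq_rev`, `rm2`, `rm2_rev`, `rm2_mean`, `delta_rm2`.
#' @export
rm2_metrics <- function(observed, predicted) {
  r2 <- pearson_r2(observed, predicted)
  r0 <- r0_squared(observed, predicted)
  r0_rev <- r0_squared(predicted, observed)
  rm2 <- r2 * (1 - sqrt(max(0, r2 - r0)))
  rm2_rev <- r2 * (1 - sqrt(max(0, r2 - r0_rev)))
  structure(
    list(r2 = r2, r0_sq = r0, r0_sq_rev = r0_rev,
         rm2 = rm2, rm2_rev = rm2_rev,
         rm2_mean = (rm2 + rm2_rev) / 2,
         delta_rm2 = abs(rm2 - rm2_rev)),
    class = "rm2_result"
  )
}

#' @export
print.rm2_result <- function(x, ...) {
  cat(sprintf("rm2 = %.3f  rm2' = %.3f  mean = %.3f  delta = %.3f\n",
              x$rm2, x$rm2_rev, x$rm2_mean, x$delta_rm2))
  invisible(x)
}

#' External predictive R^2
#'
#' `R2_pred = 1 - sum((obs - pred)^2) / sum((obs - mean(obs_train))^2)` over
#' the test set, with the training-set observed mean as the baseline. At most
#' 1; negative when predictions are worse than predicting the training mean.
#'
#' @param observed Test-set observed pIC50.
#' @param predicted Test-set predicted pIC50.
#' @param train_observed_mean Mean observed activity of the training set.
#' @return The predictive R^2.
#' @export
r2_pred <- function(observed, predicted, train_observed_mean) {
  check_pairs(observed, predicted)
  denom <- sum((observed - train_observed_mean)^2)
  if (denom <= 0) stop("degenerate baseline: test observations equal the training mean")
  1 - sum((observed - predicted)^2) / denom
}

#' Leave-one-out PRESS and Q^2 for a fixed term set
#'
#' Each compound is deleted in turn, the model (given basis terms plus
#' intercept) is refitted on the remainder, and the deleted compound is
#' predicted. `PRESS` is the sum of squared deletion residuals and
#' `Q2 = 1 - PRESS / TSS` with TSS about the full-set activity mean.
#'
#' @param table A [descriptor_table()] of the training set.
#' @param terms List of [basis_term()] objects (the fixed model spec).
#' @return List with `press`, `q2`, and `loo_predictions`.
#' @export
loo_press_q2 <- function(table, terms) {
  stopifnot(inherits(table, "descriptor_table"))
  n <- nrow(table$values)
  if (n <= length(terms) + 2L)
    stop("too few compounds for leave-one-out with this many terms")
  X <- cbind(1, term_matrix(table, terms))
  y <- table$activity
  loo_pred <- numeric(n)
  for (i in seq_len(n)) {
    Xi <- X[-i, , drop = FALSE]
    if (qr(Xi)$rank < ncol(Xi))
      stop(sprintf("singular refit when leaving out compound %s",
                   table$compound_ids[i]))
    beta <- lm.fit(Xi, y[-i])$coefficients
    loo_pred[i] <- drop(X[i, ] %*% beta)
  }
  press <- sum((y - loo_pred)^2)
  tss <- sum((y - mean(y))^2)
  list(press = press, q2 = 1 - press / tss, loo_predictions = loo_pred)
}

#' Regression quality statistics
#'
#' Standard error of estimate, variance ratio, and adjusted R^2 for a model
#' with `p` non-intercept terms fitted to `n` training compounds:
#' `s = sqrt(RSS / (n - p - 1))`,
#' `F = (R^2 / p) / ((1 - R^2) / (n - p - 1))`,
#' `Ra^2 = 1 - (1 - R^2) (n - 1) / (n - p - 1)`,
#' with `R^2 = 1 - RSS/TSS`. A perfect fit reports `s = 0`, `Ra2 = 1` and
#' `F = Inf`.
#'
#' @param observed Training-set observed pIC50.
#' @param fitted Training-set fitted (calculated) pIC50.
#' @param p Number of non-intercept model terms (a spline term counts once).
#' @return List with `n`, `p`, `R2`, `Ra2`, `s`, `F`, `rss`, `tss`.
#' @export
regression_stats <- function(observed, fitted, p) {
  check_pairs(observed, fitted)
  n <- length(observed)
  if (n <= p + 1L) stop("degrees of freedom exhausted: n <= p + 1")
  rss <- sum((observed - fitted)^2)
  tss <- sum((observed - mean(observed))^2)
  R2 <- 1 - rss / tss
  df <- n - p - 1L
  s <- sqrt(rss / df)
  Fv <- if (R2 >= 1) Inf else (R2 / p) / ((1 - R2) / df)
  list(n = n, p = p, R2 = R2,
       Ra2 = 1 - (1 - R2) * (n - 1) / df,
       s = s, F = Fv, rss = rss, tss = tss)
}

#' Y-randomization (activity scrambling) test
#'
#' Permutes the activity vector while leaving descriptors unchanged and
#' refits, recording the squared correlation `Rr^2` of each scrambled model.
#' In `"model"` mode only the fixed term set is refitted per permutation; in
#' `"process"` mode the full variable selection ([gfa_search()]) is re-run on
#' each scrambled activity vector. The identity permutation is excluded.
#'
#' @param table A [descriptor_table()].
#' @param terms Fixed term list (model mode) or `NULL` (process mode).
#' @param mode `"model"` or `"process"`.
#' @param n_permutations Number of scrambled refits (9 gives 90% confidence,
#'   99 gives 99% under the (1 - alpha) = m/(m+1) permutation convention).
#' @param seed Integer seed; permutations are reproducible.
#' @param config A [gfa_config()] for process mode.
#' @return An object of class `randomization_result`: list with `mode`,
#'   `n_permutations`, `Rr2_values`, `Rr2_mean`, `R2` (unscrambled), `cRp2`,
#'   and `warning` if the permutation count is below the conventional
#'   requirement for the implied confidence level.
#' @export
y_randomize <- function(table, terms = NULL,
                        mode = c("model", "process"),
                        n_permutations = 99, seed = 1,
                        config = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(table, "descriptor_table"), n_permutations >= 1)
  n <- length(table$activity)
  set.seed(as.integer(seed))
  if (mode == "model") {
    if (is.null(terms)) stop("model mode needs a fixed term set")
    base_fit <- fit_ols(table, terms)
    R2 <- base_fit$r2
  } else {
    if (is.null(config)) config <- gfa_config(seed = seed)
    top <- gfa_search(table, config)[[1L]]
    R2 <- top$r2
    terms_used <- top$terms
  }
  Rr2 <- numeric(n_permutations)
  for (b in seq_len(n_permutations)) {
    repeat {
      perm <- sample.int(n)
      if (!all(perm == seq_len(n))) break
    }
    tbl_b <- table
    tbl_b$activity <- table$activity[perm]
    if (mode == "model") {
      Rr2[b] <- fit_ols(tbl_b, terms)$r2
    } else {
      cfg_b <- config
      cfg_b$seed <- config$seed + b
      Rr2[b] <- gfa_search(tbl_b, cfg_b)[[1L]]$r2
    }
  }
  warn <- if (n_permutations < 9)
    "fewer than 9 permutations: below the 90% confidence convention" else NULL
  structure(
    list(mode = mode, n_permutations = n_permutations,
         Rr2_values = Rr2, Rr2_mean = mean(Rr2),
         R2 = R2, cRp2 = crp2(R2, mean(Rr2)), warning = warn),
    class = "randomization_result"
  )
}

#' @export
print.randomization_result <- function(x, ...) {
  cat(sprintf("%s randomization: %d permutations, Rr2 mean = %.3f, R2 = %.3f, cRp2 = %.3f\n",
              x$mode, x$n_permutations, x$Rr2_mean, x$R2, x$cRp2))
  invisible(x)
}

#' Chance-correlation parameter cR_p^2
#'
#' `cRp2 = R * sqrt(R^2 - mean(Rr^2))` with `R = +sqrt(R^2)`; values above
#' 0.5 indicate the model's correlation is not attributable to chance. When
#' the scrambled mean exceeds the model's R^2 the parameter is reported as 0
#' with an attribute `below_null = TRUE`.
#'
#' @param R2 The model's squared correlation coefficient, in \[0, 1\].
#' @param Rr2_mean Mean squared correlation of the Y-scrambled models.
#' @return The cR_p^2 value.
#' @export
crp2 <- function(R2, Rr2_mean) {
  stopifnot(R2 >= 0, R2 <= 1)
  if (R2 < Rr2_mean) return(structure(0, below_null = TRUE))
  sqrt(R2) * sqrt(R2 - Rr2_mean)
}

#' Assemble the full validation panel for a fitted model
#'
#' Runs the complete internal/external validation battery for a fixed-term
#' linear model on a training table and an external test table: fit quality
#' (R^2, Ra^2, s, F), leave-one-out PRESS/Q^2 and r_m^2(LOO), external
#' R^2_pred and r_m^2(test), r_m^2(overall) over the concatenation of LOO
#' training predictions and test predictions, and model-mode Y-randomization
#' cR_p^2.
#'
#' The overall r_m^2 block uses LOO predictions for the training compounds;
#' it is therefore a function of the refitting procedure, not only of a
#' printed activity table.
#'
#' @param train Training [descriptor_table()].
#' @param test Test [descriptor_table()] (may be `NULL`).
#' @param terms List of [basis_term()] objects.
#' @param n_permutations Permutations for the randomization block.
#' @param seed Seed for the randomization block.
#' @return An object of class `metric_report` (named list, JSON-serializable
#'   with [write_metric_report()]).
#' @export
metric_report <- function(train, test, terms, n_permutations = 99, seed = 1) {
  fit <- fit_ols(train, terms)
  stats_tr <- regression_stats(train$activity, fit$fitted, p = length(terms))
  loo <- loo_press_q2(train, terms)
  rm_loo <- rm2_metrics(train$activity, loo$loo_predictions)
  rand <- y_randomize(train, terms, mode = "model",
                      n_permutations = n_permutations, seed = seed)
  rep <- list(
    n_training = stats_tr$n, n_test = if (is.null(test)) 0L else nrow(test$values),
    R2 = stats_tr$R2, Ra2 = stats_tr$Ra2, s = stats_tr$s, F = stats_tr$F,
    PRESS = loo$press, Q2 = loo$q2,
    rm2_loo_mean = rm_loo$rm2_mean, delta_rm2_loo = rm_loo$delta_rm2,
    R2_pred = NA_real_, rm2_test_mean = NA_real_, delta_rm2_test = NA_real_,
    rm2_overall_mean = NA_real_, delta_rm2_overall = NA_real_,
    cRp2_model = as.numeric(rand$cRp2)
  )
  if (!is.null(test)) {
    pred_test <- predict(fit, test)
    rep$R2_pred <- r2_pred(test$activity, pred_test, mean(train$activity))
    rm_test <- rm2_metrics(test$activity, pred_test)
    rep$rm2_test_mean <- rm_test$rm2_mean
    rep$delta_rm2_test <- rm_test$delta_rm2
    rm_all <- rm2_metrics(c(train$activity, test$activity),
                          c(loo$loo_predictions, pred_test))
    rep$rm2_overall_mean <- rm_all$rm2_mean
    rep$delta_rm2_overall <- rm_all$delta_rm2
  }
  structure(rep, class = c("metric_report", "list"))
}

#' @export
print.metric_report <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "-" else sprintf("%.3f", v)
  cat(sprintf("n(train) = %d, n(test) = %d\n", x$n_training, x$n_test))
  cat(sprintf("R2 = %s  Ra2 = %s  s = %s  F = %s\n",
              fmt(x$R2), fmt(x$Ra2), fmt(x$s),
              if (is.infinite(x$F)) "Inf" else fmt(x$F)))
  cat(sprintf("PRESS = %s  Q2 = %s  rm2(LOO) = %s  delta = %s\n",
              fmt(x$PRESS), fmt(x$Q2), fmt(x$rm2_loo_mean), fmt(x$delta_rm2_loo)))
  cat(sprintf("R2pred = %s  rm2(test) = %s  delta = %s  cRp2(model) = %s\n",
              fmt(x$R2_pred), fmt(x$rm2_test_mean), fmt(x$delta_rm2_test),
              fmt(x$cRp2_model)))
  invisible(x)
}
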