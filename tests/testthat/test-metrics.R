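fixture_pairs <- function(set) {
  act <- coumarin_activity()
  act[act$set == set, ]
}

test_that("pearson_r2 matches closed-form correlation and is symmetric", {
  expect_equal(pearson_r2(1:5, 1:5), 1.0)
  # 4-point set, closed form computed long-hand
  x <- c(0, 1, 2, 3); y <- c(0, 1, 2, 0)
  num <- sum((x - mean(x)) * (y - mean(y)))
  expected <- num^2 / (sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearson_r2(x, y), expected, tolerance = 1e-12)
  expect_equal(pearson_r2(y, x), pearson_r2(x, y))
  expect_error(pearson_r2(c(1, 1, 1), c(1, 2, 3)), "zero variance")
})

test_that("r0_squared agrees with a slope-grid oracle and penalizes offsets", {
  x <- c(1, 2, 3); y <- c(2, 3, 5)
  expect_equal(r0_squared(x, y), oracle_r0_squared(x, y), tolerance = 1e-6)
  expect_equal(r0_squared(1:4, 1:4), 1.0)
  # large offset: the through-origin fit must be worse than r^2
  x2 <- c(1, 2, 3, 4); y2 <- x2 + 10
  expect_lt(r0_squared(x2, y2), pearson_r2(x2, y2))
  expect_error(r0_squared(c(0, 0, 0), 1:3), "all-zero")
})

test_that("rm2 metrics match the spreadsheet oracle on a fixed 5-point set", {
  obs <- c(1.2, 2.5, 3.1, 4.0, 4.9)
  pred <- c(1.5, 2.2, 3.4, 3.6, 5.1)
  got <- rm2_metrics(obs, pred)
  want <- oracle_rm2(obs, pred)
  expect_equal(got$rm2, want$rm2, tolerance = 1e-12)
  expect_equal(got$rm2_rev, want$rm2_rev, tolerance = 1e-12)
  expect_equal(got$rm2_mean, want$mean, tolerance = 1e-12)
  expect_equal(got$delta_rm2, want$delta, tolerance = 1e-12)
})

test_that("rm2 on identical predictions is exact and the family obeys its invariants", {
  got <- rm2_metrics(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(got$rm2_mean, 1.0)
  expect_equal(got$delta_rm2, 0.0)

  set.seed(11)
  for (i in 1:20) {
    obs <- rnorm(12); pred <- obs + rnorm(12, sd = 0.5)
    fwd <- rm2_metrics(obs, pred)
    rev <- rm2_metrics(pred, obs)
    # rm2 itself is orientation-dependent, its mean/delta are not
    expect_equal(fwd$rm2_mean, rev$rm2_mean, tolerance = 1e-12)
    expect_equal(fwd$delta_rm2, rev$delta_rm2, tolerance = 1e-12)
    expect_equal(fwd$rm2, rev$rm2_rev, tolerance = 1e-12)
    # the correction factor is <= 1
    expect_lte(fwd$rm2, fwd$r2 + 1e-12)
    expect_gte(fwd$delta_rm2, 0)
  }
})

test_that("rm2 on the fixture test set reproduces the published values", {
  te <- fixture_pairs("test")
  got <- rm2_metrics(te$observed, te$predicted)
  expect_equal(got$rm2_mean, 0.725, tolerance = 0.005)
  expect_equal(got$delta_rm2, 0.128, tolerance = 0.005)
})

test_that("r2_pred hits its exact anchor cases and the published value", {
  tr <- fixture_pairs("train"); te <- fixture_pairs("test")
  expect_equal(r2_pred(te$observed, te$predicted, mean(tr$observed)),
               0.908, tolerance = 0.002)
  obs <- c(1, 2, 3, 4)
  expect_equal(r2_pred(obs, obs, 10), 1.0)
  # predicting the training mean for every compound scores exactly 0
  expect_equal(r2_pred(obs, rep(2.2, 4), 2.2), 0.0)
  expect_error(r2_pred(rep(2, 3), c(1, 2, 3), 2), "degenerate")
})

test_that("loo_press_q2 equals an explicit per-fold lm refit oracle", {
  set.seed(3)
  n <- 6
  X <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("D1", "D2")))
  y <- 0.5 + X[, 1] - 0.7 * X[, 2] + rnorm(n, sd = 0.3)
  tbl <- descriptor_table(X, y)
  got <- loo_press_q2(tbl, list(basis_term("D1"), basis_term("D2")))
  df <- data.frame(y = y, D1 = X[, 1], D2 = X[, 2])
  expect_equal(got$press, oracle_loo_press(df, y ~ D1 + D2), tolerance = 1e-10)
  expect_equal(got$q2, 1 - got$press / sum((y - mean(y))^2), tolerance = 1e-12)
})

test_that("noise-free data fitted by its own model spec gives Q2 of 1", {
  set.seed(5)
  X <- matrix(rnorm(60), 30, 2, dimnames = list(NULL, c("D1", "D2")))
  y <- 2 + 3 * X[, 1] - X[, 2]
  tbl <- descriptor_table(X, y)
  got <- loo_press_q2(tbl, list(basis_term("D1"), basis_term("D2")))
  expect_equal(got$q2, 1.0, tolerance = 1e-10)
})

test_that("Q2 from the PRESS identity with published PRESS matches the printed value", {
  tr <- fixture_pairs("train")
  tss <- sum((tr$observed - mean(tr$observed))^2)
  expect_equal(1 - 7.122 / tss, 0.841, tolerance = 0.002)
})

test_that("regression_stats reproduces the published panel and a hand example", {
  tr <- fixture_pairs("train")
  got <- regression_stats(tr$observed, tr$predicted, p = 5L)
  expect_equal(got$s, 0.352, tolerance = 0.002)
  expect_equal(got$F, 66.98, tolerance = 0.5)
  expect_equal(got$Ra2, 0.914, tolerance = 0.002)
  expect_equal(got$R2, 0.928, tolerance = 0.002)

  # 5-point hand example: long-hand RSS/TSS arithmetic
  obs <- c(1, 2, 3, 4, 5); fit <- c(1.1, 1.9, 3.2, 3.8, 5.0)
  rss <- sum((obs - fit)^2); tss <- sum((obs - 3)^2)
  hand <- regression_stats(obs, fit, p = 1L)
  expect_equal(hand$s, sqrt(rss / 3), tolerance = 1e-12)
  expect_equal(hand$R2, 1 - rss / tss, tolerance = 1e-12)
  expect_equal(hand$F, ((1 - rss / tss) / 1) / ((rss / tss) / 3), tolerance = 1e-10)

  perfect <- regression_stats(obs, obs, p = 1L)
  expect_equal(perfect$s, 0)
  expect_equal(perfect$Ra2, 1)
  expect_true(is.infinite(perfect$F))
  expect_error(regression_stats(obs[1:2], fit[1:2], p = 1L), "degrees of freedom")
})

test_that("crp2 follows the corrected-randomization formula", {
  expect_equal(crp2(0.81, 0), 0.81, tolerance = 1e-12)   # R * sqrt(R2) = R2
  expect_equal(as.numeric(crp2(0.7, 0.7)), 0)
  expect_equal(crp2(0.928, 0.10), sqrt(0.928) * sqrt(0.828), tolerance = 1e-12)
  expect_equal(crp2(0.928, 0.10), 0.8766, tolerance = 5e-4)
  # monotone decreasing in the scrambled mean
  vals <- vapply(seq(0, 0.9, by = 0.1), function(m) as.numeric(crp2(0.9, m)),
                 numeric(1))
  expect_true(all(diff(vals) <= 0))
  expect_true(attr(crp2(0.3, 0.5), "below_null"))
})

test_that("y_randomize is seeded, excludes the identity, and covers both modes", {
  tbl <- toy_table(n = 25, d = 4, seed = 9, noise = 0.2)
  terms <- list(basis_term("D1"), basis_term("D2"))
  a <- y_randomize(tbl, terms, mode = "model", n_permutations = 20, seed = 7)
  b <- y_randomize(tbl, terms, mode = "model", n_permutations = 20, seed = 7)
  expect_identical(a$Rr2_values, b$Rr2_values)
  expect_length(a$Rr2_values, 20L)
  expect_true(all(a$Rr2_values >= 0 & a$Rr2_values <= 1))
  # a real signal should dominate its scrambled refits
  expect_gt(a$R2, a$Rr2_mean)
  expect_gt(as.numeric(a$cRp2), 0.5)

  # process mode re-runs the search per permutation
  cfg <- gfa_config(population_size = 8, generations = 3, max_terms = 2,
                    spline_enabled = FALSE, seed = 7)
  p <- y_randomize(tbl, mode = "process", n_permutations = 3, seed = 7,
                   config = cfg)
  expect_length(p$Rr2_values, 3L)
  expect_true(all(is.finite(p$Rr2_values)))
  expect_false(is.null(y_randomize(tbl, terms, n_permutations = 5,
                                   seed = 1)$warning))
})

test_that("metric_report assembles a coherent panel (Q2 <= R2, PRESS >= RSS)", {
  tbl <- toy_table(n = 30, d = 4, seed = 21, noise = 0.3)
  split <- cluster_split(tbl, n_test = 8, seed = 2)
  parts <- apply_split(tbl, split)
  terms <- list(basis_term("D1"), basis_term("D2"))
  rep <- metric_report(parts$train, parts$test, terms,
                       n_permutations = 9, seed = 3)
  fit <- fit_ols(parts$train, terms)
  expect_lte(rep$Q2, rep$R2)
  expect_gte(rep$PRESS, fit$rss)
  expect_true(all(is.finite(c(rep$R2_pred, rep$rm2_test_mean,
                              rep$rm2_overall_mean, rep$cRp2_model))))
})
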