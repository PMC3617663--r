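small_cfg <- function(...) {
  gfa_config(population_size = 30, generations = 20, ...)
}

test_that("a noise-free single-descriptor relation is found immediately", {
  set.seed(1)
  X <- matrix(rnorm(15), 15, 1, dimnames = list(NULL, "D1"))
  tbl <- descriptor_table(X, 2 + 0.7 * X[, 1])
  ranked <- gfa_search(tbl, small_cfg(max_terms = 1, spline_enabled = FALSE,
                                      seed = 3))
  top <- ranked[[1]]
  expect_equal(vapply(top$terms, format, character(1)), "D1")
  expect_lt(top$lof, 1e-20)
})

test_that("identical seeds give identical ranked output", {
  tbl <- toy_table(n = 25, d = 5, seed = 14, noise = 0.2)
  cfg <- small_cfg(max_terms = 3, seed = 11)
  a <- gfa_search(tbl, cfg)
  b <- gfa_search(tbl, cfg)
  key <- function(models) vapply(models, function(m)
    paste(sort(vapply(m$terms, format, character(1))), collapse = "|"),
    character(1))
  expect_identical(key(a), key(b))
  expect_identical(vapply(a, `[[`, numeric(1), "lof"),
                   vapply(b, `[[`, numeric(1), "lof"))
})

test_that("the best lack-of-fit never worsens across generations (elitism)", {
  tbl <- toy_table(n = 25, d = 6, seed = 15, noise = 0.3)
  ranked <- gfa_search(tbl, small_cfg(max_terms = 3, seed = 5))
  trace <- attr(ranked, "best_lof_trace")
  expect_true(all(diff(trace) <= 1e-12))
})

test_that("spline-enabled search locates a planted knot within one grid step", {
  spec <- synthetic_spec(
    n_compounds = 45, n_descriptors = 4,
    true_model = linear_model(1, list(
      basis_term("D1", form = "spline", knot = 0.5,
                 orientation = "x_minus_knot")), 2),
    descriptor_correlation = 0, noise_sd = 0.05, seed = 31)
  tbl <- gen_descriptor_dataset(spec)
  ranked <- gfa_search(tbl, gfa_config(population_size = 40, generations = 30,
                                       max_terms = 2, seed = 8))
  top <- ranked[[1]]
  splines_d1 <- Filter(function(t) t$form == "spline" && t$descriptor == "D1",
                       top$terms)
  expect_gte(length(splines_d1), 1L)
  grid <- sort(unique(tbl$values[, "D1"]))
  grid <- grid[-c(1, length(grid))]
  idx_best <- which.min(abs(grid - 0.5))
  idx_got <- which.min(abs(grid - splines_d1[[1]]$knot))
  expect_lte(abs(idx_got - idx_best), 1L)
})

test_that("gpls at full rank reduces to the GFA ranking on the same seed", {
  tbl <- toy_table(n = 20, d = 4, seed = 16, noise = 0.2)
  cfg <- small_cfg(max_terms = 2, spline_enabled = FALSE, seed = 9)
  a <- gfa_search(tbl, cfg)
  b <- gpls_search(tbl, cfg, max_components = 5, component_selection = "max")
  key <- function(models) vapply(models, function(m)
    paste(sort(vapply(m$terms, format, character(1))), collapse = "|"),
    character(1))
  expect_identical(key(a), key(b))
  expect_equal(vapply(a, `[[`, numeric(1), "lof"),
               vapply(b, `[[`, numeric(1), "lof"), tolerance = 1e-8)
})

test_that("gfa recovers a planted two-term linear truth across seeded runs", {
  # the Friedman penalty at d = 1 tolerates an occasional third term that
  # absorbs noise, so the true pair must always be present and is expected
  # to be the exact top set in the strong majority of runs
  contain <- 0L; exact <- 0L
  for (s in 1:20) {
    spec <- synthetic_spec(
      n_compounds = 45, n_descriptors = 8,
      true_model = linear_model(1, list(basis_term("D1"), basis_term("D2")),
                                c(2, -1.5)),
      descriptor_correlation = 0, noise_sd = 0.05, seed = 1000 + s)
    tbl <- gen_descriptor_dataset(spec)
    ranked <- gfa_search(tbl, gfa_config(population_size = 30, generations = 20,
                                         max_terms = 3, spline_enabled = FALSE,
                                         seed = s))
    got <- vapply(ranked[[1]]$terms, `[[`, character(1), "descriptor")
    if (all(c("D1", "D2") %in% got)) contain <- contain + 1L
    if (setequal(got, c("D1", "D2"))) exact <- exact + 1L
  }
  expect_gte(contain, 19L)
  expect_gte(exact, 14L)
})

test_that("gpls recovers a planted three-term truth in most seeded runs", {
  hits <- 0L
  for (s in 1:10) {
    spec <- synthetic_spec(
      n_compounds = 30, n_descriptors = 6,
      true_model = linear_model(0, list(basis_term("D1"), basis_term("D2"),
                                        basis_term("D3")),
                                c(1.5, -1.2, 0.8)),
      descriptor_correlation = 0, noise_sd = 0.05, seed = 100 + s)
    tbl <- gen_descriptor_dataset(spec)
    ranked <- gpls_search(tbl, gfa_config(population_size = 24, generations = 15,
                                          max_terms = 4, spline_enabled = FALSE,
                                          seed = s),
                          max_components = 4, component_selection = "max")
    got <- vapply(ranked[[1]]$terms, `[[`, character(1), "descriptor")
    if (all(c("D1", "D2", "D3") %in% got)) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("search rejects invalid inputs", {
  tbl <- toy_table(n = 8, d = 2, seed = 17)
  expect_error(gfa_search(tbl, small_cfg()), "at least 10")
  tbl2 <- toy_table(n = 20, d = 2, seed = 18)
  empty <- tbl2
  empty$descriptor_names <- character(0)
  expect_error(gx_search <- gfa_search(empty, small_cfg()), "empty|subscript")
})
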