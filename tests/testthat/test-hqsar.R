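# printed grid statistics used as replay inputs for the selection rule
flags_stage_stats <- data.frame(
  flags = c("A/C", "A/D&A", "A/B/C", "A/B/H", "A/B/C/H", "A/B/C/D&A"),
  q2 = c(0.437, 0.513, 0.430, 0.461, 0.411, 0.454),
  se_cv = c(0.916, 0.914, 0.921, 0.944, 0.952, 0.902),
  length = c(151, 97, 401, 199, 97, 401),
  stringsAsFactors = FALSE
)
size_stage_stats <- data.frame(
  size = c("4-8", "4-9", "5-8", "5-9", "6-8", "6-9", "7-8", "7-9"),
  q2 = c(0.489, 0.538, 0.490, 0.529, 0.484, 0.537, 0.496, 0.507),
  se_cv = c(0.937, 0.891, 0.936, 0.900, 0.941, 0.892, 0.931, 0.903),
  length = c(199, 83, 199, 83, 307, 83, 307, 83),
  stringsAsFactors = FALSE
)

test_that("the selection rule replays the reported grid stages", {
  expect_equal(flags_stage_stats$flags[hqsar_select(flags_stage_stats)], "A/D&A")
  expect_equal(flags_stage_stats$q2[hqsar_select(flags_stage_stats)], 0.513)
  best_size <- size_stage_stats[hqsar_select(size_stage_stats), ]
  expect_equal(best_size$size, "4-9")
  expect_equal(best_size$q2, 0.538)
  expect_equal(best_size$length, 83)
})

test_that("the 5% rule reproduces the reported component selection", {
  got <- five_percent_rule(c(`2` = 0.397, `4` = 0.525, `5` = 0.538))
  expect_equal(unname(got$percent_increase), c(32.242, 2.476), tolerance = 5e-4)
  expect_equal(got$chosen, 4L)
  flat <- five_percent_rule(c(`1` = 0.5, `2` = 0.5))
  expect_equal(flat$chosen, 1L)
  expect_equal(unname(flat$percent_increase), 0)
  rising <- five_percent_rule(c(`1` = 0.3, `2` = 0.4, `3` = 0.5))
  expect_equal(rising$chosen, 3L)
  undef <- five_percent_rule(c(`1` = -0.1, `2` = 0.2))
  expect_true(is.na(undef$percent_increase[[1]]))
})

test_that("a planted single-bin signal is recovered with Q2 > 0.9 at 1 component", {
  g <- gen_coumarin_smiles(14, seed = 37)
  mols <- attr(g, "molecules")
  fl <- distinction_flags(A = TRUE)
  X <- hologram_matrix(mols, 53, fl, 4, 6)
  varying <- which(apply(X, 2, var) > 0)
  b <- varying[which.max(apply(X[, varying, drop = FALSE], 2, var))]
  y <- 1 + 0.8 * X[, b]
  m <- hqsar_fit(mols, y, fl, c(4L, 6L), 53L, max_components = 2L)
  expect_gt(m$q2_by_components[["1"]], 0.9)
})

test_that("hqsar fits respect Q2 <= R2 and the n/5 component cap", {
  g <- gen_coumarin_smiles(16, seed = 41)
  mols <- attr(g, "molecules")
  m <- hqsar_fit(mols, g$activity, distinction_flags(A = TRUE, DA = TRUE),
                 c(4L, 7L), 83L, max_components = 6L)
  expect_lte(m$q2, m$r2 + 1e-10)
  expect_lte(m$n_components, 16 %/% 5)
  expect_equal(m$se_cv, sqrt((1 - m$q2) * sum((g$activity - mean(g$activity))^2) /
                               (16 - m$n_components - 1)), tolerance = 1e-10)
})

test_that("the staged grid search returns a coherent selection", {
  g <- gen_coumarin_smiles(16, seed = 43)
  mols <- attr(g, "molecules")
  grid <- hqsar_grid_train(
    mols, g$activity,
    flag_sets = list("A" = distinction_flags(A = TRUE),
                     "A/D&A" = distinction_flags(A = TRUE, DA = TRUE)),
    sizes = list(c(4L, 6L), c(4L, 7L)),
    lengths = c(53L, 61L),
    default_size = c(4L, 6L),
    max_components = 3L)
  expect_true(grid$flags %in% c("A", "A/D&A"))
  expect_true(grid$length %in% c(53L, 61L))
  expect_equal(nrow(grid$flags_grid), 2L)
  expect_equal(nrow(grid$size_grid), 2L)
  expect_equal(nrow(grid$length_grid), 2L)
  # the final model carries the selected configuration
  expect_equal(grid$model$hologram_length, grid$length)
  expect_equal(grid$model$fragment_size, grid$size)
  # selection is reproducible: the chosen row is the grid optimum
  i <- hqsar_select(grid$length_grid)
  expect_equal(grid$length_grid$length[i], grid$length)
})

test_that("contribution maps conserve the prediction and localize a planted signal", {
  g <- gen_coumarin_smiles(14, seed = 47)
  mols <- attr(g, "molecules")
  m <- hqsar_fit(mols, g$activity, distinction_flags(A = TRUE, DA = TRUE),
                 c(4L, 6L), 83L, max_components = 2L)
  for (mol in mols[1:5]) {
    cm <- contribution_map(m, mol)
    pred <- predict(m, list(mol))
    expect_equal(attr(cm, "intercept") + sum(cm$contribution), pred,
                 tolerance = 1e-8)
    expect_true(all(cm$color %in% c("red", "red-orange", "white",
                                    "yellow", "green")))
  }
})

test_that("hydroxyl substituent atoms outrank methyl atoms in planted-SAR recovery", {
  g <- gen_coumarin_smiles(40, seed = 51, noise_sd = 0.15)
  mols <- attr(g, "molecules")
  m <- hqsar_fit(mols, g$activity, distinction_flags(A = TRUE, DA = TRUE),
                 c(4L, 6L), 83L, max_components = 4L)
  oh_contrib <- c(); me_contrib <- c()
  for (i in seq_along(mols)) {
    mol <- mols[[i]]
    cm <- contribution_map(m, mol)
    # hydroxyl oxygens vs methyl carbons on the scaffold
    oh <- which(mol$atoms$element == "O" & mol$atoms$h_count == 1)
    # ring methyls only: CH3 not bonded to an oxygen (excludes methoxy)
    me <- which(vapply(seq_len(nrow(mol$atoms)), function(a) {
      if (mol$atoms$element[a] != "C" || mol$atoms$h_count[a] != 3 ||
          mol$atoms$aromatic[a]) return(FALSE)
      nb <- c(mol$bonds$a2[mol$bonds$a1 == a], mol$bonds$a1[mol$bonds$a2 == a])
      !any(mol$atoms$element[nb] == "O")
    }, logical(1)))
    oh_contrib <- c(oh_contrib, cm$contribution[oh])
    me_contrib <- c(me_contrib, cm$contribution[me])
  }
  expect_gte(length(oh_contrib), 3L)
  expect_gte(length(me_contrib), 3L)
  expect_gt(mean(oh_contrib), mean(me_contrib))
})
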