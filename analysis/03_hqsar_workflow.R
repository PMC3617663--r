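#!/usr/bin/env Rscript
# Hologram QSAR workflow on synthetic coumarins.
#
# The compound structures of the original dataset exist only as images, so
# the HQSAR track runs on generated substituted-coumarin SMILES with a
# planted additive structure-activity pattern (oxygen-bearing substituents
# favour activity). Staged grid selection follows the original procedure:
# fragment distinction first, then fragment size, then hologram length; the
# latent-variable count is re-examined with the 5% rule, and the best
# model's fragment contributions are mapped onto the most active molecule.

library(coumarinQSAR)

dir.create("results", showWarnings = FALSE)
seed <- 2026

g <- gen_coumarin_smiles(32, seed = seed, noise_sd = 0.2)
mols <- attr(g, "molecules")
cat(sprintf("Generated %d unique substituted coumarins, activity %.2f-%.2f pIC50\n",
            nrow(g), min(g$activity), max(g$activity)))

grid <- hqsar_grid_train(
  mols, g$activity,
  flag_sets = list(
    "A"     = distinction_flags(A = TRUE),
    "A/C"   = distinction_flags(A = TRUE, C = TRUE),
    "A/D&A" = distinction_flags(A = TRUE, DA = TRUE),
    "A/B/H" = distinction_flags(A = TRUE, B = TRUE, H = TRUE)),
  sizes = list(c(4L, 7L), c(4L, 9L), c(5L, 8L)),
  lengths = c(53L, 83L, 199L),
  max_components = 6L)

cat("\nStage 1 (fragment distinction):\n"); print(grid$flags_grid, digits = 3)
cat("\nStage 2 (fragment size):\n"); print(grid$size_grid, digits = 3)
cat("\nStage 3 (hologram length):\n"); print(grid$length_grid, digits = 3)
cat(sprintf("\nSelected: %s, size %d-%d, length %d\n",
            grid$flags, grid$size[1], grid$size[2], grid$length))
print(grid$model)

fp <- five_percent_rule(grid$model$q2_by_components)
cat("5% rule on the Q2-by-components profile: chosen LV =", fp$chosen, "\n")
print(round(fp$percent_increase, 2))

best_mol <- mols[[which.max(g$activity)]]
cmap <- contribution_map(grid$model, best_mol)
cat(sprintf("\nContribution map of the most active molecule (%s):\n",
            g$smiles[which.max(g$activity)]))
print(cmap)
cat(sprintf("sum(contributions) + intercept = %.4f (prediction %.4f)\n",
            sum(cmap$contribution) + attr(cmap, "intercept"),
            attr(cmap, "prediction")))

jsonlite::write_json(
  list(selected = list(flags = grid$flags, size = grid$size,
                       length = grid$length,
                       n_components = grid$model$n_components,
                       q2 = grid$model$q2, se_cv = grid$model$se_cv,
                       r2 = grid$model$r2),
       five_percent = list(chosen = fp$chosen,
                           percent_increase = as.list(fp$percent_increase)),
       flags_grid = grid$flags_grid, size_grid = grid$size_grid,
       length_grid = grid$length_grid,
       contribution_map = cmap),
  "results/hqsar_workflow.json", auto_unbox = TRUE, digits = NA, pretty = TRUE)
cat("Written: results/hqsar_workflow.json\n")
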