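# Independent oracle implementations used to cross-check the package's
# metric and fragment code. These deliberately take the slow, literal route
# (grid searches, explicit refit loops, subset enumeration) and share no code
# with the implementations they verify.

# through-origin r0^2 by brute-force minimization of sum((y - k x)^2) over a
# fine slope grid
oracle_r0_squared <- function(x, y, k_grid = seq(-10, 10, by = 1e-4)) {
  sse <- vapply(k_grid, function(k) sum((y - k * x)^2), numeric(1))
  1 - min(sse) / sum((y - mean(y))^2)
}

# spreadsheet-style rm2 computation: every intermediate written out
oracle_rm2 <- function(obs, pred) {
  r <- sum((obs - mean(obs)) * (pred - mean(pred))) /
    sqrt(sum((obs - mean(obs))^2) * sum((pred - mean(pred))^2))
  r2 <- r^2
  k <- sum(obs * pred) / sum(obs^2)
  r02 <- 1 - sum((pred - k * obs)^2) / sum((pred - mean(pred))^2)
  k_rev <- sum(obs * pred) / sum(pred^2)
  r02_rev <- 1 - sum((obs - k_rev * pred)^2) / sum((obs - mean(obs))^2)
  rm2 <- r2 * (1 - sqrt(max(0, r2 - r02)))
  rm2_rev <- r2 * (1 - sqrt(max(0, r2 - r02_rev)))
  list(rm2 = rm2, rm2_rev = rm2_rev, mean = (rm2 + rm2_rev) / 2,
       delta = abs(rm2 - rm2_rev))
}

# literal leave-one-out refit with stats::lm on a data.frame
oracle_loo_press <- function(df, formula) {
  press <- 0
  for (i in seq_len(nrow(df))) {
    fit <- stats::lm(formula, data = df[-i, , drop = FALSE])
    press <- press + (df$y[i] - stats::predict(fit, df[i, , drop = FALSE]))^2
  }
  unname(press)
}

# brute-force connected-induced-subgraph enumeration via subset scan
oracle_fragments <- function(mol, min_atoms, max_atoms) {
  n <- nrow(mol$atoms)
  adj <- lapply(seq_len(n), function(i) {
    b <- mol$bonds
    sort(c(b$a2[b$a1 == i], b$a1[b$a2 == i]))
  })
  connected <- function(S) {
    if (length(S) == 1L) return(TRUE)
    seen <- S[1L]
    repeat {
      grow <- unique(unlist(adj[seen]))
      grow <- intersect(grow, S)
      new_seen <- union(seen, grow)
      if (length(new_seen) == length(seen)) break
      seen <- new_seen
    }
    length(seen) == length(S)
  }
  out <- list()
  for (k in seq(min_atoms, min(max_atoms, n))) {
    for (S in utils::combn(n, k, simplify = FALSE)) {
      if (connected(S)) out[[length(out) + 1L]] <- S
    }
  }
  out
}

# canonical representation of a fragment list for set comparison
frag_set_string <- function(frags) {
  sort(vapply(frags, function(f) paste(sort(f), collapse = ","), character(1)))
}

# small descriptor table with a known linear structure
toy_table <- function(n = 20, d = 4, seed = 42, noise = 0.1) {
  set.seed(seed)
  X <- matrix(rnorm(n * d), n, d, dimnames = list(NULL, paste0("D", 1:d)))
  y <- 1 + 2 * X[, 1] - 1.5 * X[, 2] + rnorm(n, sd = noise)
  descriptor_table(X, y)
}

# a small, varied molecule fixture set (all parse with the package reader)
fixture_smiles <- c(
  ethanol = "CCO", propane = "CCC", benzene = "c1ccccc1",
  isobutane = "CC(C)C", cyclopropane = "C1CC1", glyoxal = "O=CC=O",
  acetic = "CC(=O)O", furan = "c1ccoc1", tbutylamine = "CC(C)(C)N",
  acrylonitrile = "N#CC"
)
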