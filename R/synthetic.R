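#' Specification for a synthetic descriptor dataset
#'
#' Stands in for a computed molecular-descriptor matrix: descriptors are
#' drawn from an equicorrelated Gaussian and the activity is a sparse
#' linear-plus-spline ground truth with additive Gaussian noise. The
#' defaults emulate the modeled study conditions: 45 compounds, a five-term
#' truth (four linear terms and one truncated-power spline), residual noise
#' of 0.35 pIC50 units, and activities centred near 3 pIC50 with a standard
#' deviation of about 1.2 — the dispersion of the modeled activity window,
#' whose central range is roughly 1 to 5.2.
#'
#' @param n_compounds Number of compounds.
#' @param n_descriptors Number of descriptor columns (named `D1`, `D2`, ...).
#' @param true_model A [linear_model()] whose terms reference the generated
#'   descriptor names; `NULL` uses the default five-term truth.
#' @param descriptor_correlation Pairwise descriptor correlation in `[0, 1)`.
#' @param noise_sd Gaussian noise on the activity (pIC50 units, >= 0).
#' @param seed Integer seed.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_compounds = 45L, n_descriptors = 10L,
                           true_model = NULL, descriptor_correlation = 0.3,
                           noise_sd = 0.35, seed = 1L) {
  stopifnot(n_compounds >= 4L, n_descriptors >= 1L,
            descriptor_correlation >= 0, descriptor_correlation < 1,
            noise_sd >= 0)
  if (is.null(true_model)) {
    stopifnot(n_descriptors >= 5L)
    true_model <- linear_model(
      intercept = 3.0,
      terms = list(basis_term("D1"), basis_term("D2"), basis_term("D3"),
                   basis_term("D4"),
                   basis_term("D5", form = "spline", knot = 0.2,
                              orientation = "x_minus_knot")),
      coefficients = c(0.6, 0.45, -0.5, 0.3, 1.2)
    )
  }
  names_ok <- vapply(true_model$terms, `[[`, character(1), "descriptor") %in%
    paste0("D", seq_len(n_descriptors))
  if (!all(names_ok)) stop("true_model references descriptors outside the generated set")
  structure(list(n_compounds = as.integer(n_compounds),
                 n_descriptors = as.integer(n_descriptors),
                 true_model = true_model,
                 descriptor_correlation = descriptor_correlation,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic descriptor dataset
#'
#' @param spec A [synthetic_spec()].
#' @return A [descriptor_table()]; attributes `spec` and `noise_free_activity`
#'   record the generating conditions.
#' @export
gen_descriptor_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  n <- spec$n_compounds; d <- spec$n_descriptors
  rho <- spec$descriptor_correlation
  Z <- matrix(stats::rnorm(n * d), n, d)
  if (rho > 0) {
    sigma <- matrix(rho, d, d); diag(sigma) <- 1
    Z <- Z %*% chol(sigma)
  }
  colnames(Z) <- paste0("D", seq_len(d))
  mu <- predict(spec$true_model, Z)
  y <- mu + stats::rnorm(n, sd = spec$noise_sd)
  tbl <- descriptor_table(Z, y)
  attr(tbl, "spec") <- spec
  attr(tbl, "noise_free_activity") <- mu
  tbl
}

coumarin_substituents <- data.frame(
  smiles = c("", "O", "OC", "C", "[N+](=O)[O-]", "F", "Cl", "Br",
             "OCc3ccccc3"),
  label = c("H", "OH", "OMe", "Me", "NO2", "F", "Cl", "Br", "OBn"),
  effect = c(0, 0.9, 0.55, 0.15, -0.25, 0.0, -0.05, -0.05, 0.45),
  stringsAsFactors = FALSE
)

#' Generate substituted-coumarin SMILES with synthetic activities
#'
#' Enumerates the 2H-chromen-2-one (coumarin) scaffold with substituents
#' (OH, OMe, Me, NO2, F, Cl, Br, benzyloxy) at ring positions 3-8 and
#' assigns activities from additive substituent effects plus Gaussian
#' noise. Oxygen-bearing substituents (hydroxy, methoxy, benzyloxy) carry
#' positive effects, mirroring the structure-activity pattern in which
#' oxygen-bearing fragments favour antioxidant activity; the base scaffold
#' activity (1.6) and effect sizes keep the pIC50 range near 1-5.2.
#'
#' @param n Number of molecules (>= 4).
#' @param seed Integer seed.
#' @param noise_sd Activity noise (pIC50 units).
#' @param max_substituents Maximum decorated positions per molecule.
#' @return A data.frame with `id`, `smiles`, `activity`, and `substituents`;
#'   attribute `molecules` holds the parsed graphs and `effects` the
#'   noise-free activities.
#' @export
gen_coumarin_smiles <- function(n, seed = 1L, noise_sd = 0.3,
                                max_substituents = 3L) {
  stopifnot(n >= 4L)
  set.seed(as.integer(seed))
  positions <- c("R3", "R4", "R5", "R6", "R7", "R8")
  subs <- coumarin_substituents
  seen <- character(0)
  out <- vector("list", n)
  base_activity <- 1.6
  i <- 0L
  guard <- 0L
  while (i < n) {
    guard <- guard + 1L
    if (guard > 50L * n) stop("could not generate enough unique molecules")
    k <- sample.int(max_substituents + 1L, 1L) - 1L   # 0..max substituents
    assignment <- stats::setNames(rep("", length(positions)), positions)
    labels <- character(0)
    effect <- 0
    if (k > 0L) {
      pos <- sample(positions, k)
      for (p in pos) {
        j <- sample.int(nrow(subs) - 1L, 1L) + 1L     # never "H"
        assignment[[p]] <- subs$smiles[j]
        labels <- c(labels, paste0(p, "-", subs$label[j]))
        effect <- effect + subs$effect[j]
      }
    }
    smi <- coumarin_smiles(assignment)
    if (smi %in% seen) next
    seen <- c(seen, smi)
    i <- i + 1L
    out[[i]] <- list(smiles = smi,
                     substituents = if (length(labels))
                       paste(sort(labels), collapse = ",") else "none",
                     effect = base_activity + effect)
  }
  effects <- vapply(out, `[[`, numeric(1), "effect")
  activity <- effects + stats::rnorm(n, sd = noise_sd)
  df <- data.frame(id = sprintf("syn%02d", seq_len(n)),
                   smiles = vapply(out, `[[`, character(1), "smiles"),
                   activity = activity,
                   substituents = vapply(out, `[[`, character(1), "substituents"),
                   stringsAsFactors = FALSE)
  attr(df, "molecules") <- lapply(df$smiles, parse_smiles)
  attr(df, "effects") <- effects
  df
}

# assemble a substituted 2H-chromen-2-one SMILES; empty strings mean H
coumarin_smiles <- function(assignment) {
  br <- function(x) if (nzchar(x)) paste0("(", x, ")") else ""
  paste0("O=C1C", br(assignment[["R3"]]),
         "=C", br(assignment[["R4"]]),
         "c2c", br(assignment[["R5"]]),
         "c", br(assignment[["R6"]]),
         "c", br(assignment[["R7"]]),
         "c", br(assignment[["R8"]]),
         "c2O1")
}

#' The unsubstituted coumarin scaffold
#'
#' @return A [parse_smiles()] molecule of 2H-chromen-2-one.
#' @export
coumarin_core <- function() {
  parse_smiles("O=C1C=Cc2ccccc2O1")
}
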