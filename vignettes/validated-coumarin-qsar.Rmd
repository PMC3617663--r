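---
title: "Validated QSAR modeling of antioxidant coumarins: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validated QSAR modeling of antioxidant coumarins: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coumarinQSAR)
```

## The problem

Coumarin derivatives scavenge free radicals; their potency against the
stable DPPH radical is expressed as pIC50 = log10(1/IC50) with IC50 on the
molar scale. Given a table of computed molecular descriptors (spatial,
topological, electronic, structural) for a set of coumarins, or their 2-D
structures as SMILES, the task is to build regression models that predict
pIC50 and — just as importantly — to validate those models with the metric
battery this field demands, because a QSAR model is only as credible as its
internal and external validation.

The package covers three tracks: descriptor-based model search (GFA and
G/PLS), hologram QSAR on molecular fragments, and the validation machinery
shared by both. A reference study of 45 coumarins (32 training, 13 test) is
embedded as a fixture: its printed activity table and its selected
five-term spline model, so that every statistic computable from printed
numbers alone is recomputed by the test suite and by
`reproduce_reference_statistics()`.

## Descriptor-based models

### Basis terms and the spline option

Models are linear in basis terms: either a raw descriptor or a
truncated-power spline `<x − a> = max(0, x − a)` (both orientations are
supported). A spline term contributes nothing below its knot, which lets a
model express "activity rises once Density exceeds 1.18" — the form of the
reference model's fifth term. Knot candidates default to the observed
training values of the descriptor with the extremes excluded; that is how
GFA implementations traditionally place knots, and the reference model's
knot (1.18046, stored exactly) is plausibly such a data value.

### Genetic function approximation

`gfa_search()` evolves term subsets: tournament selection (size 2),
subset-exchange crossover (rate 0.9), add/remove/replace/knot-shift
mutation (rate 0.1), elitism (the best individual always survives, so the
best score is monotone), at most `max_terms` terms (default 5, the size of
the reference model). Fitness is Friedman's lack-of-fit

LOF = (RSS/m) / (1 − (c + d·p)/m)²

with `c` the number of basis functions, `p = c + 1` the parameter count
including the intercept, `m` the training size, and smoothness `d = 1` by
default — the canonical GFA formulation; the source material names GFA but
gives no fitness details, so these constants are this package's design
choice. Rank-deficient candidates score `Inf` and die out. Ranking is
deterministic: LOF, then fewer terms, then lexicographic term labels; the
whole search is reproducible from `config$seed`.

A property of this fitness worth knowing: at `d = 1` and `m` near 30–45,
a spurious extra term is accepted whenever it absorbs roughly ten percent
of the residual sum of squares, and with several candidate descriptors the
best-of-k partial F statistic crosses that line in a nontrivial fraction of
random datasets. In recovery experiments on planted two-term truths the top
model therefore always contains the true descriptors, but in roughly one
run in six it carries one extra noise term. That is the expected behaviour
of the criterion, not a search failure; raising `lof_smoothness_d`
increases parsimony pressure if exact-support recovery matters more than
fit.

The search budget is a convergence knob, not a statistical parameter: the
package defaults (population 100, 500 generations) are desk-scale; the test
suite uses 100 × 300 for the calibration experiment, where the search
converges on every seed, and smaller budgets for cheap unit checks.

### G/PLS

`gpls_search()` keeps the genetic machinery but fits each candidate by
NIPALS PLS (centered, unit-variance scaled for descriptor blocks) at the
latent-variable count that maximizes leave-one-out Q² (up to
`max_components`), with lack-of-fit taken on the PLS residuals. With
`component_selection = "max"` and components equal to the rank, PLS
coincides with least squares and the ranking reduces exactly to
`gfa_search()`'s — a property the tests exploit as an equivalence oracle.

### NIPALS

`pls_fit()` is a standard single-response NIPALS: weights from the
covariance of the deflated predictor block with the response, scores,
loadings, deflation, and the regression vector `B = W(PᵀW)⁻¹q` mapped back
to the original scale. Holograms are centered but not scaled (bins are
counts on a common scale); descriptor blocks are scaled (heterogeneous
units). At full rank NIPALS reproduces OLS predictions to numerical
precision, which the suite asserts at 1e−8.

## The validation battery

All metrics operate on aligned observed/predicted vectors:

- `pearson_r2()` — squared Pearson correlation, symmetric in its axes.
- `r0_squared()` — determination coefficient of the least-squares fit
  through the origin, `k = Σxy/Σx²`; asymmetric, possibly negative.
- `rm2_metrics()` — `r_m² = r²(1 − √(r² − r0²))` with observed on the first
  axis, the primed variant with axes interchanged, and the two summary
  forms: mean and absolute difference. Two numerical choices matter.
  First, `r² − r0²` is clamped at zero before the square root: `r0²` can
  exceed `r²` on rare well-aligned data, and the clamp keeps the radical
  real while matching the metric's published behaviour. Second, activities
  enter unscaled — the later convention of min–max scaling the inputs
  postdates the metric's original form, and only the unscaled form
  reproduces the reference values (0.725 / 0.128 on the fixture test set).
- `r2_pred()` — external predictive R² against the training-mean baseline;
  exactly 1 for perfect prediction, exactly 0 for the baseline itself.
- `loo_press_q2()` — literal leave-one-out: the fixed term set is refitted
  with each compound deleted; PRESS is the sum of squared deletion
  residuals and `Q² = 1 − PRESS/TSS`. This assumes the model specification
  is fixed across folds (the selection is not re-run per fold); the
  alternative reading — re-running variable selection in each fold — is
  available through `y_randomize(mode = "process")`-style machinery but is
  not what the reference Q² appears to report, since the printed PRESS
  satisfies the fixed-spec identity.
- `regression_stats()` — `s = √(RSS/(n − p − 1))`,
  `F = (R²/p)/((1 − R²)/(n − p − 1))`, `Ra² = 1 − (1 − R²)(n − 1)/(n − p − 1)`.
  `p` counts non-intercept terms, a spline term counting once; on the
  fixture (n = 32, p = 5, df = 26) this reproduces the printed s and F.
- `y_randomize()` — scrambles the activity vector (identity permutation
  excluded), refits, and records each scrambled R². Model mode refits the
  fixed term set; process mode re-runs the genetic selection per
  permutation. Conventional counts are 9 permutations for 90% confidence
  and 99 for 99% (the (1 − α) = m/(m+1) rule); fewer than 9 triggers a
  recorded warning. Under the null, the expected scrambled R² for p
  regressors is p/(n − 1), which the suite verifies by Monte Carlo.
- `crp2()` — `R·√(R² − R̄r²)`, reported as 0 with a flag when the scrambled
  mean exceeds the model's R²; monotone decreasing in the scrambled mean.

`metric_report()` assembles the full panel. The overall r_m² block
concatenates LOO training predictions with test predictions; the reference
study's LOO predictions were never printed, so this block is reproducible
only against the package's own refits, never against the fixture — the
desk-reproduction path excludes it deliberately.

One recorded ambiguity: the source material's running text and its summary
table swap the two cR_p² values (0.850/0.780) between process and model
randomization. `published_model_statistics()` stores both attributions
without attempting reconciliation.

## Cluster-based splitting

`cluster_split()` z-scores the descriptor columns, runs k-means (k-means++
seeding, default k = ⌈n/5⌉, up to 10 restarts if a cluster empties), and
allocates test quotas per cluster proportionally to cluster size with
largest-remainder rounding, with every cluster retaining at least one
training member. Within a cluster the points most distant from the centroid
(up to 20%, always at least one when room permits) are reserved for
training, and test members are taken nearest the centroid — so the training
set spans the chemical space and test compounds interpolate rather than
extrapolate. On convex synthetic blobs this yields test descriptor ranges
nested inside training ranges, which the suite checks. The source material
names only "cluster analysis"; every detail above is a package design
choice, and the reference 32/13 membership is shipped as a fixture rather
than re-derived.

## Hologram QSAR

### Molecular graphs

`parse_smiles()` is a compact reader for the organic subset plus bracket
atoms, branches and ring closures. It keeps aromatic bonds as their own
bond class instead of kekulizing; this matters because fragment keys built
from alternating single/double assignments would depend on how a ring was
written, breaking the invariance of holograms under atom reordering that
the engine guarantees. Implicit hydrogens follow standard valence rules;
bracket atoms carry exactly the hydrogens they declare. Donor/acceptor
classes use the standard pharmacophoric definition: donor = N/O with at
least one hydrogen, acceptor = N/O without positive formal charge.

### Fragments, keys, and holograms

`enumerate_fragments()` emits every connected induced subgraph with atom
count in the configured range, each distinct atom set once (ESU
enumeration — linear, branched, cyclic, and overlapping fragments are all
covered; a fragment is an atom subset, not a path, which is the reading
consistent with "overlapping" features). A guard caps fragments at 12
atoms. `fragment_key()` canonicalizes a fragment using exactly the flagged
properties (A atoms, B bonds, C connectivity, H hydrogens, DA
donor/acceptor): Morgan-style iterative refinement of atom colours followed
by backtracking individualization of tied classes, taking the
lexicographically smallest labelling — so keys are invariant under any
renumbering, which the suite verifies by permutation tests.
`build_hologram()` hashes each key with CRC-32 into `counts[hash mod L + 1]`
for a prime length L; bin collisions are intrinsic to the method. The
proprietary engine's exact hash is not public, so bit-compatibility with it
is a non-goal; internal self-consistency (invariance, conservation of the
occurrence count, sensitivity to substituent changes) is the contract.

### Model fitting and grid selection

`hqsar_fit()` fits centered NIPALS PLS on the hologram block and scores
every latent-variable count up to `max_components` by leave-one-out Q²,
additionally capped at ⌊n/5⌋ against overfitting;
`SEcv = √(PRESS/(n − c − 1))` with `c` components (the assumed
degrees-of-freedom convention). `hqsar_grid_train()` reproduces the staged
protocol: best fragment-distinction flags at the default size (4–7), then
best fragment size, then best hologram length, each stage selected by
maximum Q² with ties broken by minimum SEcv then smaller length. The
selection rule is a pure function (`hqsar_select()`), so the suite can
replay it on previously reported grid-statistics tables as inputs and
confirm it picks the reported winners (A/D&A; size 4–9 at length 83).
`five_percent_rule()` re-examines the component count: a latent variable is
kept only when it improves Q² by at least 5% of the previous value; fed the
reported component profile (0.397 → 0.525 → 0.538) it returns increases of
32.242% and 2.476% and keeps four components.

### Contribution maps

Each fragment occurrence contributes its bin's regression coefficient,
split equally over the fragment's atoms; summed per atom, the
contributions satisfy Σ(atoms) = prediction − intercept exactly, which the
suite asserts at 1e−8. Colour bins run red → red-orange → white → yellow →
green. The reference study's printed colour ranges are mutually
inconsistent (the white band overlaps the red-orange one), so they are not
used as defaults; default thresholds are the quintiles of the training-set
atom-contribution distribution, and explicit thresholds can be supplied.

## Synthetic data: what it emulates, and what it does not

No machine-readable inputs of the reference study exist beyond its printed
activity table: descriptor matrices came from commercial software, and the
structures are images. The generators therefore stand in for them.

`gen_descriptor_dataset()` draws descriptors from an equicorrelated
Gaussian (default pairwise correlation 0.3) and builds activity from a
five-term linear-plus-spline truth with Gaussian noise (default sd 0.35
pIC50). The defaults put the activity standard deviation near 1.2 —
exactly the dispersion implied by the reference training set's total sum
of squares — with a central range of about 1–5.2 pIC50, so metric
magnitudes are comparable to the reference panel. What it does not
emulate: real descriptor distributions are neither Gaussian nor
equicorrelated (surface areas are skewed, atom counts are integers), and
real structure–activity relationships are not exactly sparse-linear. A
passing recovery test therefore shows the machinery is correct under the
assumed data model, not that it would select the same descriptors on the
original matrix.

`gen_coumarin_smiles()` enumerates the 2H-chromen-2-one scaffold with
substituents (OH, OMe, Me, NO2, F, Cl, Br, benzyloxy) at ring positions
3–8 and assigns activity as base (1.6) plus additive substituent effects
plus noise (default sd 0.3), with oxygen-bearing substituents carrying the
positive effects — mirroring the qualitative conclusion that oxygen-bearing
fragments favour antioxidant activity. Effects are additive by
construction, so contribution-map localization tests have a planted ground
truth; real substituent effects interact.

## Problem sizes and numerical choices

The test suite runs at desk scale, chosen so each experiment is converged
rather than fast: recovery and calibration experiments use 20 seeded
datasets of 32–45 compounds; the null-distribution check for
Y-randomization uses n = 100, p = 5, 200 permutations; hologram invariance
uses 20 permutations of each of 10 generated coumarins; fragment
enumeration is cross-checked against a brute-force subset oracle on all
fixture molecules with at most 8 heavy atoms. Tolerances: published-value
reproduction at ±0.002 (R²-type, s), ±0.005 (r_m² family), ±0.5 (F) — the
propagation of 3-decimal rounding in the printed activities; algebraic
identities (PLS/OLS equivalence, contribution conservation) at 1e−8.
Degenerate inputs fail loudly: zero-variance responses, rank-deficient
designs (with the collinear terms named), exhausted degrees of freedom,
unclosed rings in SMILES, and over-large fragment requests are all errors,
not warnings.

## Known limitations

- The descriptor matrix of the reference study being unavailable, Q²,
  r_m²(LOO), r_m²(overall) and the cR_p² values cannot be recomputed from
  scratch; they are covered by property-based tests on synthetic data and
  by the PRESS identity.
- The SMILES reader covers the organic subset the generators produce; it is
  not a general cheminformatics parser (no stereochemistry semantics, no
  isotope distinction, no disconnected structures).
- Fragment canonicalization is exact but exponential in the worst case over
  highly symmetric fragments; the 12-atom guard keeps it comfortably fast.
- The genetic search is stochastic; identical seeds give identical output,
  but different budgets explore differently. Convergence should be checked
  by the elitism trace (`attr(result, "best_lof_trace")`) when in doubt.
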