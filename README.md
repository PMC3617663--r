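# coumarinQSAR

Quantitative structure–activity modeling of antioxidant coumarin
derivatives, rebuilt as a tested, reusable R package. Coumarins scavenge the
stable DPPH radical, and their potency (pIC50 = −log10 of the molar IC50)
can be modeled from computed molecular descriptors and from molecular
fragments. This package implements the three analysis tracks such a study
runs, and the full validation battery used to judge the resulting models:

- **Descriptor-based model search** — genetic function approximation (GFA)
  over linear and truncated-power spline basis terms `<x − a> = max(0, x − a)`,
  scored by Friedman's lack-of-fit `LOF = (RSS/m) / (1 − (c + d·p)/m)²`, and a
  genetic PLS variant (G/PLS) built on an in-package NIPALS implementation.
- **Validation metrics** — r², through-origin r0², the r_m² family
  (`r_m² = r²(1 − √(r² − r0²))`, computed in both axis orientations with its
  mean and Δ summaries), external predictive R²
  (`R²_pred = 1 − Σ(obs − pred)²_test / Σ(obs_test − ȳ_train)²`),
  leave-one-out PRESS/Q², classical s/F/Ra², and Y-randomization with the
  chance-correlation parameter `cR_p² = R·√(R² − R̄r²)`.
- **Cluster-based splitting** — k-means on z-scored descriptors with
  per-cluster proportional test allocation, reserving each cluster's extreme
  points for training so the training set spans the chemical space.
- **Hologram QSAR (HQSAR)** — exhaustive connected-fragment enumeration,
  canonical fragment keys under configurable distinction flags (atoms,
  bonds, connectivity, hydrogens, donor/acceptor), CRC-32 hashing into
  prime-length count vectors, PLS with leave-one-out Q², staged
  flags→size→length grid selection, the 5% rule for latent variables, and
  per-atom contribution maps.

The package embeds, as fixtures, the published 45-compound activity table
of its reference study (32 training / 13 test compounds) and the selected
five-term GFA spline model

```
pIC50 = −0.123 + 1.243·Atype_O57 + 0.010·JursPPSA_1 − 0.806·Atype_C25
        + 0.085·²κ + 67.5·<Density − 1.18046>
```

so that every statistic that depends only on printed numbers can be
recomputed and checked. Descriptor values are consumed as inputs, never
computed; the original compound structures exist only as images, so the
HQSAR track runs on generated substituted-coumarin SMILES with a planted
structure–activity pattern (module `gen_coumarin_smiles()`).

## Worked example

Recompute the reference model's desk-reproducible validation panel from the
embedded activity table:

```r
library(coumarinQSAR)
reproduce_reference_statistics()
#>              metric   computed published tolerance pass
#> 1                R2  0.9279388     0.928     0.002 TRUE
#> 2               Ra2  0.9140809     0.914     0.002 TRUE
#> 3                 s  0.3518459     0.352     0.002 TRUE
#> 4                 F 66.9609301    66.980     0.500 TRUE
#> 5 Q2_press_identity  0.8405499     0.841     0.002 TRUE
#> 6           R2_pred  0.9082150     0.908     0.002 TRUE
#> 7     rm2_test_mean  0.7254360     0.725     0.005 TRUE
#> 8    delta_rm2_test  0.1275253     0.128     0.005 TRUE
```

Row by row: the training fit (R², adjusted R², standard error of estimate
and F at p = 5 terms, df = 26), Q² recovered through the identity
`Q² = 1 − PRESS/TSS` from the published PRESS = 7.122, and the external
panel (R²_pred against the training-mean baseline, and the r_m²(test)
mean/Δ pair) — all within the tolerance implied by the 3-decimal rounding
of the printed activities.

A full synthetic run of the descriptor workflow:

```r
tbl   <- gen_descriptor_dataset(synthetic_spec(seed = 2026))
split <- cluster_split(tbl, n_test = 13, seed = 2026)
parts <- apply_split(tbl, split)
top   <- gfa_search(parts$train, gfa_config(population_size = 50,
                                            generations = 40, seed = 2026))[[1]]
metric_report(parts$train, parts$test, top$terms, seed = 2026)
#> n(train) = 32, n(test) = 13
#> R2 = 0.886  Ra2 = 0.869  s = 0.572  F = 52.614
#> PRESS = 12.567  Q2 = 0.838  rm2(LOO) = 0.772  delta = 0.111
#> R2pred = 0.626  rm2(test) = 0.542  delta = 0.064  cRp2(model) = 0.825
```

The numbered drivers under `analysis/` run the three tracks end to end and
write their tables under `results/`:

```sh
Rscript analysis/01_reproduce_statistics.R   # desk reproduction + negative control
Rscript analysis/02_descriptor_workflow.R    # split -> GFA -> validation panel
Rscript analysis/03_hqsar_workflow.R         # HQSAR grid -> 5% rule -> contribution map
```

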