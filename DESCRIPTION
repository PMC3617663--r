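Package: coumarinQSAR
Title: Descriptor-Based QSAR, Validation Metrics, and Hologram QSAR for
    Antioxidant Coumarins
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Re-implements a three-pronged QSAR analysis of antioxidant
    coumarin derivatives: genetic function approximation (GFA) model search
    over linear and truncated-power spline basis terms scored by Friedman's
    lack-of-fit, genetic partial least squares (G/PLS), the r_m^2 family of
    internal/external validation metrics together with predictive R^2,
    leave-one-out Q^2/PRESS and Y-randomization with the cR_p^2 parameter,
    cluster-analysis-based training/test splitting, and a hologram QSAR
    engine (connected-fragment enumeration, canonical fragment keys, CRC-32
    hashing into prime-length count vectors, NIPALS PLS, the 5% rule for
    latent-variable selection, and per-atom contribution maps). Ships the
    published 45-compound coumarin DPPH pIC50 activity table and the
    published five-term GFA spline model as fixtures, plus synthetic-data
    generators for descriptor matrices and substituted-coumarin SMILES.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    mixOmics,
    igraph
Config/testthat/edition: 3
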