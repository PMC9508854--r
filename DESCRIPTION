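Package: chromoclutch
Title: Nucleosome-Resolution Analysis of Chromatin Unfolding Under Tension
    and Crowding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to characterize how chromatin fibers unfold under pulling
    forces and molecular crowding at nucleosome resolution.  Provides a data
    model for nucleosome rigid-body frames and wrap fractions, the collective
    variables used to monitor unfolding (inter-nucleosome stacking distance,
    wrapping degree, the clutch ratio alpha, shear/normal decompositions and
    inter-chain contacts), a toy Metropolis Monte Carlo chromatin simulator
    with umbrella and constant-force biases, WHAM free-energy reconstruction
    with block-averaged errors and force-extension reweighting, a
    force-matched neural-network surrogate free-energy model over
    inter-nucleosome distances, and single-linkage RMSD clustering for
    representative-structure extraction.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    bio3d,
    yaml,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
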