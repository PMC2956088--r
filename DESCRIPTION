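Package: pgdimer
Title: Potential-of-Mean-Force and Interface Analysis for Peptide Dimerization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis machinery for restrained molecular-dynamics studies of
    beta-hairpin antimicrobial peptide dimerization. Builds potential-of-mean-force
    profiles from per-window restraint-force time series by trapezoidal integration
    of block-averaged mean forces, converts profiles into relative equilibrium
    binding constants and dimerization free energies, and performs a persistence-
    filtered census of ionic bridges (contact and solvent-separated guanidinium
    pairs) and hydrogen bonds on coordinate trajectories. Ships a synthetic-data
    generator (correlated-noise and overdamped-Langevin force series on known
    one-dimensional landscapes, scheduled-contact trajectories) so every stage is
    testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    bio3d,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
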