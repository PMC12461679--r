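Package: pncnmr
Title: Structural and NMR Ensemble Analysis of Calcium Phosphate
    Prenucleation Clusters
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for solution-state 31P NMR of calcium
    phosphate prenucleation clusters (PNCs). Provides ion-cluster
    detection and structural analytics for molecular-dynamics
    trajectories (formation detection from Ca-P distance RMSD,
    connected-component cluster identification, hydration-shell
    counting, Ca-P distance distributions with crystal-phase
    references), bootstrap ensemble averaging of per-snapshot isotropic
    magnetic shieldings with percentile confidence intervals,
    Henderson-Hasselbalch speciation weighting of phosphate protonation
    states, shielding-to-shift referencing, Lorentzian lineshape
    synthesis and fitting for fingerprint spectra, solution-condition
    bookkeeping (box electroneutrality, mixing and dilution
    arithmetic), and seeded synthetic-data generators with planted
    ground truth standing in for the MD/DFT stages.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    igraph,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
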