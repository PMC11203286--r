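Package: floraNMR
Title: 1H-NMR Metabolite Fingerprinting for Flower Species Ingredient
    Verification
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis of one-dimensional 1H-NMR metabolite
    fingerprints of flower extracts for botanical ingredient authentication.
    Provides a chemical-shift signature library of flower metabolites,
    multiplet simulation from J-couplings with Lorentzian lineshapes, a
    synthetic multi-species cohort generator with color-variant edits,
    spectral calibration and asymmetric least squares baseline correction,
    rectangular bucketing with solvent-region exclusion and per-spectrum
    integer normalization, Euclidean/Ward hierarchical clustering with
    species-recovery scoring, and peak picking with chemical-shift library
    matching for metabolite assignment. Spectra are read and written as
    plain two-column text or JCAMP-DX.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    yaml,
    jsonlite,
    ape,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
biocViews: Metabolomics, Classification, Clustering, QualityControl
RoxygenNote: 7.3.3
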