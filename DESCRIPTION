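Package: ensembledecomp
Title: Conformational Ensemble Decomposition for Disordered Peptides
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Decomposes simulated conformational ensembles of intrinsically
    disordered peptides into groups of a combined conformation parameter
    built from per-frame radius of gyration, end-to-end distance and
    solvent-accessible surface area. Provides per-frame structural
    descriptors (Rg, Ree, SASA, polymer shape, RMSF, minimum-distance and
    hydrogen-bond contact maps), dihedral-angle featurization with PCA and
    time-lagged independent component analysis (tICA) free-energy
    landscapes, K-means clustering with elbow selection and medoid
    representative extraction, small-angle X-ray scattering utilities
    (rebinning, Guinier fits, normalized Kratky transforms, chi-squared
    model comparison, Debye toy curves), charge-patterning sequence
    parameters (kappa, FCR, NCPR, hydropathy), and a synthetic dihedral
    backbone generator so every analysis is testable without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    MASS,
    purrr,
    Rcpp,
    rlang,
    seqinr,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
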