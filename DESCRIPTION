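Package: crossvae
Title: Cross-Species Single-Cell Comparison with VAE-Based In-Silico Humanization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for comparing single-cell transcriptomic
    responses between two species (cynomolgus monkey and human PBMCs as the
    motivating system). Provides ortholog-aware gene-space harmonization,
    MAD/doublet/cluster-vote quality control, cluster majority annotation,
    a from-scratch variational autoencoder with latent shift-vector
    arithmetic for in-silico humanization and temporal trajectory geometry,
    a perturbation-based feature-importance heuristic with a sign-concordance
    test, cross-species differential-expression and pathway co-enrichment
    statistics, ligand-receptor conservation analysis, and a negative-binomial
    two-species synthetic data generator with planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    MASS,
    igraph,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
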