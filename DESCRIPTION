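Package: bcrep
Title: B Cell Receptor Repertoire Variability Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing variability in B cell receptor (BCR)
    heavy-chain repertoires from annotated rearrangement tables: quality
    filtering and fixed-depth subsampling, constant-region sequencing
    error-rate estimation, CDR3-based clonal clustering with nearest-neighbour
    distance diagnostics and threshold scans, rarefaction with Chao richness
    extrapolation, Chapman capture-recapture repertoire-size estimation,
    replicate overlap metrics, Shannon/Simpson/clonality indices and Hill
    diversity profiles, VJ gene usage summaries with PCA, temporal cluster
    persistence, and public (cross-individual) repertoire characterisation
    with antigen-specificity annotation. Includes a synthetic repertoire
    simulator that reproduces the statistical structure these analyses
    assume, so the whole pipeline is testable without raw sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    methods,
    Biostrings,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    vegan,
    jsonlite
Config/testthat/edition: 3
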