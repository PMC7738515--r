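Package: multiRppa
Title: Integrative Analysis of Multi-Platform Reverse-Phase Protein Array Data
Version: 0.99.0
Authors@R: person("RPPA", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for integrating reverse-phase protein array (RPPA) data
    generated on multiple platforms with distinct workflows. Provides a
    synthetic multi-platform study generator with known ground truth,
    simplified per-platform processing (technical-replicate aggregation,
    dilution-series fitting, total-protein normalisation), antibody-wise
    median centring and cross-platform concatenation, agglomerative
    hierarchical clustering with rank-correlation distances and
    TreeView-compatible output, clustered antibody antigen maps with
    concordance scoring, all-pairs correlation statistics with Fisher
    z-tests, and moderated t-tests with permutation-based false discovery
    rate control for drug-response contrasts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3), SummarizedExperiment
Imports: methods, stats, utils, graphics, grDevices, S4Vectors, data.table, jsonlite, yaml
Suggests: testthat (>= 3.0.0), withr
biocViews: Proteomics, Normalization, Clustering, QualityControl, Software
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
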