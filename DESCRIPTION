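Package: omiclag
Title: Paired Transcriptome-Proteome Time-Course Analysis with Translation Lag
Version: 0.1.0
Authors@R: person("Omiclag", "Developers", role = c("aut", "cre"),
    email = "maintainers@omiclag.dev")
Description: Tools for analysing paired bulk RNA-seq and label-free proteomics
    time courses, motivated by starvation-induced multicellular development in
    the social amoeba Dictyostelium discoideum. Provides differential
    expression for both modalities (negative-binomial likelihood-ratio tests
    for counts, empirical-Bayes moderated F-tests for log-intensities),
    missing-not-at-random imputation by a probabilistic minimum, hierarchical
    clustering of fold-change profiles with Fisher-exact gene-set enrichment,
    fraction-of-total scaling, across-gene and per-gene mRNA-protein
    correlations including a full time-lag matrix, ranged-major-axis
    regression, protein:mRNA ratio dynamics with Dunnett many-to-one
    contrasts, and a deterministic multi-view factor decomposition with
    per-view variance explained. A synthetic paired-omics generator with an
    explicit mRNA-to-protein kinetic lag makes every stage testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
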