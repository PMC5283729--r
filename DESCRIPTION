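Package: metabolokit
Title: Processing, Design-Driven Statistics, Network Construction and
    Functional Analysis for Metabolomic Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A desk-scale toolbox for post-acquisition metabolomic data
    analysis. Provides intensity-table import and validation, value
    transformation, sample- and feature-based normalization including
    QC-LOESS signal-drift correction with cross-validated span selection,
    PCA overviews, study-design-driven univariate statistics with automatic
    method suggestion (Welch/Student t, Mann-Whitney, Welch ANOVA,
    Kruskal-Wallis, repeated-measures ANOVA with Greenhouse-Geisser
    correction, Friedman, factorial and mixed ANOVA with a trimmed-means
    robust variant), post hoc procedures (Games-Howell, Tukey, Dunn,
    Bonferroni families) with Benjamini-Hochberg FDR control, bootstrap
    tests and power analysis. Constructs knowledge-based networks from
    flat-file property graphs, data-driven correlation and shrinkage
    partial-correlation networks, and Tanimoto chemical-similarity networks
    from substructure fingerprints; scores nodes with a beta-uniform
    mixture model of p-values and extracts high-scoring connected
    subnetworks. Functional interpretation via functional class scoring
    (Fisher, Stouffer, Reporter, median, mean with entity permutation),
    hypergeometric overrepresentation analysis with multi-type combination,
    and annotation term frequencies. Includes seeded synthetic-data
    generators and a configuration-driven pipeline runner.
License: GPL-3
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    igraph,
    car,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
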