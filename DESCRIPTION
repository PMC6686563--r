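Package: netmark
Title: Network-Based Biomarker Discovery from Gene Co-Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovery of condition-specific transcriptomic biomarkers from
    gene expression studies via co-expression network rewiring. Implements an
    end-to-end pipeline for case/control expression matrices: quality control
    (missing-gene filtering, KNN imputation, median normalization, PCA plus
    local-outlier-factor sample screening), empirical-Bayes moderated-t
    differential expression with a sample-type covariate, per-condition
    weighted co-expression networks built from normalized mutual information
    with permutation-calibrated edge significance, differential PageRank
    centrality with bootstrap inference, power-law degree diagnostics, and a
    multi-objective genetic-algorithm wrapper around cross-validated support
    vector machines that selects compact, accurate gene signatures. A seeded
    synthetic-study generator with planted differential expression, hub
    rewiring, outliers and missingness supports calibration and recovery
    testing, and a packaged miRNA:target confidence table links signatures to
    candidate regulators.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    e1071,
    yaml,
    jsonlite,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    limma,
    MASS
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllGenerics.R'
    'AllClasses.R'
    'RcppExports.R'
    'core_io.R'
    'network.R'
    'centrality.R'
    'diffexp.R'
    'gasvm.R'
    'netmark-package.R'
    'preprocess.R'
    'pipeline.R'
    'synthetic.R'
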