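Package: decayflux
Title: mRNA Decay Kinetics, Regulatory Control Coefficients and
    Expression-Constrained Flux Balance Analysis
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimates genome-wide mRNA half-lives from
    transcription-arrest RNA-seq time courses by first-order decay
    fitting with reference-gene drift correction and coefficient-of-
    variation quality control; partitions changes in steady-state
    transcript abundance between growth conditions into transcriptional
    and degradational control coefficients; calls consensus
    differentially expressed genes across methods and pools reads over
    operons; and predicts condition-dependent metabolic phenotypes by
    flux balance analysis with biomass coefficients refitted so that
    flux ratios track expression ratios of differentially expressed
    genes. Includes a synthetic-data generator with ground truth for
    parameter-recovery testing and a compiled dense simplex kernel for
    the linear programs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.3.0),
    S4Vectors,
    SummarizedExperiment
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    xml2,
    limma,
    minpack.lm,
    Matrix,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
biocViews: Transcriptomics, GeneExpression, DifferentialExpression,
    SystemsBiology
RoxygenNote: 7.3.3
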