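Package: dysbiome
Title: Gut Microbiome Dysbiosis Indices and Lung Function Decline
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline linking species-level gut metagenomic
    profiles to lung function outcomes in a clinical cohort. Reads
    MetaPhlAn-style merged relative-abundance tables, derives rapid
    lung-function-decline and airflow-limitation outcomes from spirometry,
    computes alpha/beta diversity with covariate-adjusted PERMANOVA, runs a
    negative-binomial Wald differential-abundance analysis with
    median-of-ratios normalization and parametric dispersion shrinkage,
    constructs a microbial dysbiosis index (log10 ratio of
    outcome-enriched over outcome-depleted species) with Mann-Whitney
    sensitivity pruning, estimates adjusted odds ratios from multivariable
    logistic regressions, and builds Spearman co-occurrence networks. A
    synthetic-cohort generator with planted effects and known ground truth
    supports calibration and parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils,
    vegan,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    DESeq2,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
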