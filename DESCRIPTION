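Package: methylFR
Title: Bayesian Functional Regression for Differential Methylation from
    Bisulfite Sequencing Counts
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Identifies differentially methylated cytosines (DMCs) from
    sequencing-derived methylation count data using a Bayesian functional
    regression model. Per-CpG methylated read counts are modelled as
    binomial with a logit link decomposed over a natural cubic spline
    basis evaluated at genomic coordinates, with baseline, group-contrast,
    individual-level and covariate blocks (including a read-depth
    covariate). Inference uses a block Gibbs sampler with
    Gaussian-approximation full-conditional updates; missing positions
    (zero read depth) drop out of the likelihood and are imputed by the
    smooth posterior. DMCs are called from credible intervals of group
    contrasts. The package ships synthetic-data generators for four
    benchmark simulation designs and the matching evaluation metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    splines,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    parallel,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
biocViews: DNAMethylation, DifferentialMethylation, Bayesian, Regression,
    Sequencing, Coverage
RoxygenNote: 7.3.3
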