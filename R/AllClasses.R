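#' @import methods
#' @importFrom stats quantile sd var ave rnorm rbinom runif rpois
#'   rnbinom rt plogis qlogis spline
#' @importFrom utils read.delim write.table packageVersion
#' @importClassesFrom SummarizedExperiment RangedSummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   rowRanges colData
#' @importFrom GenomicRanges GRanges start end seqnames
#' @importFrom IRanges IRanges width
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @useDynLib methylFR, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Methylation count container
#'
#' \code{MethylCounts} holds per-CpG bisulfite-sequencing counts for a set
#' of samples: a \code{meth} assay (methylated read counts \eqn{y}) and a
#' \code{depth} assay (total read depths \eqn{n}), with CpG positions as
#' row ranges and sample metadata (including the mandatory \code{group}
#' factor) as column data.  Entries with \eqn{n = 0} are treated as
#' missing: they are stored as \eqn{y = 0, n = 0} and contribute nothing
#' to the model likelihood.
#'
#' @slot .  Inherits all slots from
#'   \linkS4class{RangedSummarizedExperiment}.
#' @seealso \code{\link{MethylCounts}} (constructor),
#'   \code{\link{methReads}}, \code{\link{totalReads}},
#'   \code{\link{missingMask}}
#' @export
setClass("MethylCounts", contains = "RangedSummarizedExperiment")

setValidity("MethylCounts", function(object) {
    msg <- character()
    an <- SummarizedExperiment::assayNames(object)
    if (!all(c("meth", "depth") %in% an))
        return("assays 'meth' and 'depth' are required")
    y <- assay(object, "meth")
    n <- assay(object, "depth")
    if (any(!is.finite(y)) || any(!is.finite(n)))
        msg <- c(msg, "counts must be finite (use y=0,n=0 for missing)")
    else {
        if (any(y < 0) || any(n < 0))
            msg <- c(msg, "counts must be non-negative")
        bad <- which(y > n)
        if (length(bad)) {
            rc <- arrayInd(bad[1L], dim(y))
            msg <- c(msg, sprintf(
                "methylated reads exceed depth (first at row %d, sample %d)",
                rc[1L], rc[2L]))
        }
    }
    pos <- start(rowRanges(object))
    if (length(pos) > 1L && any(diff(pos) <= 0))
        msg <- c(msg, "positions must be strictly increasing (duplicates rejected)")
    if (length(unique(as.character(seqnames(object)))) > 1L)
        msg <- c(msg, "a MethylCounts object covers a single chromosome")
    if (!"group" %in% colnames(colData(object)))
        msg <- c(msg, "colData must contain a 'group' column")
    if (length(msg)) msg else TRUE
})

#' Index partition of a methylation region
#'
#' Contiguous, disjoint index ranges over the CpG axis used to fit the
#' model piecewise.  Regions default to 500 positions; a degenerate
#' trailing remainder shorter than the spline resolution is merged into
#' the preceding range so every fitted region supports its basis.
#'
#' @slot ranges \code{IRanges} of 1-based closed index ranges.
#' @slot nPositions total number of positions covered.
#' @slot size requested partition size.
#' @export
setClass("RegionPartition",
    representation(ranges = "IRanges", nPositions = "integer",
                   size = "integer"))

setValidity("RegionPartition", function(object) {
    r <- object@ranges
    if (length(r) == 0L) return("empty partition")
    s <- IRanges::start(r); e <- IRanges::end(r)
    if (s[1L] != 1L || e[length(r)] != object@nPositions)
        return("partition must cover 1..T")
    if (length(r) > 1L && any(s[-1L] != e[-length(r)] + 1L))
        return("partition ranges must be contiguous and disjoint")
    TRUE
})

#' Natural cubic spline basis over genomic coordinates
#'
#' The basis is evaluated at the actual genomic coordinates (not at the
#' CpG rank), so uneven CpG spacing changes the fitted smooth.  Column 1
#' is the constant function; columns 2..p are a natural cubic spline with
#' interior knots at coordinate quantiles of the observed CpGs and
#' boundary knots at the region ends (linear extrapolation beyond them).
#'
#' @slot positions genomic coordinates the basis was evaluated at.
#' @slot p basis dimension (the resolution / bandwidth).
#' @slot knots interior knot coordinates.
#' @slot boundary boundary knot coordinates (length 2).
#' @slot matrix the T x p basis matrix.
#' @export
setClass("SplineBasis",
    representation(positions = "numeric", p = "integer", knots = "numeric",
                   boundary = "numeric", matrix = "matrix"))

#' Block design layout
#'
#' Maps the stacked parameter vector (baseline \eqn{\gamma_0}, group
#' contrasts \eqn{\delta_g} for \eqn{g \ge 2} with \eqn{\delta_1 \equiv 0},
#' per-sample deviations \eqn{\upsilon_{g,i}}, covariate effects
#' \eqn{\eta}) to column blocks, and records which samples each block
#' touches.  Supports a coarser resolution for the individual-level
#' blocks (multi-resolution fitting).
#'
#' @slot basisGroup \code{SplineBasis} for baseline/group blocks.
#' @slot basisIndiv \code{SplineBasis} for individual blocks.
#' @slot groups factor of length M; level 1 is the baseline group.
#' @slot sampleIds character sample identifiers.
#' @slot depthCovariate logical; include the log(n+1) read-depth column.
#' @slot covariates M x q matrix of standardized sample covariates.
#' @slot covariateCenter,covariateScale standardization constants.
#' @slot blocks list of block descriptors (name, type, cols, samples).
#' @slot npar total number of parameters.
#' @export
setClass("DesignLayout",
    representation(basisGroup = "SplineBasis", basisIndiv = "SplineBasis",
                   groups = "factor", sampleIds = "character",
                   depthCovariate = "logical", covariates = "matrix",
                   covariateCenter = "numeric", covariateScale = "numeric",
                   blocks = "list", npar = "integer"))

#' Prior specification for the coefficient blocks
#'
#' Either a common Gaussian prior N(0, tau^2) on every coefficient, or
#' per-block variances with an InverseGamma(a, b) hyperprior sampled
#' within the Gibbs chain.
#'
#' @slot kind \code{"common_gaussian"} or \code{"inverse_gamma"}.
#' @slot tau common prior standard deviation for the deviation blocks
#'   (group contrasts, individual effects, covariates); also the
#'   initial value in the inverse-gamma variant.
#' @slot tauBaseline prior standard deviation for the baseline block
#'   \eqn{\gamma_0}.  The empirical-Bayes scale \code{tau} measures
#'   across-sample variation and would squash the baseline level, so
#'   \eqn{\gamma_0} gets a weakly-informative scale (default 10 on the
#'   logit scale).
#' @slot a,b inverse-gamma hyperparameters.
#' @export
setClass("PriorSpec",
    representation(kind = "character", tau = "numeric",
                   tauBaseline = "numeric", a = "numeric",
                   b = "numeric"))

setValidity("PriorSpec", function(object) {
    if (!object@kind %in% c("common_gaussian", "inverse_gamma"))
        return("kind must be 'common_gaussian' or 'inverse_gamma'")
    if (!is.finite(object@tau) || object@tau <= 0 ||
        !is.finite(object@tauBaseline) || object@tauBaseline <= 0)
        return("tau must be a positive real (improper priors are not supported)")
    if (object@kind == "inverse_gamma" &&
        (object@a <= 0 || object@b <= 0))
        return("inverse-gamma hyperparameters must be positive")
    TRUE
})

#' MCMC chain configuration
#'
#' @slot nIter total iterations; \code{burnin} discarded; every
#'   \code{thin}-th kept thereafter.
#' @slot burnin,thin,seed integers.
#' @slot strategy block-update strategy: \code{"gauss"}
#'   (Gaussian-approximation exact update), \code{"mh1"} (single inner
#'   Metropolis-Hastings step) or \code{"mhN"} (multiple inner steps).
#' @slot mhInnerSteps inner MH steps for \code{"mhN"}.
#' @slot initSweeps deterministic quasi-IRLS sweeps used to seed the chain.
#' @slot refreshEvery sweeps between refreshes of the block curvature
#'   (X'WX) used by the Gaussian-approximation update.
#' @slot randomScan update blocks in random order instead of the fixed
#'   gamma0, delta, upsilon, eta order.
#' @export
setClass("ChainConfig",
    representation(nIter = "integer", burnin = "integer", thin = "integer",
                   seed = "integer", strategy = "character",
                   mhInnerSteps = "integer", initSweeps = "integer",
                   refreshEvery = "integer", randomScan = "logical"))

setValidity("ChainConfig", function(object) {
    if (object@nIter <= object@burnin)
        return("nIter must exceed burnin")
    if (object@thin < 1L) return("thin must be >= 1")
    kept <- (object@nIter - object@burnin) %/% object@thin
    if (kept < 1L) return("no draws would be kept")
    if (!object@strategy %in% c("gauss", "mh1", "mhN"))
        return("strategy must be 'gauss', 'mh1' or 'mhN'")
    TRUE
})

#' Posterior draws for one fitted region
#'
#' @slot draws kept draws (rows) of the stacked parameter vector.
#' @slot layout the \code{DesignLayout} the draws refer to.
#' @slot betaMean T x M posterior mean methylation level per sample.
#' @slot groupCurves T x G x nkeep array of logit-scale group-level
#'   curves x(gamma0 + delta_g).
#' @slot logLik per-kept-draw log-likelihood trace.
#' @slot config the \code{ChainConfig} used.
#' @export
setClass("PosteriorDraws",
    representation(draws = "matrix", layout = "DesignLayout",
                   betaMean = "matrix", groupCurves = "array",
                   logLik = "numeric", config = "ChainConfig"))

#' Partitioned model fit
#'
#' Result of \code{\link{runPartitioned}}: per-region posterior draws
#' plus the data and settings needed to call DMCs.
#'
#' @slot counts the fitted \code{MethylCounts}.
#' @slot partition the \code{RegionPartition} used.
#' @slot results list of \code{PosteriorDraws}, one per region (NULL
#'   where a region failed).
#' @slot prior,config the settings used.
#' @export
setClass("MethylFit",
    representation(counts = "MethylCounts", partition = "RegionPartition",
                   results = "list", prior = "PriorSpec",
                   config = "ChainConfig"))

#' Ground truth of a simulated dataset
#'
#' @slot group1,group2 true methylation curves (length T, values in [0,1]).
#' @slot dmrs data.frame with columns \code{start}, \code{end} (1-based
#'   closed index ranges) and \code{effect}.
#' @slot dmc logical length-T true DMC label (TRUE exactly inside DMRs).
#' @export
setClass("SimTruth",
    representation(group1 = "numeric", group2 = "numeric",
                   dmrs = "data.frame", dmc = "logical"))

setValidity("SimTruth", function(object) {
    TT <- length(object@dmc)
    if (length(object@group1) != TT || length(object@group2) != TT)
        return("curve lengths must match the dmc label length")
    lab <- rep(FALSE, TT)
    if (nrow(object@dmrs))
        for (j in seq_len(nrow(object@dmrs)))
            lab[object@dmrs$start[j]:object@dmrs$end[j]] <- TRUE
    if (!identical(lab, object@dmc))
        return("dmc label must be TRUE exactly inside the DMR ranges")
    TRUE
})

#' Read-depth generator
#'
#' @slot kind one of \code{"nbinom"} (overdispersed, the default stand-in
#'   for resampled real coverage), \code{"uniform"}, \code{"poisson"},
#'   \code{"empirical"}.
#' @slot lo,hi uniform range bounds.
#' @slot lambda Poisson mean.
#' @slot mu,size negative-binomial mean and dispersion.
#' @slot table depth table resampled by the empirical kind.
#' @export
setClass("DepthModel",
    representation(kind = "character", lo = "numeric", hi = "numeric",
                   lambda = "numeric", mu = "numeric", size = "numeric",
                   table = "numeric"))

#' Per-CpG DMC calls from credible intervals
#'
#' For each CpG and each group contrast, the equal-tailed
#' \eqn{100(1-\alpha)\%} credible interval of the logit-scale contrast
#' curve, the DMC flag (interval excludes zero), and the direction
#' (hyper if the posterior mean contrast is positive, i.e. the first
#' named group is more methylated).  A CpG is an overall DMC if at least
#' one contrast flags it.
#'
#' @slot pos \code{GRanges} of the CpGs.
#' @slot contrasts contrast labels, \code{"<g>.vs.<g'>"}.
#' @slot alpha credible level used.
#' @slot estimate,lower,upper T x C matrices on the logit scale.
#' @slot dmc T x C logical flag matrix.
#' @slot direction T x C character matrix ("hyper"/"hypo", NA when not
#'   flagged).
#' @slot groupMeans T x G posterior mean methylation per group.
#' @export
setClass("DMCResult",
    representation(pos = "GRanges", contrasts = "character",
                   alpha = "numeric", estimate = "matrix", lower = "matrix",
                   upper = "matrix", dmc = "matrix", direction = "matrix",
                   groupMeans = "matrix"))
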