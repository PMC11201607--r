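#' Quasi-IRLS initialization of the chain
#'
#' Runs deterministic per-block penalized Newton sweeps (quasi-IRLS,
#' exploiting the block structure rather than forming the full stacked
#' design) to produce an approximate penalized-ML state that seeds the
#' Gibbs chain.  With all data missing the prior mode (all zeros) is
#' returned.
#'
#' @param counts a \linkS4class{MethylCounts}.
#' @param layout a \linkS4class{DesignLayout}.
#' @param prior a \linkS4class{PriorSpec}; its Gaussian scale penalizes
#'   the fit (so fully separated data still yield finite estimates).
#' @param sweeps number of full passes over the blocks.
#' @param theta optional starting vector (defaults to zero).
#' @return The stacked parameter vector at the approximate penalized ML.
#' @export
initializeState <- function(counts, layout, prior, sweeps = 25L,
                            theta = NULL) {
    if (is.null(theta)) theta <- rep(0, layout@npar)
    ins <- chainInputs(counts, layout)
    out <- .init_core(ins$y, ins$n, ins$Xg, ins$Xi, ins$grp, ins$Zc,
                      ins$useDepth, ins$dlog, theta,
                      blockTaus(layout, prior), ins$G,
                      as.integer(sweeps))
    as.vector(out$theta)
}

# shared marshalling of R objects into the compiled core
chainInputs <- function(counts, layout) {
    y <- unname(methReads(counts))
    n <- unname(totalReads(counts))
    grp <- as.integer(layout@groups)
    useDepth <- isTRUE(layout@depthCovariate)
    Zc <- layout@covariates
    if (ncol(Zc) == 0L) Zc <- matrix(0, length(grp), 0L)
    dlog <- if (useDepth) log(n + 1) else matrix(0, nrow(y), ncol(y))
    list(y = y, n = n, Xg = layout@basisGroup@matrix,
         Xi = layout@basisIndiv@matrix, grp = grp, Zc = unname(Zc),
         useDepth = useDepth, dlog = dlog, G = nlevels(layout@groups))
}

#' Run the block Gibbs chain on one region
#'
#' Fits the Bayesian functional regression on a single (partition-sized)
#' region: quasi-IRLS initialization, then \code{nIter} full sweeps over
#' the blocks in fixed order (\eqn{\gamma_0}, then \eqn{\delta_2..\delta_G},
#' then all \eqn{\upsilon_{g,i}}, then \eqn{\eta}), discarding
#' \code{burnin} and thinning.  The default \code{"gauss"} strategy
#' (exact update from the Gaussian approximation of each block
#' conditional) runs in compiled code; the Metropolis-Hastings
#' strategies use the R reference implementation and are intended for
#' small problems and cross-checks.
#'
#' @param counts a \linkS4class{MethylCounts} (one region).
#' @param layout a \linkS4class{DesignLayout}; built from \code{p},
#'   \code{depthCovariate} and \code{covariates} when NULL.
#' @param prior a \linkS4class{PriorSpec}; empirical-Bayes estimate when
#'   NULL.
#' @param config a \linkS4class{ChainConfig}.
#' @param p spline resolution used when \code{layout} is NULL.
#' @param depthCovariate,covariates design options used when
#'   \code{layout} is NULL.
#' @return A \linkS4class{PosteriorDraws}.
#' @examples
#' sim <- simulateExample1(T = 120, seed = 7)
#' cfg <- chainConfig(nIter = 300, burnin = 100, thin = 2, seed = 1)
#' dr <- runChain(sim$counts, p = 10, config = cfg)
#' dim(drawMatrix(dr))
#' @export
runChain <- function(counts, layout = NULL, prior = NULL,
                     config = chainConfig(), p = 30L,
                     depthCovariate = TRUE, covariates = character()) {
    if (is.null(layout)) {
        basis <- splineBasis(start(rowRanges(counts)), p)
        layout <- designLayout(basis, counts,
                               depthCovariate = depthCovariate,
                               covariates = covariates)
    }
    if (is.null(prior)) prior <- estimateTau(counts)
    validObject(config)
    if (config@strategy != "gauss")
        return(runChainR(counts, layout, prior, config))
    set.seed(config@seed)
    ins <- chainInputs(counts, layout)
    priorKind <- if (prior@kind == "inverse_gamma") 1L else 0L
    # the inverse-gamma variant resamples prior precisions every sweep,
    # so the cached curvature must be rebuilt every sweep too
    refresh <- if (priorKind == 1L) 1L else config@refreshEvery
    theta0 <- rep(0, layout@npar)
    out <- .chain_core(ins$y, ins$n, ins$Xg, ins$Xi, ins$grp, ins$Zc,
                       ins$useDepth, ins$dlog, theta0,
                       blockTaus(layout, prior),
                       priorKind, prior@a, prior@b, ins$G,
                       config@initSweeps, config@nIter, config@burnin,
                       config@thin, refresh, config@randomScan)
    new("PosteriorDraws", draws = out$draws, layout = layout,
        betaMean = out$beta_mean,
        groupCurves = array(out$group_curves,
                            dim = dim(out$group_curves)),
        logLik = as.vector(out$loglik), config = config)
}

#' @describeIn runChain the kept draw matrix (draws x parameters).
#' @param draws a \linkS4class{PosteriorDraws}.
#' @export
drawMatrix <- function(draws) draws@draws

#' @describeIn runChain T x G x nkeep array of logit-scale group curves
#'   \eqn{x(\gamma_0 + \delta_g)}.
#' @export
groupCurves <- function(draws) draws@groupCurves

setMethod("show", "PosteriorDraws", function(object) {
    cat(sprintf(
        "PosteriorDraws: %d kept draws of %d parameters (%d CpGs, %d groups)\n",
        nrow(object@draws), ncol(object@draws),
        dim(object@groupCurves)[1L], dim(object@groupCurves)[2L]))
})

# deterministic per-region seed derived from the master seed, so worker
# count never changes the output
partitionSeed <- function(master, k) {
    as.integer((as.numeric(master) * 48271 + k * 104729) %% 2147483629 + 1)
}

#' Fit the model region by region
#'
#' Partitions the CpG axis (default regions of 500 positions with a
#' resolution-30 basis), fits each region independently with
#' \code{\link{runChain}}, and concatenates the results by position.
#' Region seeds are derived deterministically from the master seed and
#' the region index, so results are identical for any \code{workers}
#' count.  A failing region is reported, skipped and recorded as a gap.
#'
#' @param counts a \linkS4class{MethylCounts}.
#' @param p spline resolution per region.
#' @param prior a \linkS4class{PriorSpec}; empirical-Bayes estimate from
#'   the whole object when NULL.
#' @param config a \linkS4class{ChainConfig}; its seed is the master
#'   seed.
#' @param partitionSize maximum region size.
#' @param workers parallel workers (forked; 1 = serial).
#' @param depthCovariate,covariates design options.
#' @param pIndiv optional coarser resolution for the individual-level
#'   blocks.
#' @return A \linkS4class{MethylFit}.
#' @seealso \code{\link{callDMCs}}, \code{\link{posteriorMeans}}
#' @export
runPartitioned <- function(counts, p = 30L, prior = NULL,
                           config = chainConfig(), partitionSize = 500L,
                           workers = 1L, depthCovariate = TRUE,
                           covariates = character(), pIndiv = NULL) {
    if (is.null(prior)) prior <- estimateTau(counts)
    part <- partitionRegions(nrow(counts), size = partitionSize,
                             resolution = p)
    fitOne <- function(k) {
        idx <- regionIndices(part, k)
        sub <- counts[idx, ]
        basis <- splineBasis(start(rowRanges(sub)), p)
        basisI <- if (is.null(pIndiv)) basis
                  else splineBasis(start(rowRanges(sub)), pIndiv)
        layout <- designLayout(basis, sub, depthCovariate = depthCovariate,
                               covariates = covariates,
                               basisIndiv = basisI)
        cfg <- config
        cfg@seed <- partitionSeed(config@seed, k)
        tryCatch(runChain(sub, layout, prior, cfg),
                 error = function(e) {
                     warning(sprintf("region %d (positions %d..%d) failed: %s",
                                     k, min(idx), max(idx),
                                     conditionMessage(e)))
                     NULL
                 })
    }
    ks <- seq_len(length(part@ranges))
    results <- if (workers > 1L)
        parallel::mclapply(ks, fitOne, mc.cores = workers)
    else lapply(ks, fitOne)
    new("MethylFit", counts = counts, partition = part,
        results = results, prior = prior, config = config)
}

setMethod("show", "MethylFit", function(object) {
    ok <- sum(!vapply(object@results, is.null, TRUE))
    cat(sprintf("MethylFit: %d/%d regions fitted, %d CpGs, %d samples\n",
                ok, length(object@results), nrow(object@counts),
                ncol(object@counts)))
    show(object@prior); show(object@config)
})

#' Posterior mean methylation levels per sample
#'
#' Assembles the per-region posterior means of \eqn{\beta^*_{t,g,i}}
#' into a T x M matrix (NA rows where a region failed).  Values at
#' missing entries are the model's imputation from the neighbouring
#' smooth fit.
#'
#' @param object a \linkS4class{MethylFit}.
#' @return T x M numeric matrix.
#' @export
setMethod("posteriorMeans", "MethylFit", function(object) {
    TT <- nrow(object@counts); M <- ncol(object@counts)
    out <- matrix(NA_real_, TT, M,
                  dimnames = list(NULL, colnames(object@counts)))
    for (k in seq_along(object@results)) {
        r <- object@results[[k]]
        if (!is.null(r)) out[regionIndices(object@partition, k), ] <- r@betaMean
    }
    out
})

# region-wise quantiles of the logit-scale group curves:
# returns T x G x length(probs)
groupCurveQuantiles <- function(fit, probs) {
    TT <- nrow(fit@counts)
    G <- nlevels(sampleGroups(fit@counts))
    out <- array(NA_real_, c(TT, G, length(probs)))
    for (k in seq_along(fit@results)) {
        r <- fit@results[[k]]
        if (is.null(r)) next
        idx <- regionIndices(fit@partition, k)
        for (g in seq_len(G)) {
            qs <- rowQuantiles(r@groupCurves[, g, , drop = FALSE], probs)
            out[idx, g, ] <- qs
        }
    }
    out
}

# row-wise quantiles of a T x 1 x nkeep slab
rowQuantiles <- function(slab, probs) {
    m <- matrix(slab, nrow = dim(slab)[1L])
    t(apply(m, 1L, quantile, probs = probs, names = FALSE,
            type = 7))
}
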