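# small in-code fixtures shared across test files

tinyCounts <- function(TT = 40L, M = 4L, depth = 20, beta = 0.5,
                       groups = rep(c("a", "b"), each = M / 2),
                       seed = 1L) {
    set.seed(seed)
    pos <- sort(sample.int(TT * 25L, TT))
    n <- matrix(depth, TT, M)
    y <- matrix(rbinom(TT * M, depth, beta), TT, M)
    MethylCounts(pos, y, n,
                 data.frame(group = groups,
                            row.names = paste0("s", seq_len(M))))
}

positionsOf <- function(counts)
    GenomicRanges::start(SummarizedExperiment::rowRanges(counts))

# hand-assembled MethylFit whose group-curve draws are fully controlled,
# for direct unit tests of the credible-interval DMC logic
manualFit <- function(curveDraws, counts, config = chainConfig(
                          nIter = 30, burnin = 10, thin = 1, seed = 1)) {
    TT <- nrow(counts)
    basis <- splineBasis(positionsOf(counts), p = 2)
    lay <- designLayout(basis, counts, depthCovariate = FALSE)
    nkeep <- dim(curveDraws)[3L]
    dr <- new("PosteriorDraws",
              draws = matrix(0, nkeep, lay@npar), layout = lay,
              betaMean = matrix(0.5, TT, ncol(counts)),
              groupCurves = curveDraws,
              logLik = numeric(nkeep), config = config)
    new("MethylFit", counts = counts,
        partition = partitionRegions(TT, size = max(TT, 60L),
                                     resolution = 2L),
        results = list(dr), prior = priorSpec(), config = config)
}
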