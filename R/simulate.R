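#' Read-depth generators
#'
#' Stand-ins for the observed coverage of real bisulfite experiments:
#' \code{"nbinom"} (negative binomial, mean ~30, overdispersed — the
#' default that mimics resampled real depth tables), \code{"uniform"}
#' (integer uniform on [lo, hi]), \code{"poisson"}, or
#' \code{"empirical"} (resample a supplied depth table).
#'
#' @param kind generator kind.
#' @param lo,hi uniform bounds (default 15, 45).
#' @param lambda Poisson mean (default 30).
#' @param mu,size negative-binomial mean and dispersion (default 30, 5).
#' @param table integer vector of depths to resample.
#' @return A \linkS4class{DepthModel}.
#' @examples
#' d <- depthModel("uniform", lo = 15, hi = 45)
#' range(drawDepths(d, 100, 2))
#' @export
depthModel <- function(kind = c("nbinom", "uniform", "poisson",
                                "empirical"),
                       lo = 15, hi = 45, lambda = 30, mu = 30, size = 5,
                       table = integer()) {
    kind <- match.arg(kind)
    if (kind == "empirical" && length(table) == 0L)
        stop("the empirical depth model needs a depth table")
    new("DepthModel", kind = kind, lo = lo, hi = hi, lambda = lambda,
        mu = mu, size = size, table = as.numeric(table))
}

#' @rdname depthModel
#' @param object a \code{DepthModel}.
#' @param nPos,nSamples matrix dimensions to draw.
#' @export
setMethod("drawDepths", "DepthModel", function(object, nPos, nSamples) {
    N <- nPos * nSamples
    d <- switch(object@kind,
        uniform = sample(seq.int(object@lo, object@hi), N, replace = TRUE),
        poisson = rpois(N, object@lambda),
        nbinom = rnbinom(N, mu = object@mu, size = object@size),
        empirical = sample(object@table, N, replace = TRUE))
    matrix(as.numeric(d), nPos, nSamples)
})

# CpG-like uneven genomic coordinates: small, overdispersed gaps
cpgPositions <- function(TT, meanGap = 20) {
    gaps <- 1 + rnbinom(TT - 1L, mu = meanGap - 1, size = 1)
    as.integer(cumsum(c(1, gaps)))
}

# smooth random curve in (lo, hi): cubic spline through random control
# heights, squashed through the logistic function
smoothCurve <- function(positions, nCtrl = 12L, lo = 0.05, hi = 0.95,
                        wiggle = 1.2) {
    ctrlx <- seq(min(positions), max(positions), length.out = nCtrl)
    ctrly <- cumsum(rnorm(nCtrl, 0, wiggle))
    ctrly <- ctrly - mean(ctrly)
    f <- spline(ctrlx, ctrly, xout = positions)$y
    lo + (hi - lo) * plogis(f)
}

# place disjoint index intervals of the given lengths with a minimum gap;
# lengths are capped so a region always fits the position axis
placeRegions <- function(TT, lens, minGap = 20L) {
    placed <- data.frame(start = integer(), end = integer())
    lens <- pmin(lens, max(1L, TT %/% 3L))
    for (len in lens) {
        ok <- FALSE
        for (try in seq_len(2000L)) {
            s <- sample.int(TT - len + 1L, 1L)
            e <- s + len - 1L
            if (!nrow(placed) ||
                all(e < placed$start - minGap | s > placed$end + minGap)) {
                placed <- rbind(placed, data.frame(start = s, end = e))
                ok <- TRUE
                break
            }
        }
        if (!ok) break  # region space exhausted; stop adding
    }
    placed[order(placed$start), , drop = FALSE]
}

# flip the effect sign when it would push the (region-mean) curve
# against the [0,1] boundary, then clip
applyEffect <- function(base, dmrs) {
    out <- base
    if (!nrow(dmrs)) return(list(curve = out, dmrs = dmrs))
    for (j in seq_len(nrow(dmrs))) {
        idx <- dmrs$start[j]:dmrs$end[j]
        eff <- dmrs$effect[j]
        m <- mean(base[idx])
        if (m + eff > 0.98 || m + eff < 0.02) eff <- -eff
        dmrs$effect[j] <- eff
        out[idx] <- pmin(pmax(base[idx] + eff, 0), 1)
    }
    list(curve = out, dmrs = dmrs)
}

makeTruth <- function(g1, g2, dmrs) {
    TT <- length(g1)
    dmc <- rep(FALSE, TT)
    if (nrow(dmrs))
        for (j in seq_len(nrow(dmrs))) dmc[dmrs$start[j]:dmrs$end[j]] <- TRUE
    new("SimTruth", group1 = g1, group2 = g2,
        dmrs = dmrs[, c("start", "end", "effect"), drop = FALSE],
        dmc = dmc)
}

assembleCounts <- function(positions, beta, depth, groupOf) {
    y <- floor(beta * depth)
    sd <- data.frame(group = groupOf,
                     row.names = paste0(groupOf, "_",
                                        ave(seq_along(groupOf), groupOf,
                                            FUN = seq_along)))
    MethylCounts(positions, y, depth, sd)
}

#' Smooth-baseline simulation with additive Gaussian site noise
#'
#' Emulates WGBS-derived two-group data: a smooth baseline methylation
#' curve g1; a second-group curve g2 obtained by adding region effects
#' inside DMRs (clipped to [0,1]); per sample and site,
#' \eqn{N(0, \sigma)} noise (default \eqn{\sigma = 0.18}) added and
#' truncated to [0,1]; counts are the integer part of level x depth.
#' Default group sizes are 8 vs 13 samples.  The default DMR layout
#' draws lengths uniformly in [50, 300] with alternating effects of
#' magnitude 0.1 and 0.2 until about \code{dmrCoverage} of the positions
#' are covered.
#'
#' The full-scale version of this design derives g1 by lowess on real
#' aggregated WGBS counts; here a parameterized smooth random curve
#' stands in, preserving the statistical structure (smooth baseline,
#' additive region effects, truncated Gaussian noise, floor-count
#' discretization).
#'
#' @param T number of CpGs.
#' @param nGroup1,nGroup2 samples per group.
#' @param dmrSpec optional data.frame with columns \code{start},
#'   \code{end}, \code{effect} (1-based index ranges); NULL = default
#'   layout.
#' @param noiseSd site-noise standard deviation.
#' @param depth a \linkS4class{DepthModel}.
#' @param dmrCoverage target fraction of positions inside DMRs for the
#'   default layout.
#' @param seed RNG seed.
#' @return list with \code{counts} (\linkS4class{MethylCounts}) and
#'   \code{truth} (\linkS4class{SimTruth}).
#' @export
simulateExample1 <- function(T = 3000L, nGroup1 = 8L, nGroup2 = 13L,
                             dmrSpec = NULL, noiseSd = 0.18,
                             depth = depthModel("nbinom"),
                             dmrCoverage = 0.2, seed = 1L) {
    set.seed(seed)
    TT <- as.integer(T)
    positions <- cpgPositions(TT)
    g1 <- smoothCurve(positions)
    if (is.null(dmrSpec)) {
        lens <- integer(); effs <- numeric()
        magn <- c(0.1, 0.2)
        lenHi <- min(300L, max(10L, TT %/% 3L))
        lenLo <- min(50L, lenHi)
        while (sum(lens) < dmrCoverage * TT) {
            lens <- c(lens, sample(lenLo:lenHi, 1L))
            k <- length(lens)
            effs <- c(effs, magn[(k - 1L) %% 2L + 1L] *
                            (if (k %% 2L) 1 else -1))
        }
        dmrSpec <- placeRegions(TT, lens)
        dmrSpec$effect <- effs[seq_len(nrow(dmrSpec))]
    }
    ae <- applyEffect(g1, dmrSpec)
    g2 <- ae$curve
    M <- nGroup1 + nGroup2
    groupOf <- rep(c("g1", "g2"), c(nGroup1, nGroup2))
    n <- drawDepths(depth, TT, M)
    beta <- vapply(seq_len(M), function(i) {
        g <- if (groupOf[i] == "g1") g1 else g2
        pmin(pmax(g + rnorm(TT, 0, noiseSd), 0), 1)
    }, numeric(TT))
    list(counts = assembleCounts(positions, beta, n, groupOf),
         truth = makeTruth(g1, g2, ae$dmrs))
}

#' DMR-cluster simulation with binomial reads given coverage
#'
#' Two groups of equal size; DMRs are clusters of neighbouring CpGs at
#' random locations; group-2 binomial probabilities equal the baseline
#' proportions plus or minus an effect size drawn uniformly from
#' \code{effectRange} (small to moderate, ~0.1-0.5), clipped to [0,1];
#' reads are binomial given the synthetic coverage.
#'
#' @param T number of CpGs (default 5000).
#' @param nPerGroup samples per group (default 10).
#' @param nDmrs number of DMRs (default 50).
#' @param effectRange uniform effect-size range.
#' @param lenRange DMR length range in CpGs.
#' @param depth a \linkS4class{DepthModel}.
#' @param seed RNG seed.
#' @return list with \code{counts} and \code{truth}.
#' @export
simulateExample2 <- function(T = 5000L, nPerGroup = 10L, nDmrs = 50L,
                             effectRange = c(0.1, 0.5),
                             lenRange = c(10L, 40L),
                             depth = depthModel("nbinom"), seed = 1L) {
    set.seed(seed)
    TT <- as.integer(T)
    positions <- cpgPositions(TT)
    base <- smoothCurve(positions, nCtrl = 25L)
    dmrs <- data.frame(start = integer(), end = integer(),
                       effect = numeric())
    if (nDmrs > 0L) {
        lens <- sample(seq.int(lenRange[1L], lenRange[2L]), nDmrs,
                       replace = TRUE)
        dmrs <- placeRegions(TT, lens)
        dmrs$effect <- runif(nrow(dmrs), effectRange[1L],
                             effectRange[2L]) *
                       sample(c(-1, 1), nrow(dmrs), replace = TRUE)
    }
    ae <- applyEffect(base, dmrs)
    g2 <- ae$curve
    M <- 2L * nPerGroup
    groupOf <- rep(c("g1", "g2"), each = nPerGroup)
    n <- drawDepths(depth, TT, M)
    beta <- vapply(seq_len(M), function(i)
        if (groupOf[i] == "g1") base else g2, numeric(TT))
    y <- matrix(rbinom(TT * M, size = as.integer(n), prob = beta), TT, M)
    sd <- data.frame(group = groupOf,
                     row.names = paste0(groupOf, "_",
                                        rep(seq_len(nPerGroup), 2L)))
    list(counts = MethylCounts(positions, y, n, sd),
         truth = makeTruth(base, g2, ae$dmrs))
}

#' Hidden-Markov baseline simulation
#'
#' The baseline methylation path follows a sticky 8-state Markov chain
#' with states spread evenly over [0,1] and binomial emissions; group 2
#' adds fixed methylation differences inside a few random regions.
#' Default read depths are integer-uniform on [15, 45].
#'
#' @param T number of CpGs (default 5000).
#' @param nPerGroup samples per group (default 10).
#' @param nDmrs number of DMRs (default 4).
#' @param sizeRange DMR size range (default [100, 300]).
#' @param effects per-DMR methylation differences (default
#'   \code{c(0.2, -0.2, 0.3, -0.3)}, recycled).
#' @param depth a \linkS4class{DepthModel} (default uniform [15, 45]).
#' @param selfTrans self-transition probability of the sticky chain
#'   (remaining mass spread uniformly; 1 gives a constant baseline).
#' @param seed RNG seed.
#' @return list with \code{counts} and \code{truth}.
#' @export
simulateExample3 <- function(T = 5000L, nPerGroup = 10L, nDmrs = 4L,
                             sizeRange = c(100L, 300L),
                             effects = c(0.2, -0.2, 0.3, -0.3),
                             depth = depthModel("uniform", lo = 15,
                                                hi = 45),
                             selfTrans = 0.98, seed = 1L) {
    set.seed(seed)
    TT <- as.integer(T)
    positions <- cpgPositions(TT)
    states <- (2 * seq_len(8L) - 1) / 16   # 8 states spread over [0,1]
    path <- integer(TT)
    path[1L] <- sample.int(8L, 1L)
    for (t in seq_len(TT)[-1L])
        path[t] <- if (runif(1) < selfTrans) path[t - 1L]
                   else sample(seq_len(8L)[-path[t - 1L]], 1L)
    g1 <- states[path]
    dmrs <- data.frame(start = integer(), end = integer(),
                       effect = numeric())
    if (nDmrs > 0L) {
        lens <- sample(seq.int(sizeRange[1L], sizeRange[2L]), nDmrs,
                       replace = TRUE)
        dmrs <- placeRegions(TT, lens)
        dmrs$effect <- rep_len(effects, nrow(dmrs))
    }
    g2 <- g1
    if (nrow(dmrs))
        for (j in seq_len(nrow(dmrs))) {
            idx <- dmrs$start[j]:dmrs$end[j]
            g2[idx] <- pmin(pmax(g1[idx] + dmrs$effect[j], 0), 1)
        }
    M <- 2L * nPerGroup
    groupOf <- rep(c("g1", "g2"), each = nPerGroup)
    n <- drawDepths(depth, TT, M)
    beta <- vapply(seq_len(M), function(i)
        if (groupOf[i] == "g1") g1 else g2, numeric(TT))
    y <- matrix(rbinom(TT * M, size = as.integer(n), prob = beta), TT, M)
    sd <- data.frame(group = groupOf,
                     row.names = paste0(groupOf, "_",
                                        rep(seq_len(nPerGroup), 2L)))
    list(counts = MethylCounts(positions, y, n, sd),
         truth = makeTruth(g1, g2, dmrs))
}

# stationary AR(1) series with innovation sd sigma
arNoise <- function(TT, phi, sigma) {
    e <- rnorm(TT, 0, sigma)
    x <- numeric(TT)
    x[1L] <- rnorm(1L, 0, sigma / sqrt(1 - phi^2))
    for (t in seq_len(TT)[-1L]) x[t] <- phi * x[t - 1L] + e[t]
    x
}

#' Bump-hunting style simulation with AR(1) noise and outliers
#'
#' Logit-scale methylation surfaces: a smooth baseline plus per-sample
#' AR(1) noise (default \eqn{\phi = 0.21}, innovation sd 0.2) and
#' heavy-tailed \eqn{t_5} outliers; group 2 carries bumps (plateaus with
#' cosine-tapered edges, the taper covering \code{bumpParam} of each
#' flank) of random size, sign and height on the methylation scale.
#' Converted to counts through the depth model.  Default group sizes
#' are 8 vs 13.
#'
#' @param nBumps number of bumps (default 10).
#' @param groupSizes samples per group (default \code{c(8, 13)}).
#' @param T number of CpGs (default 5000).
#' @param bumpParam edge-taper fraction of each bump flank.
#' @param ar \code{c(phi, sigma)} AR(1) parameters (default 0.21, 0.2).
#' @param outlierDf degrees of freedom of the outlier t distribution.
#' @param outlierProb per-site outlier probability.
#' @param heightRange bump height range on the methylation scale.
#' @param lenRange bump length range in CpGs.
#' @param depth a \linkS4class{DepthModel}.
#' @param seed RNG seed.
#' @return list with \code{counts} and \code{truth}.
#' @export
simulateExample4 <- function(nBumps = 10L, groupSizes = c(8L, 13L),
                             T = 5000L, bumpParam = 0.3,
                             ar = c(0.21, 0.2), outlierDf = 5,
                             outlierProb = 0.01,
                             heightRange = c(0.1, 0.5),
                             lenRange = c(30L, 150L),
                             depth = depthModel("nbinom"), seed = 1L) {
    set.seed(seed)
    TT <- as.integer(T)
    positions <- cpgPositions(TT)
    mu <- qlogis(smoothCurve(positions, nCtrl = 15L, lo = 0.15,
                             hi = 0.85))
    dmrs <- data.frame(start = integer(), end = integer(),
                       effect = numeric())
    bump <- numeric(TT)
    if (nBumps > 0L) {
        lens <- sample(seq.int(lenRange[1L], lenRange[2L]), nBumps,
                       replace = TRUE)
        dmrs <- placeRegions(TT, lens)
        dmrs$effect <- runif(nrow(dmrs), heightRange[1L],
                             heightRange[2L]) *
                       sample(c(-1, 1), nrow(dmrs), replace = TRUE)
        for (j in seq_len(nrow(dmrs))) {
            idx <- dmrs$start[j]:dmrs$end[j]
            L <- length(idx)
            taper <- max(1L, round(bumpParam * L))
            prof <- rep(1, L)
            ramp <- (1 - cos(pi * seq_len(taper) / (taper + 1))) / 2
            prof[seq_len(taper)] <- ramp
            prof[L + 1L - seq_len(taper)] <- ramp
            bump[idx] <- dmrs$effect[j] * prof
        }
    }
    M <- sum(groupSizes)
    groupOf <- rep(c("g1", "g2"), groupSizes)
    n <- drawDepths(depth, TT, M)
    beta <- vapply(seq_len(M), function(i) {
        noise <- arNoise(TT, ar[1L], ar[2L])
        out <- runif(TT) < outlierProb
        noise[out] <- noise[out] + ar[2L] * rt(sum(out), df = outlierDf)
        b <- plogis(mu + noise)
        if (groupOf[i] == "g2") b <- pmin(pmax(b + bump, 0), 1)
        b
    }, numeric(TT))
    y <- matrix(rbinom(TT * M, size = as.integer(n), prob = beta), TT, M)
    g1c <- plogis(mu)
    g2c <- pmin(pmax(g1c + bump, 0), 1)
    sd <- data.frame(group = groupOf,
                     row.names = paste0(groupOf, "_",
                                        ave(seq_along(groupOf), groupOf,
                                            FUN = seq_along)))
    list(counts = MethylCounts(positions, y, n, sd),
         truth = makeTruth(g1c, g2c, dmrs))
}

#' Mask observed entries at random
#'
#' Sets the given fraction of observed entries to \eqn{y = 0, n = 0}
#' (the missing-data convention), e.g. to emulate the high missingness
#' of RRBS data or to score imputation.
#'
#' @param counts a \linkS4class{MethylCounts}.
#' @param fraction fraction of observed entries to mask, in [0, 1).
#' @param seed RNG seed.
#' @return list with \code{counts} (masked) and \code{maskedCells}
#'   (2-column index matrix of the masked entries).
#' @export
maskAtRandom <- function(counts, fraction, seed = 1L) {
    if (fraction < 0 || fraction >= 1)
        stop("fraction must be in [0, 1)")
    set.seed(seed)
    y <- methReads(counts); n <- totalReads(counts)
    obs <- which(n > 0)
    take <- sample(obs, round(fraction * length(obs)))
    y[take] <- 0; n[take] <- 0
    out <- MethylCounts(start(rowRanges(counts)), y, n,
                        as.data.frame(colData(counts)),
                        chrom = as.character(seqnames(counts)@values[1L]))
    list(counts = out,
         maskedCells = arrayInd(take, dim(y)))
}
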