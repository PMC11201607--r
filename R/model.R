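#' Binomial functional-regression log-likelihood
#'
#' Evaluates
#' \deqn{\ell(\Psi) = \sum_{g,i,t} y_{t,g,i}\,lp_{t,g,i}
#'   - n_{t,g,i}\log(1+e^{lp_{t,g,i}})}
#' where \eqn{lp} is the logit-scale linear predictor.  The binomial
#' normalizing constant \eqn{\log{n \choose y}} is omitted (it does not
#' depend on parameters).  Missing entries (\eqn{y=0, n=0}) contribute
#' exactly zero.  \eqn{\log(1+e^x)} is computed with the stable
#' \code{log1p} formulation and linear predictors are clipped to
#' \eqn{\pm 35} before exponentiation.
#'
#' @param theta stacked parameter vector.
#' @param counts a \linkS4class{MethylCounts}.
#' @param layout a \linkS4class{DesignLayout}.
#' @return A finite scalar.
#' @export
logLikelihood <- function(theta, counts, layout) {
    if (length(theta) != layout@npar)
        stop(sprintf("theta has length %d but the layout has %d parameters",
                     length(theta), layout@npar))
    lp <- linearPredictor(theta, layout, counts)
    y <- methReads(counts); n <- totalReads(counts)
    lp <- pmin(pmax(lp, -35), 35)
    sum(y * lp - n * log1pexp(lp))
}

# numerically stable log(1 + exp(x))
log1pexp <- function(x) {
    out <- x
    lo <- x <= 18
    out[lo] <- log1p(exp(x[lo]))
    hi <- x > 18 & x <= 33.3
    out[hi] <- x[hi] + exp(-x[hi])
    out
}

#' Gaussian or inverse-gamma prior specification
#'
#' @param kind \code{"common_gaussian"} (one prior sd \code{tau} for the
#'   deviation blocks) or \code{"inverse_gamma"} (per-block variances
#'   with an InverseGamma(a, b) hyperprior, resampled within the chain).
#' @param tau positive prior standard deviation for the group-contrast,
#'   individual and covariate blocks.
#' @param tauBaseline weakly-informative prior standard deviation for
#'   the baseline block \eqn{\gamma_0} (logit scale).  \code{tau}
#'   estimates across-sample variation and is far too tight for the
#'   baseline level itself: shrinking \eqn{\gamma_0} leaves a baseline
#'   misfit that the \eqn{\delta_g} blocks of the non-baseline groups
#'   can absorb more cheaply than the baseline group's individual
#'   blocks, which manifests as spurious group contrasts.
#' @param a,b positive inverse-gamma hyperparameters.
#' @return A \linkS4class{PriorSpec}.
#' @export
priorSpec <- function(kind = c("common_gaussian", "inverse_gamma"),
                      tau = 0.18, tauBaseline = 10, a = 2, b = 0.05) {
    kind <- match.arg(kind)
    new("PriorSpec", kind = kind, tau = as.numeric(tau),
        tauBaseline = as.numeric(tauBaseline),
        a = as.numeric(a), b = as.numeric(b))
}

# per-block prior standard deviations, in layout block order
blockTaus <- function(layout, prior) {
    vapply(layout@blocks, function(b)
        if (b$type == "gamma0") prior@tauBaseline else prior@tau, 0)
}

setMethod("show", "PriorSpec", function(object) {
    if (object@kind == "common_gaussian")
        cat(sprintf("PriorSpec: common Gaussian, tau = %.4g\n", object@tau))
    else
        cat(sprintf(
            "PriorSpec: per-block Gaussian, tau^2 ~ InvGamma(%.3g, %.3g)\n",
            object@a, object@b))
})

#' Empirical-Bayes prior scale from the data
#'
#' Estimates the common prior standard deviation as the average (over
#' CpGs with at least two observed samples) of the across-sample
#' standard deviation of the raw methylation fractions \eqn{y/n},
#' floored at a small positive constant.  On typical WGBS data this
#' yields values near 0.18; on RRBS-like data near 0.12.
#'
#' @param counts a \linkS4class{MethylCounts}.
#' @param floor lower bound for the estimate.
#' @return A \code{"common_gaussian"} \linkS4class{PriorSpec}.
#' @export
estimateTau <- function(counts, floor = 0.01) {
    f <- rawFractions(counts)
    nobs <- rowSums(!is.na(f))
    if (all(nobs == 0)) stop("all entries are missing")
    keep <- nobs >= 2L
    if (!any(keep))
        stop("no CpG has two or more observed samples")
    sds <- apply(f[keep, , drop = FALSE], 1L, sd, na.rm = TRUE)
    tau <- mean(sds, na.rm = TRUE)
    if (!is.finite(tau)) tau <- floor
    priorSpec("common_gaussian", tau = max(tau, floor))
}

#' Empirical inverse-gamma hyperparameters
#'
#' Fits (a, b) of the inverse-gamma hyperprior on per-block prior
#' variances by moment-matching the squared coefficient scales of the
#' quasi-IRLS initializer's blocks: with sample mean m and variance v of
#' the per-block mean-square coefficients, a = m^2/v + 2 and
#' b = m (a - 1).
#'
#' @param counts a \linkS4class{MethylCounts}.
#' @param layout a \linkS4class{DesignLayout}.
#' @param tau0 Gaussian scale used for the initializer run.
#' @return An \code{"inverse_gamma"} \linkS4class{PriorSpec}.
#' @export
estimateInvGamma <- function(counts, layout, tau0 = NULL) {
    if (is.null(tau0)) tau0 <- estimateTau(counts)@tau
    st <- initializeState(counts, layout, priorSpec(tau = tau0))
    s2 <- vapply(layout@blocks, function(b) mean(st[b$cols]^2), 0)
    s2 <- pmax(s2, 1e-6)
    m <- mean(s2); v <- var(s2)
    if (!is.finite(v) || v <= 0) v <- m^2
    a <- m^2 / v + 2
    b <- m * (a - 1)
    priorSpec("inverse_gamma", tau = sqrt(m), a = a, b = b)
}

#' MCMC chain configuration constructor
#'
#' Defaults follow the simulation profile (15,000 iterations, 5000
#' burn-in, thin 10, i.e. 1000 kept draws); \code{profile = "real"}
#' selects the heavier real-data profile (60,000 / 10,000 / 10).
#'
#' @param nIter,burnin,thin,seed chain arithmetic and RNG seed.
#' @param strategy \code{"gauss"} (Gaussian-approximation block update,
#'   the default), \code{"mh1"} or \code{"mhN"} (random-walk
#'   Metropolis-Hastings inner steps).
#' @param mhInnerSteps inner steps for \code{"mhN"}.
#' @param initSweeps quasi-IRLS sweeps used to seed the chain.
#' @param refreshEvery sweeps between block-curvature refreshes.
#' @param randomScan update blocks in random order each sweep.
#' @param profile \code{"simulation"} or \code{"real"}; sets
#'   \code{nIter}/\code{burnin}/\code{thin} when they are missing.
#' @return A \linkS4class{ChainConfig}.
#' @export
chainConfig <- function(nIter = NULL, burnin = NULL, thin = NULL,
                        seed = 1L,
                        strategy = c("gauss", "mh1", "mhN"),
                        mhInnerSteps = 5L, initSweeps = 25L,
                        refreshEvery = 5L, randomScan = FALSE,
                        profile = c("simulation", "real")) {
    profile <- match.arg(profile)
    def <- if (profile == "simulation") c(15000L, 5000L, 10L)
           else c(60000L, 10000L, 10L)
    if (is.null(nIter)) nIter <- def[1L]
    if (is.null(burnin)) burnin <- def[2L]
    if (is.null(thin)) thin <- def[3L]
    new("ChainConfig", nIter = as.integer(nIter),
        burnin = as.integer(burnin), thin = as.integer(thin),
        seed = as.integer(seed), strategy = match.arg(strategy),
        mhInnerSteps = as.integer(mhInnerSteps),
        initSweeps = as.integer(initSweeps),
        refreshEvery = as.integer(refreshEvery),
        randomScan = isTRUE(randomScan))
}

setMethod("show", "ChainConfig", function(object) {
    cat(sprintf(
        "ChainConfig: %d iter, %d burn-in, thin %d -> %d kept (%s, seed %d)\n",
        object@nIter, object@burnin, object@thin,
        (object@nIter - object@burnin) %/% object@thin,
        object@strategy, object@seed))
})

#' Number of kept draws implied by a configuration
#' @param config a \linkS4class{ChainConfig}.
#' @return Integer.
#' @export
keptDraws <- function(config) (config@nIter - config@burnin) %/% config@thin
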