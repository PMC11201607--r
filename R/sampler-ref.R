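# R-level reference implementation of the block updates.  The production
# chain runs in compiled code (see runChain); these functions exist as an
# independent, readable route used for small problems, the MH update
# strategies, and cross-checks.

getBlock <- function(layout, block) {
    if (is.character(block)) {
        if (!block %in% names(layout@blocks))
            stop(sprintf("unknown block '%s'", block))
        layout@blocks[[block]]
    } else layout@blocks[[block]]
}

# per-sample T x pb design matrices of a block
blockDesignList <- function(layout, counts, b) {
    switch(b$type,
        gamma0 = ,
        delta = rep(list(layout@basisGroup@matrix), length(b$samples)),
        upsilon = list(layout@basisIndiv@matrix),
        eta = lapply(b$samples, function(i) etaDesign(layout, counts, i)))
}

# block-conditional log-posterior (up to a constant), given fixed lp of
# the other blocks
blockLogPost <- function(thb, b, Xlist, yS, nS, lpOther, tau2) {
    val <- -sum(thb^2) / (2 * tau2)
    for (k in seq_along(Xlist)) {
        lp <- pmin(pmax(lpOther[, k] + Xlist[[k]] %*% thb, -35), 35)
        val <- val + sum(yS[, k] * lp - nS[, k] * log1pexp(lp))
    }
    val
}

#' Gaussian approximation to a block full conditional
#'
#' Runs penalized IRLS to convergence on the block's conditional
#' logistic model (offset = contribution of all other blocks) and
#' returns the conditional mode together with the penalized curvature
#' \eqn{A = \sum_i X_i' W_i X_i + I/\tau^2} (Fisher weights
#' \eqn{W = diag(n\,\hat\beta(1-\hat\beta))}) and its upper Cholesky
#' factor, so a draw is \code{mean + backsolve(cholFactor, z)}.
#'
#' @param block block name (see \code{names(layout@blocks)}) or index.
#' @param theta current stacked parameter vector.
#' @param counts,layout data and design.
#' @param prior a \linkS4class{PriorSpec} (common Gaussian scale used).
#' @param maxit,tol IRLS iteration control.
#' @return list with \code{mean}, \code{precision}, \code{cholFactor}.
#' @export
gaussianApproxConditional <- function(block, theta, counts, layout, prior,
                                      maxit = 50L, tol = 1e-10) {
    b <- getBlock(layout, block)
    tau2 <- (if (b$type == "gamma0") prior@tauBaseline else prior@tau)^2
    pb <- length(b$cols)
    Xlist <- blockDesignList(layout, counts, b)
    y <- methReads(counts); n <- totalReads(counts)
    yS <- y[, b$samples, drop = FALSE]
    nS <- n[, b$samples, drop = FALSE]
    thetaOff <- theta; thetaOff[b$cols] <- 0
    lpOtherFull <- linearPredictor(thetaOff, layout, counts)
    lpOther <- lpOtherFull[, b$samples, drop = FALSE]
    thb <- theta[b$cols]
    A <- NULL
    for (iter in seq_len(maxit)) {
        g <- -thb / tau2
        A <- diag(1 / tau2, pb)
        for (k in seq_along(Xlist)) {
            lp <- pmin(pmax(lpOther[, k] + Xlist[[k]] %*% thb, -35), 35)
            mu <- plogis(as.vector(lp))
            mu <- pmin(pmax(mu, 1e-9), 1 - 1e-9)
            g <- g + crossprod(Xlist[[k]], yS[, k] - nS[, k] * mu)
            w <- nS[, k] * mu * (1 - mu)
            A <- A + crossprod(Xlist[[k]] * w, Xlist[[k]])
        }
        d <- solve(A, g)
        thb <- thb + as.vector(d)
        if (max(abs(d)) < tol) break
    }
    list(mean = as.vector(thb), precision = A, cholFactor = chol(A))
}

#' Redraw one block of the chain (reference implementation)
#'
#' Draws the named block from its Gaussian-approximation full
#' conditional (or via random-walk Metropolis-Hastings inner steps),
#' leaving all other blocks unchanged.
#'
#' @inheritParams gaussianApproxConditional
#' @param strategy \code{"gauss"}, \code{"mh1"} or \code{"mhN"}.
#' @param mhInnerSteps inner steps for \code{"mhN"}.
#' @return The updated stacked parameter vector.
#' @export
gibbsSweep <- function(theta, block, counts, layout, prior,
                       strategy = "gauss", mhInnerSteps = 5L) {
    b <- getBlock(layout, block)
    if (strategy == "gauss") {
        cond <- gaussianApproxConditional(block, theta, counts, layout, prior)
        z <- rnorm(length(b$cols))
        theta[b$cols] <- cond$mean + backsolve(cond$cholFactor, z)
        return(theta)
    }
    # random-walk MH with proposal covariance (2.38^2/p) * A^{-1}
    steps <- if (strategy == "mh1") 1L else as.integer(mhInnerSteps)
    cond <- gaussianApproxConditional(block, theta, counts, layout, prior)
    scl <- 2.38 / sqrt(length(b$cols))
    Xlist <- blockDesignList(layout, counts, b)
    y <- methReads(counts); n <- totalReads(counts)
    yS <- y[, b$samples, drop = FALSE]
    nS <- n[, b$samples, drop = FALSE]
    thetaOff <- theta; thetaOff[b$cols] <- 0
    lpOther <- linearPredictor(thetaOff, layout, counts)[, b$samples,
                                                         drop = FALSE]
    tau2 <- (if (b$type == "gamma0") prior@tauBaseline else prior@tau)^2
    thb <- theta[b$cols]
    f <- blockLogPost(thb, b, Xlist, yS, nS, lpOther, tau2)
    for (s in seq_len(steps)) {
        prop <- thb + scl * backsolve(cond$cholFactor,
                                      rnorm(length(b$cols)))
        fp <- blockLogPost(prop, b, Xlist, yS, nS, lpOther, tau2)
        if (log(runif(1)) < fp - f) { thb <- prop; f <- fp }
    }
    theta[b$cols] <- thb
    theta
}

# Gibbs recentering along the likelihood-invariant directions
# delta_g + c / upsilon_{g,i} - c and gamma0 + c / upsilon - c (see the
# compiled core for the rationale); requires a common resolution.
recenterTheta <- function(theta, layout, prior) {
    p <- layout@basisGroup@p
    if (layout@basisIndiv@p != p) return(theta)
    tau2 <- prior@tau^2
    ups <- Filter(function(b) b$type == "upsilon", layout@blocks)
    for (b in layout@blocks) {
        if (!b$type %in% c("delta", "gamma0")) next
        tau2b <- (if (b$type == "gamma0") prior@tauBaseline else prior@tau)^2
        mates <- Filter(function(u) all(u$samples %in% b$samples), ups)
        prec <- 1 / tau2b + length(mates) / tau2
        num <- -theta[b$cols] / tau2b
        for (u in mates) num <- num + theta[u$cols] / tau2
        cc <- num / prec + rnorm(p) / sqrt(prec)
        theta[b$cols] <- theta[b$cols] + cc
        for (u in mates) theta[u$cols] <- theta[u$cols] - cc
    }
    theta
}

# Full R-level chain; used for the MH strategies and tiny-model checks.
runChainR <- function(counts, layout, prior, config) {
    set.seed(config@seed)
    theta <- rep(0, layout@npar)
    theta <- initializeState(counts, layout, prior,
                             sweeps = config@initSweeps, theta = theta)
    nkeep <- keptDraws(config)
    draws <- matrix(NA_real_, nkeep, layout@npar)
    TT <- nrow(counts); G <- nlevels(layout@groups)
    M <- length(layout@groups)
    groupCurves <- array(NA_real_, c(TT, G, nkeep))
    betaMean <- matrix(0, TT, M)
    ll <- numeric(nkeep)
    Xg <- layout@basisGroup@matrix
    kept <- 0L
    blockNames <- names(layout@blocks)
    for (it in seq_len(config@nIter)) {
        ord <- if (config@randomScan) sample(blockNames) else blockNames
        for (nm in ord)
            theta <- gibbsSweep(theta, nm, counts, layout, prior,
                                strategy = config@strategy,
                                mhInnerSteps = config@mhInnerSteps)
        theta <- recenterTheta(theta, layout, prior)
        if (it > config@burnin &&
            (it - config@burnin) %% config@thin == 0L) {
            kept <- kept + 1L
            draws[kept, ] <- theta
            base <- as.vector(Xg %*% theta[layout@blocks[["gamma0"]]$cols])
            groupCurves[, 1L, kept] <- base
            for (b in layout@blocks)
                if (b$type == "delta")
                    groupCurves[, b$group, kept] <-
                        base + as.vector(Xg %*% theta[b$cols])
            betaMean <- betaMean + fittedBeta(theta, layout, counts)
            ll[kept] <- logLikelihood(theta, counts, layout)
        }
    }
    betaMean <- betaMean / max(kept, 1L)
    new("PosteriorDraws", draws = draws, layout = layout,
        betaMean = betaMean, groupCurves = groupCurves, logLik = ll,
        config = config)
}
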