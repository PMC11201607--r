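#' Assemble the block design layout
#'
#' Lays out the stacked parameter vector of the functional logistic
#' model
#' \deqn{logit(\beta_{t,g,i}) = x_t(\gamma_0 + \delta_g + \upsilon_{g,i})
#'   + \eta_1 \log(n_{t,g,i}+1) + z_{g,i}\eta}
#' with the identifiability constraint \eqn{\delta_1 \equiv 0} (group
#' level 1, the baseline, has no contrast block).  Total column count is
#' \eqn{(G+M)p - p + q}.  Sample covariates are standardized (mean 0,
#' sd 1) for sampler conditioning; coefficients can be back-transformed
#' with the stored center/scale.
#'
#' @param basis \linkS4class{SplineBasis} for the baseline and group
#'   blocks.
#' @param sampleData data.frame/DataFrame with a \code{group} column, or
#'   a \linkS4class{MethylCounts} (its colData is used).
#' @param depthCovariate include the per-entry \eqn{\log(n+1)} read-depth
#'   covariate column.
#' @param covariates names of numeric sample covariate columns to
#'   include.
#' @param basisIndiv optional coarser basis for the individual-level
#'   blocks (multi-resolution); defaults to \code{basis}.
#' @return A \linkS4class{DesignLayout}.
#' @export
designLayout <- function(basis, sampleData, depthCovariate = TRUE,
                         covariates = character(), basisIndiv = basis) {
    if (is(sampleData, "MethylCounts")) sampleData <- colData(sampleData)
    groups <- factor(sampleData$group)
    M <- length(groups)
    ids <- rownames(sampleData)
    if (is.null(ids)) ids <- paste0("s", seq_len(M))
    G <- nlevels(groups)
    p <- basis@p; pI <- basisIndiv@p
    Z <- matrix(0, M, 0)
    ctr <- numeric(0); scl <- numeric(0)
    for (cv in covariates) {
        if (!cv %in% colnames(sampleData))
            stop(sprintf("unknown covariate '%s'", cv))
        v <- as.numeric(sampleData[[cv]])
        m <- mean(v); s <- sd(v)
        if (!is.finite(s) || s == 0) s <- 1
        Z <- cbind(Z, (v - m) / s)
        ctr <- c(ctr, m); scl <- c(scl, s)
    }
    colnames(Z) <- covariates
    q <- as.integer(depthCovariate) + ncol(Z)

    blocks <- list()
    off <- 0L
    blocks[["gamma0"]] <- list(name = "gamma0", type = "gamma0",
                               cols = seq_len(p), samples = seq_len(M),
                               group = NA_integer_)
    off <- p
    for (g in seq_len(G)[-1L]) {
        nm <- paste0("delta.", levels(groups)[g])
        blocks[[nm]] <- list(name = nm, type = "delta",
                             cols = off + seq_len(p),
                             samples = which(as.integer(groups) == g),
                             group = g)
        off <- off + p
    }
    for (i in seq_len(M)) {
        nm <- paste0("upsilon.", ids[i])
        blocks[[nm]] <- list(name = nm, type = "upsilon",
                             cols = off + seq_len(pI), samples = i,
                             group = as.integer(groups)[i])
        off <- off + pI
    }
    if (q > 0L) {
        blocks[["eta"]] <- list(name = "eta", type = "eta",
                                cols = off + seq_len(q),
                                samples = seq_len(M),
                                group = NA_integer_)
        off <- off + q
    }
    new("DesignLayout", basisGroup = basis, basisIndiv = basisIndiv,
        groups = groups, sampleIds = ids,
        depthCovariate = depthCovariate, covariates = Z,
        covariateCenter = ctr, covariateScale = scl,
        blocks = blocks, npar = as.integer(off))
}

setMethod("show", "DesignLayout", function(object) {
    cat(sprintf(paste0(
        "DesignLayout: %d parameters (p = %d, G = %d, M = %d, q = %d%s)\n"),
        object@npar, object@basisGroup@p, nlevels(object@groups),
        length(object@groups),
        as.integer(object@depthCovariate) + ncol(object@covariates),
        if (object@basisIndiv@p != object@basisGroup@p)
            sprintf(", individual p = %d", object@basisIndiv@p) else ""))
})

#' Per-entry covariate design for the eta block
#'
#' Returns, for sample i, the T x q matrix whose columns are the
#' read-depth covariate log(n+1) (position-specific; 0 at missing
#' entries by construction) followed by the standardized sample
#' covariates (constant across positions).
#'
#' @keywords internal
etaDesign <- function(layout, counts, i) {
    TT <- nrow(counts)
    cols <- NULL
    if (layout@depthCovariate)
        cols <- cbind(cols, log(totalReads(counts)[, i] + 1))
    if (ncol(layout@covariates) > 0L)
        for (j in seq_len(ncol(layout@covariates)))
            cols <- cbind(cols, rep(layout@covariates[i, j], TT))
    cols
}

#' Linear predictor matrix for a parameter vector
#'
#' Computes the T x M matrix of logit-scale linear predictors implied by
#' the stacked parameter vector under a layout, summing each sample's
#' active blocks.
#'
#' @param theta stacked parameter vector (length \code{layout@npar}).
#' @param layout a \linkS4class{DesignLayout}.
#' @param counts the \linkS4class{MethylCounts} (needed for the
#'   read-depth covariate).
#' @return T x M numeric matrix.
#' @export
linearPredictor <- function(theta, layout, counts) {
    TT <- nrow(counts); M <- length(layout@groups)
    Xg <- layout@basisGroup@matrix
    Xi <- layout@basisIndiv@matrix
    lp <- matrix(0, TT, M)
    for (b in layout@blocks) {
        th <- theta[b$cols]
        if (b$type %in% c("gamma0", "delta")) {
            v <- Xg %*% th
            lp[, b$samples] <- lp[, b$samples] + as.vector(v)
        } else if (b$type == "upsilon") {
            lp[, b$samples] <- lp[, b$samples] + as.vector(Xi %*% th)
        } else {  # eta
            for (i in seq_len(M))
                lp[, i] <- lp[, i] + as.vector(etaDesign(layout, counts, i) %*% th)
        }
    }
    lp
}

#' Per-sample fitted methylation levels
#'
#' @inheritParams linearPredictor
#' @return T x M matrix of \eqn{\beta^* = logit^{-1}} of the linear
#'   predictor, strictly inside (0,1).
#' @export
fittedBeta <- function(theta, layout, counts)
    plogis(linearPredictor(theta, layout, counts))
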