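#' Natural cubic spline basis at genomic coordinates
#'
#' Builds the p-dimensional functional basis used by every coefficient
#' block.  The basis is evaluated at genomic coordinates, so uneven CpG
#' spacing is reflected in the fit (two position vectors with the same
#' ordering but different gaps give different bases).  Column 1 is the
#' constant; columns 2..p are natural cubic splines (linear beyond the
#' boundary knots) with interior knots at coordinate quantiles of the
#' CpGs, which tracks uneven CpG density.
#'
#' @param positions strictly increasing coordinate vector (length T).
#' @param p basis dimension (resolution); requires \code{T >= p} and
#'   \code{p >= 2}.
#' @return A \linkS4class{SplineBasis}.
#' @examples
#' b <- splineBasis(sort(sample(1e5, 200)), p = 30)
#' dim(basisMatrix(b))
#' @export
splineBasis <- function(positions, p = 30L) {
    positions <- as.numeric(positions)
    TT <- length(positions)
    p <- as.integer(p)
    if (p < 2L) stop("resolution p must be at least 2")
    if (TT < p)
        stop(sprintf(paste0(
            "region has %d positions but resolution is %d; ",
            "use a smaller resolution or a larger partition"), TT, p))
    if (any(diff(positions) <= 0))
        stop("positions must be strictly increasing")
    ns <- splines::ns(positions, df = p - 1L)
    X <- cbind(1, unclass(ns))
    dimnames(X) <- NULL
    new("SplineBasis", positions = positions, p = p,
        knots = as.numeric(attr(ns, "knots")),
        boundary = as.numeric(attr(ns, "Boundary.knots")),
        matrix = X)
}

#' @describeIn splineBasis the T x p basis matrix.
#' @param basis a \code{SplineBasis}.
#' @export
basisMatrix <- function(basis) basis@matrix

setMethod("show", "SplineBasis", function(object) {
    cat(sprintf("SplineBasis: p = %d over %d positions [%s, %s]\n",
                object@p, length(object@positions),
                format(object@boundary[1L]), format(object@boundary[2L])))
})
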