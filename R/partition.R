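#' Partition the CpG axis into fitting regions
#'
#' Splits 1..T into contiguous regions of at most \code{size} positions
#' (default 500, the recommended region size for a resolution-30 basis).
#' A trailing remainder shorter than \code{resolution} is merged into the
#' preceding region so every fitted region supports its spline basis.
#'
#' @param x a \linkS4class{MethylCounts} object, or an integer T.
#' @param size maximum region size; must be at least
#'   \code{2 * resolution}.
#' @param resolution the spline resolution the regions must support.
#' @return A \linkS4class{RegionPartition}.
#' @examples
#' partitionRegions(1200L, size = 500L)
#' @export
partitionRegions <- function(x, size = 500L, resolution = 30L) {
    TT <- if (is(x, "MethylCounts")) nrow(x) else as.integer(x)
    size <- as.integer(size); resolution <- as.integer(resolution)
    if (size < 2L * resolution)
        stop(sprintf(
            "partition size (%d) must be at least twice the resolution (%d)",
            size, resolution))
    if (TT < 1L) stop("no positions to partition")
    starts <- seq.int(1L, TT, by = size)
    ends <- pmin(starts + size - 1L, TT)
    k <- length(starts)
    if (k > 1L && (ends[k] - starts[k] + 1L) < resolution) {
        ends[k - 1L] <- ends[k]
        starts <- starts[-k]; ends <- ends[-k]
    }
    new("RegionPartition",
        ranges = IRanges(start = starts, end = ends),
        nPositions = TT, size = size)
}

#' @describeIn partitionRegions number of regions.
#' @param object a \code{RegionPartition}.
#' @export
setMethod("length", "RegionPartition", function(x) length(x@ranges))

setMethod("show", "RegionPartition", function(object) {
    cat(sprintf("RegionPartition: %d region(s) over %d positions (size %d)\n",
                length(object@ranges), object@nPositions, object@size))
})

#' Index range of one partition region
#'
#' @param part a \linkS4class{RegionPartition}.
#' @param k region number.
#' @return Integer vector of 1-based row indices.
#' @export
regionIndices <- function(part, k) {
    seq.int(IRanges::start(part@ranges)[k], IRanges::end(part@ranges)[k])
}
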