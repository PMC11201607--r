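#' Build a MethylCounts object
#'
#' Assembles per-CpG methylated counts and read depths into the central
#' data container.  \code{NA} entries in either matrix are interpreted as
#' missing observations and converted to \code{y = 0, n = 0}; entries
#' with zero depth are likewise flagged missing.
#'
#' @param positions integer vector of 1-based genomic coordinates,
#'   strictly increasing.
#' @param meth T x M matrix of methylated read counts.
#' @param depth T x M matrix of read depths.
#' @param sampleData \code{data.frame} or \code{DataFrame} with one row
#'   per sample; must contain a \code{group} column (coerced to factor;
#'   the first level is the baseline).  Additional numeric columns can be
#'   used as model covariates.  Row names (or a \code{sample_id} column)
#'   name the samples.
#' @param chrom chromosome name (single value).
#'
#' @return A \linkS4class{MethylCounts} object.
#' @examples
#' mc <- MethylCounts(positions = c(100L, 150L),
#'                    meth = matrix(c(3L, 5L), 2, 1),
#'                    depth = matrix(c(10L, 9L), 2, 1),
#'                    sampleData = data.frame(group = "a",
#'                                            row.names = "s1"))
#' rawFractions(mc)
#' @export
MethylCounts <- function(positions, meth, depth, sampleData,
                         chrom = "chr1") {
    meth <- as.matrix(meth); depth <- as.matrix(depth)
    storage.mode(meth) <- "double"; storage.mode(depth) <- "double"
    miss <- is.na(meth) | is.na(depth) | (!is.na(depth) & depth == 0)
    meth[miss] <- 0; depth[miss] <- 0
    if (is.data.frame(sampleData)) {
        if ("sample_id" %in% colnames(sampleData) &&
            is.null(attr(sampleData, "row.names.explicit")) &&
            all(row.names(sampleData) == as.character(seq_len(nrow(sampleData)))))
            row.names(sampleData) <- sampleData$sample_id
        sampleData <- DataFrame(sampleData)
    }
    sampleData$group <- factor(sampleData$group)
    colnames(meth) <- colnames(depth) <- rownames(sampleData)
    gr <- GRanges(chrom, IRanges(start = as.integer(positions), width = 1L))
    se <- SummarizedExperiment(
        assays = list(meth = meth, depth = depth),
        rowRanges = gr, colData = sampleData)
    new("MethylCounts", se)
}

#' Count and metadata accessors
#'
#' \code{methReads} and \code{totalReads} return the count matrices,
#' \code{missingMask} the logical matrix of missing (zero-depth) entries,
#' \code{sampleGroups} the group factor, and \code{rawFractions} the raw
#' methylation levels \eqn{y/n} (\code{NA} at missing entries).
#'
#' @param x a \linkS4class{MethylCounts} object.
#' @return A matrix (or factor for \code{sampleGroups}).
#' @aliases methReads totalReads missingMask sampleGroups rawFractions
#' @export
setMethod("methReads", "MethylCounts", function(x) assay(x, "meth"))

#' @rdname methReads
#' @export
setMethod("totalReads", "MethylCounts", function(x) assay(x, "depth"))

#' @rdname methReads
#' @export
setMethod("missingMask", "MethylCounts",
          function(x) assay(x, "depth") == 0)

#' @rdname methReads
#' @export
setMethod("sampleGroups", "MethylCounts",
          function(x) factor(colData(x)$group))

#' @rdname methReads
#' @export
setMethod("rawFractions", "MethylCounts", function(x) {
    n <- assay(x, "depth")
    f <- assay(x, "meth") / n
    f[n == 0] <- NA_real_
    f
})

setMethod("show", "MethylCounts", function(object) {
    pos <- start(rowRanges(object))
    cat(sprintf("MethylCounts: %d CpGs x %d samples on %s\n",
                nrow(object), ncol(object),
                as.character(seqnames(object)@values[1L])))
    if (nrow(object)) cat(sprintf("  positions %d..%d\n",
                                  min(pos), max(pos)))
    cat(sprintf("  groups: %s\n",
                paste(sprintf("%s(%d)", levels(sampleGroups(object)),
                              table(sampleGroups(object))),
                      collapse = " ")))
    cat(sprintf("  missing entries: %.1f%%\n",
                100 * mean(missingMask(object))))
})
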