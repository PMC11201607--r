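# ---- scoring DMC calls against simulation truth -----------------------

asCalls <- function(calls) {
    if (is(calls, "DMCResult")) dmcCalls(calls) else as.logical(calls)
}

#' Non-DMR segments of a truth object
#'
#' The complement of the DMR ranges over 1..T as closed index ranges
#' (with J DMRs strictly inside the region there are J+1 NDMRs).
#'
#' @param truth a \linkS4class{SimTruth}.
#' @return data.frame with columns \code{start}, \code{end}.
#' @export
ndmrRanges <- function(truth) {
    TT <- length(truth@dmc)
    d <- truth@dmrs[order(truth@dmrs$start), , drop = FALSE]
    starts <- c(1L, d$end + 1L)
    ends <- c(d$start - 1L, TT)
    keep <- starts <= ends
    data.frame(start = starts[keep], end = ends[keep])
}

#' Confusion counts of DMC calls against truth
#'
#' @param calls logical per-CpG call vector or a
#'   \linkS4class{DMCResult}.
#' @param truth a \linkS4class{SimTruth}.
#' @return list with TP, TN, FP, FN.
#' @export
confusionCounts <- function(calls, truth) {
    cl <- asCalls(calls); tr <- truth@dmc
    stopifnot(length(cl) == length(tr))
    list(TP = sum(cl & tr), TN = sum(!cl & !tr),
         FP = sum(cl & !tr), FN = sum(!cl & tr))
}

#' Per-region sensitivity and specificity
#'
#' \code{sensitivityPerDmr} returns, for each DMR j, the fraction of its
#' CpGs called DMC; \code{specificityPerNdmr} returns, for each non-DMR
#' segment k, the fraction of its CpGs not called.  Replicate averages
#' are taken by the caller.
#'
#' @inheritParams confusionCounts
#' @return Numeric vector in [0, 1], one entry per region.
#' @export
sensitivityPerDmr <- function(calls, truth) {
    cl <- asCalls(calls)
    d <- truth@dmrs
    if (!nrow(d)) stop("truth has no DMRs")
    vapply(seq_len(nrow(d)), function(j)
        mean(cl[d$start[j]:d$end[j]]), 0)
}

#' @rdname sensitivityPerDmr
#' @export
specificityPerNdmr <- function(calls, truth) {
    cl <- asCalls(calls)
    nd <- ndmrRanges(truth)
    if (!nrow(nd)) stop("truth has no non-DMR segment")
    vapply(seq_len(nrow(nd)), function(k)
        mean(!cl[nd$start[k]:nd$end[k]]), 0)
}

#' Overall and modified accuracy
#'
#' \code{accuracy} is (TP + TN) / T.  \code{modifiedAccuracy} relabels
#' the truth so that only the listed DMRs count as positive before
#' computing the same ratio (used when some planted regions carry
#' negligible effects).
#'
#' @inheritParams confusionCounts
#' @param realDmrIds row indices into \code{truth@dmrs} of the regions
#'   treated as real.
#' @return A proportion in [0, 1].
#' @export
accuracy <- function(calls, truth) {
    cc <- confusionCounts(calls, truth)
    (cc$TP + cc$TN) / length(truth@dmc)
}

#' @rdname accuracy
#' @export
modifiedAccuracy <- function(calls, truth, realDmrIds) {
    if (length(realDmrIds) &&
        any(realDmrIds < 1L | realDmrIds > nrow(truth@dmrs)))
        stop("unknown DMR id in realDmrIds")
    d <- truth@dmrs[realDmrIds, , drop = FALSE]
    relabeled <- makeTruth(truth@group1, truth@group2, d)
    accuracy(calls, relabeled)
}

#' Empirical FDR, Cohen's kappa and DMR boundary detection
#'
#' \code{empiricalFdr} is FP / (FP + TP), defined as 0 when nothing is
#' called.  \code{cohensKappa} is the standard 2x2 observed-vs-chance
#' agreement.  \code{boundaryDetection} returns the fraction of DMRs
#' whose first and last CpG were called.
#'
#' @inheritParams confusionCounts
#' @return A scalar (\code{boundaryDetection}: named vector
#'   \code{c(start=, end=)}).
#' @export
empiricalFdr <- function(calls, truth) {
    cc <- confusionCounts(calls, truth)
    if (cc$FP + cc$TP == 0L) return(0)
    cc$FP / (cc$FP + cc$TP)
}

#' @rdname empiricalFdr
#' @export
cohensKappa <- function(calls, truth) {
    cc <- confusionCounts(calls, truth)
    N <- length(truth@dmc)
    po <- (cc$TP + cc$TN) / N
    pe <- ((cc$TP + cc$FP) * (cc$TP + cc$FN) +
           (cc$FN + cc$TN) * (cc$FP + cc$TN)) / N^2
    if (1 - pe == 0) return(0)
    (po - pe) / (1 - pe)
}

#' @rdname empiricalFdr
#' @export
boundaryDetection <- function(calls, truth) {
    cl <- asCalls(calls)
    d <- truth@dmrs
    if (!nrow(d)) stop("truth has no DMRs")
    c(start = mean(cl[d$start]), end = mean(cl[d$end]))
}

#' One-row metric summary for a replicate
#'
#' Convenience wrapper computing the full metric set used in
#' simulation scoring: mean per-DMR sensitivity, mean per-NDMR
#' specificity, accuracy, empirical FDR, Cohen's kappa and boundary
#' detection rates.
#'
#' @inheritParams confusionCounts
#' @return A one-row \code{data.frame}.
#' @export
evaluateCalls <- function(calls, truth) {
    bd <- boundaryDetection(calls, truth)
    data.frame(sensitivity = mean(sensitivityPerDmr(calls, truth)),
               specificity = mean(specificityPerNdmr(calls, truth)),
               accuracy = accuracy(calls, truth),
               efdr = empiricalFdr(calls, truth),
               kappa = cohensKappa(calls, truth),
               boundaryStart = unname(bd["start"]),
               boundaryEnd = unname(bd["end"]))
}
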