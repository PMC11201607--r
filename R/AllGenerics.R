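#' @rdname methReads
#' @export
setGeneric("methReads", function(x) standardGeneric("methReads"))

#' @rdname methReads
#' @export
setGeneric("totalReads", function(x) standardGeneric("totalReads"))

#' @rdname methReads
#' @export
setGeneric("missingMask", function(x) standardGeneric("missingMask"))

#' @rdname methReads
#' @export
setGeneric("sampleGroups", function(x) standardGeneric("sampleGroups"))

#' @rdname methReads
#' @export
setGeneric("rawFractions", function(x) standardGeneric("rawFractions"))

#' @rdname callDMCs
#' @export
setGeneric("callDMCs", function(object, alpha = 0.05, contrasts = NULL, ...)
    standardGeneric("callDMCs"))

#' @rdname summarizeCalls
#' @export
setGeneric("summarizeCalls", function(object) standardGeneric("summarizeCalls"))

#' @rdname callDMCs
#' @export
setGeneric("dmcCalls", function(object) standardGeneric("dmcCalls"))

#' @rdname posteriorMeans
#' @export
setGeneric("posteriorMeans", function(object) standardGeneric("posteriorMeans"))

#' @rdname drawDepths
#' @export
setGeneric("drawDepths", function(object, nPos, nSamples)
    standardGeneric("drawDepths"))
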