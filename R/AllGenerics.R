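#' @export
setGeneric("basePairs", function(x) standardGeneric("basePairs"))

#' @export
setGeneric("seqLength", function(x) standardGeneric("seqLength"))

#' @export
setGeneric("reactivities", function(x) standardGeneric("reactivities"))

#' @export
setGeneric("missingMask", function(x) standardGeneric("missingMask"))

#' @export
setGeneric("pairProbs", function(x) standardGeneric("pairProbs"))

#' @export
setGeneric("structures", function(x) standardGeneric("structures"))

#' @export
setGeneric("centroids", function(x) standardGeneric("centroids"))

#' @export
setGeneric("populations", function(x) standardGeneric("populations"))

#' @export
setGeneric("shannonEntropy", function(x, ...) standardGeneric("shannonEntropy"))

#' @export
setGeneric("classMeans", function(x) standardGeneric("classMeans"))
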