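#' @rdname MaldrResults-class
#' @param x a \code{MaldrResults} object.
#' @export
setGeneric("maldrPass", function(x) standardGeneric("maldrPass"))

#' @rdname MaldrResults-class
#' @export
setGeneric("smoothedCurves", function(x) standardGeneric("smoothedCurves"))

#' @rdname DepthProfileList-class
#' @param x a \code{DepthProfileList}.
#' @param gene gene identifier.
#' @export
setGeneric("depthProfile", function(x, gene) standardGeneric("depthProfile"))

#' @rdname DepthProfileList-class
#' @export
setGeneric("sampleData", function(x) standardGeneric("sampleData"))
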