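#' Construct MALDR parameters
#'
#' @param prefilterFdr FDR threshold of the gap-site pre-filter (default 0.1).
#' @param lowCoverageFrac low-coverage cut as a fraction of the maximal
#'   smoothed depth within the gene (default 0.02, i.e. 2%).
#' @param ratioThreshold adjacent-group depth ratio bound, strict (default 1.2).
#' @param fractionThreshold monotone fraction bound, strict (default 0.99).
#' @param correlationThreshold pairwise correlation bound of the
#'   co-expression screen (default 0.8).
#' @param loessSpan span of the depth smoother (default 0.3).
#' @return a validated [MaldrParameters-class] object.
#' @examples
#' MaldrParameters()
#' MaldrParameters(ratioThreshold = 1.5)
#' @export
MaldrParameters <- function(prefilterFdr = 0.1, lowCoverageFrac = 0.02,
                            ratioThreshold = 1.2, fractionThreshold = 0.99,
                            correlationThreshold = 0.8, loessSpan = 0.3) {
    new("MaldrParameters",
        prefilterFdr = prefilterFdr, lowCoverageFrac = lowCoverageFrac,
        ratioThreshold = ratioThreshold, fractionThreshold = fractionThreshold,
        correlationThreshold = correlationThreshold, loessSpan = loessSpan)
}

#' @describeIn MaldrParameters-class display the thresholds.
#' @param object a \code{MaldrParameters} object.
#' @export
setMethod("show", "MaldrParameters", function(object) {
    cat("MaldrParameters\n")
    cat("  prefilter FDR        <", object@prefilterFdr, "\n")
    cat("  low-coverage cut     <", object@lowCoverageFrac, "x max depth\n")
    cat("  adjacent ratio       >", object@ratioThreshold, "\n")
    cat("  monotone fraction    >", object@fractionThreshold, "\n")
    cat("  correlation          >", object@correlationThreshold, "\n")
    cat("  loess span            ", object@loessSpan, "\n")
})
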