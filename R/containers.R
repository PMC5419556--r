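#' Construct a gap-site count experiment
#'
#' @param counts integer matrix, gap-sites x samples.
#' @param gapSites a [GenomicRanges::GRanges-class] of the same length as
#'   \code{nrow(counts)}; each range spans leftEnd..rightStart of one
#'   gap-site (last aligned base before the gap to first aligned base after
#'   it).
#' @param sampleData a \code{DataFrame}/\code{data.frame} with one row per
#'   sample (donor, age group, gender, location, library size, ...).
#' @return a [GapSiteCounts-class] object.
#' @export
GapSiteCounts <- function(counts, gapSites, sampleData = NULL) {
    counts <- as.matrix(counts)
    storage.mode(counts) <- "integer"
    if (is.null(sampleData))
        sampleData <- DataFrame(row.names = colnames(counts))
    if (is.null(rownames(sampleData)) && !is.null(colnames(counts)))
        rownames(sampleData) <- colnames(counts)
    se <- SummarizedExperiment(
        assays = list(counts = counts),
        rowRanges = gapSites,
        colData = as(sampleData, "DataFrame"))
    new("GapSiteCounts", se)
}

#' Extract the count assay
#' @param x a [GapSiteCounts-class] object.
#' @return integer matrix of gap-site read counts.
#' @export
gapSiteCounts <- function(x) SummarizedExperiment::assay(x, "counts")

#' Left end of each gap-site (last aligned base before the gap)
#' @param x a \code{GapSiteCounts} or gap-site \code{GRanges}.
#' @export
leftEnd <- function(x) {
    if (is(x, "SummarizedExperiment")) x <- SummarizedExperiment::rowRanges(x)
    GenomicRanges::start(x)
}

#' Right start of each gap-site (first aligned base after the gap)
#' @param x a \code{GapSiteCounts} or gap-site \code{GRanges}.
#' @export
rightStart <- function(x) {
    if (is(x, "SummarizedExperiment")) x <- SummarizedExperiment::rowRanges(x)
    GenomicRanges::end(x)
}

#' @describeIn GapSiteCounts-class summary display.
#' @param object a \code{GapSiteCounts} object.
#' @export
setMethod("show", "GapSiteCounts", function(object) {
    callNextMethod()
    cat("gap-sites:", nrow(object), " samples:", ncol(object),
        " total reads:", sum(gapSiteCounts(object)), "\n")
})

#' Construct a depth profile list
#'
#' @param profiles named list (by gene) of integer matrices, positions x
#'   samples; rownames are 1-based genomic positions.
#' @param sampleData per-sample annotation, one row per sample, rownames =
#'   sample ids matching the matrix columns.
#' @return a [DepthProfileList-class] object.
#' @export
DepthProfileList <- function(profiles, sampleData) {
    new("DepthProfileList", profiles = profiles,
        sampleData = as(sampleData, "DataFrame"))
}

#' @describeIn DepthProfileList-class depth matrix of one gene.
#' @export
setMethod("depthProfile", "DepthProfileList", function(x, gene) {
    if (!gene %in% names(x@profiles))
        stop("no depth profile for gene '", gene, "'")
    x@profiles[[gene]]
})

#' @describeIn DepthProfileList-class the per-sample annotation.
#' @export
setMethod("sampleData", "DepthProfileList", function(x) x@sampleData)

#' @describeIn DepthProfileList-class gene identifiers.
#' @param x a \code{DepthProfileList}.
#' @export
setMethod("names", "DepthProfileList", function(x) names(x@profiles))

#' @describeIn DepthProfileList-class number of genes.
#' @export
setMethod("length", "DepthProfileList", function(x) length(x@profiles))

#' @describeIn DepthProfileList-class summary display.
#' @param object a \code{DepthProfileList}.
#' @export
setMethod("show", "DepthProfileList", function(object) {
    cat("DepthProfileList with", length(object@profiles), "genes,",
        nrow(object@sampleData), "samples\n")
    if (length(object@profiles)) {
        g <- names(object@profiles)[1L]
        cat("  e.g.", g, "-", nrow(object@profiles[[g]]), "positions\n")
    }
})

#' @describeIn MaldrResults-class per-gene result table as a \code{DataFrame}.
#' @param x a \code{MaldrResults} object.
#' @export
maldrResults <- function(x) x@results

#' @describeIn MaldrResults-class ids of genes passing the filter,
#'   ordered by decreasing monotone fraction.
#' @export
setMethod("maldrPass", "MaldrResults", function(x) {
    r <- x@results[x@results$passes %in% TRUE, , drop = FALSE]
    r$gene_id[order(-r$monotoneFraction, r$gene_id)]
})

#' @describeIn MaldrResults-class smoothed group-mean depth curves
#'   (named list of groups-x-positions matrices).
#' @export
setMethod("smoothedCurves", "MaldrResults", function(x) x@curves)

#' @describeIn MaldrResults-class coerce the result table to a data.frame.
#' @param row.names,optional,... passed on, as for [base::as.data.frame()].
#' @export
setMethod("as.data.frame", "MaldrResults",
    function(x, row.names = NULL, optional = FALSE, ...)
        as.data.frame(x@results, row.names = row.names, optional = optional, ...))

#' @describeIn MaldrResults-class summary display.
#' @param object a \code{MaldrResults} object.
#' @export
setMethod("show", "MaldrResults", function(object) {
    r <- object@results
    cat("MaldrResults:", nrow(r), "genes evaluated,",
        sum(r$passes %in% TRUE), "pass the monotone filter\n")
    cat("  (ratio >", object@parameters@ratioThreshold,
        "over >", 100 * object@parameters@fractionThreshold,
        "% of the restricted region)\n")
})
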