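#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- SimpleList
#' @importFrom GenomicRanges GRanges GRangesList seqnames start end width
#'   strand mcols mcols<-
#' @importFrom IRanges IRanges
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#'   rowRanges rowData
NULL

#' Parameters of the MALDR filter
#'
#' Container for every numeric threshold of the monotone alignment depth
#' ratio method. Defaults are the published operating point of the filter:
#' gap-site pre-filter FDR below 0.1, low-coverage cut at 2% of the gene's
#' maximal smoothed depth, adjacent-group depth ratio strictly above 1.2,
#' monotone fraction strictly above 99% of the restricted region, and
#' correlation threshold 0.8 for the co-expression screen. The loess span
#' is not fixed by the method description; 0.3 is the package default.
#'
#' @slot prefilterFdr FDR threshold of the two-group gap-site pre-filter.
#' @slot lowCoverageFrac fraction of the maximal smoothed depth below which
#'   positions are discarded.
#' @slot ratioThreshold adjacent-group depth ratio that a position must
#'   strictly exceed to count as monotone.
#' @slot fractionThreshold fraction of the restricted region that must be
#'   monotone for a gene to pass.
#' @slot correlationThreshold pairwise correlation bound of the
#'   co-expression clique search.
#' @slot loessSpan span of the local-linear smoother on group-mean depth.
#' @export
setClass("MaldrParameters",
    representation(
        prefilterFdr         = "numeric",
        lowCoverageFrac      = "numeric",
        ratioThreshold       = "numeric",
        fractionThreshold    = "numeric",
        correlationThreshold = "numeric",
        loessSpan            = "numeric"
    ),
    prototype(
        prefilterFdr         = 0.1,
        lowCoverageFrac      = 0.02,
        ratioThreshold       = 1.2,
        fractionThreshold    = 0.99,
        correlationThreshold = 0.8,
        loessSpan            = 0.3
    )
)

setValidity("MaldrParameters", function(object) {
    msg <- character()
    in01 <- function(x) length(x) == 1L && is.finite(x) && x > 0 && x < 1
    if (!in01(object@prefilterFdr))
        msg <- c(msg, "'prefilterFdr' must be a single value in (0,1)")
    if (!in01(object@lowCoverageFrac))
        msg <- c(msg, "'lowCoverageFrac' must be a single value in (0,1)")
    if (!(length(object@ratioThreshold) == 1L &&
          is.finite(object@ratioThreshold) && object@ratioThreshold > 1))
        msg <- c(msg, "'ratioThreshold' must be a single value > 1")
    if (!in01(object@fractionThreshold))
        msg <- c(msg, "'fractionThreshold' must be a single value in (0,1)")
    if (!in01(object@correlationThreshold))
        msg <- c(msg, "'correlationThreshold' must be a single value in (0,1)")
    if (!(length(object@loessSpan) == 1L && is.finite(object@loessSpan) &&
          object@loessSpan > 0 && object@loessSpan <= 1))
        msg <- c(msg, "'loessSpan' must be a single value in (0,1]")
    if (length(msg)) msg else TRUE
})

#' Gap-site count experiment
#'
#' A \linkS4class{RangedSummarizedExperiment} whose rows are gap-sites
#' (the inner border pair of a gapped read alignment, the surrogate of a
#' splice junction) and whose columns are samples. The row ranges span
#' \code{leftEnd..rightStart}, i.e. the last aligned base before the gap to
#' the first aligned base after it; \code{rowData} may carry
#' \code{gene_id} and \code{ambiguous} after annotation matching. The
#' \code{"counts"} assay holds non-negative integer read counts.
#'
#' @seealso [GapSiteCounts()], [assembleCountMatrix()]
#' @export
setClass("GapSiteCounts",
    contains = "RangedSummarizedExperiment")

setValidity("GapSiteCounts", function(object) {
    msg <- character()
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'counts' is required")
    else {
        cts <- SummarizedExperiment::assay(object, "counts")
        if (any(cts < 0)) msg <- c(msg, "counts must be non-negative")
        if (any(cts != round(cts))) msg <- c(msg, "counts must be integers")
    }
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, "sample ids must be unique")
    w <- GenomicRanges::width(SummarizedExperiment::rowRanges(object))
    if (length(w) && any(w < 3L))
        msg <- c(msg, "gap-sites need rightStart > leftEnd + 1 (gap >= 1 base)")
    if (length(msg)) msg else TRUE
})

#' Per-base depth profiles for a set of genes
#'
#' One integer matrix per gene, rows = genomic positions over the gene span
#' (1-based, stored as rownames), columns = samples. The shared sample
#' annotation lives in \code{sampleData}.
#'
#' @slot profiles named list of integer matrices (positions x samples).
#' @slot sampleData a [S4Vectors::DataFrame-class] with one row per sample.
#' @export
setClass("DepthProfileList",
    representation(
        profiles   = "list",
        sampleData = "DataFrame"
    )
)

setValidity("DepthProfileList", function(object) {
    msg <- character()
    sid <- rownames(object@sampleData)
    for (g in names(object@profiles)) {
        m <- object@profiles[[g]]
        if (!is.matrix(m)) { msg <- c(msg, sprintf("'%s': not a matrix", g)); next }
        pos <- suppressWarnings(as.numeric(rownames(m)))
        if (anyNA(pos) || is.unsorted(pos, strictly = TRUE))
            msg <- c(msg, sprintf("'%s': positions must be strictly increasing", g))
        if (!identical(colnames(m), sid))
            msg <- c(msg, sprintf("'%s': columns must match sampleData rows", g))
        if (any(m < 0)) msg <- c(msg, sprintf("'%s': negative depth", g))
    }
    if (length(msg)) head(msg, 5L) else TRUE
})

#' Results of the MALDR filter
#'
#' Per-gene outcome of the monotone alignment depth ratio pipeline: the
#' dominant trend direction across age groups, the fraction of the
#' restricted gene region where all adjacent group ratios strictly exceed
#' the ratio threshold, and the pass flag. Smoothed group curves are kept
#' (one matrix per evaluated gene) for plotting.
#'
#' @slot results a [S4Vectors::DataFrame-class] with columns \code{gene_id},
#'   \code{direction}, \code{monotoneFraction}, \code{nKept}, \code{passes}.
#' @slot parameters the [MaldrParameters-class] used.
#' @slot curves named list of groups-x-positions matrices of smoothed depth.
#' @export
setClass("MaldrResults",
    representation(
        results    = "DataFrame",
        parameters = "MaldrParameters",
        curves     = "list"
    )
)

setValidity("MaldrResults", function(object) {
    need <- c("gene_id", "direction", "monotoneFraction", "nKept", "passes")
    if (!all(need %in% colnames(object@results)))
        return(paste("results must have columns:", paste(need, collapse = ", ")))
    fr <- object@results$monotoneFraction
    if (length(fr) && any(fr < 0 | fr > 1, na.rm = TRUE))
        return("monotoneFraction must lie in [0,1]")
    ok <- object@results$passes ==
        (fr > object@parameters@fractionThreshold)
    if (length(ok) && !all(ok, na.rm = TRUE))
        return("passes must equal monotoneFraction > fractionThreshold")
    TRUE
})

# --- synthetic-data specification classes ---------------------------------

#' Specification of a synthetic genome
#'
#' Describes the artificial chromosome on which gene models are laid out:
#' number of genes, exon count and length ranges, intron length range.
#' Stands in for a real annotation so that the whole pipeline can be
#' exercised without any download.
#'
#' @slot nGenes number of gene models.
#' @slot exonsPerGene integer range \code{c(min,max)}; at least 1.
#' @slot exonLen,intronLen base-pair ranges \code{c(min,max)}.
#' @slot chrom chromosome name.
#' @slot chromLen declared chromosome length; layout must fit inside it.
#' @export
setClass("SyntheticGenomeSpec",
    representation(nGenes = "integer", exonsPerGene = "integer",
                   exonLen = "integer", intronLen = "integer",
                   chrom = "character", chromLen = "integer"),
    prototype(nGenes = 10L, exonsPerGene = c(4L, 6L),
              exonLen = c(100L, 250L), intronLen = c(200L, 600L),
              chrom = "chrS", chromLen = 10000000L)
)

setValidity("SyntheticGenomeSpec", function(object) {
    msg <- character()
    rng <- function(x) length(x) == 2L && all(x >= 1L) && x[1] <= x[2]
    if (!(length(object@nGenes) == 1L && object@nGenes >= 1L))
        msg <- c(msg, "'nGenes' must be >= 1")
    if (!rng(object@exonsPerGene))
        msg <- c(msg, "'exonsPerGene' must be a positive range c(min,max)")
    if (!rng(object@exonLen)) msg <- c(msg, "'exonLen' must be a positive range")
    if (!rng(object@intronLen)) msg <- c(msg, "'intronLen' must be a positive range")
    if (!(length(object@chromLen) == 1L && object@chromLen > 0L))
        msg <- c(msg, "'chromLen' must be positive")
    if (length(msg)) msg else TRUE
})

#' Specification of a donor cohort
#'
#' The sampling design the method was developed for: paired biopsies (one
#' sun-exposed, one sun-protected site) from each donor, donors assigned to
#' three ordered age groups. Defaults reproduce the reference cohort:
#' 27 donors (9 per group, hence 18 samples per group, 54 samples in
#' total), age ranges Young 18-25, Middle 35-49, Old 60-67, 13 female and
#' 14 male donors.
#'
#' @slot nDonors number of donors; each yields one sample per location.
#' @slot ageGroups data.frame with columns \code{group}, \code{minAge},
#'   \code{maxAge}, \code{nDonors} (ordered youngest first).
#' @slot nFemale number of female donors (the rest are male).
#' @slot locations the two body-site labels.
#' @slot libSizeRange reads-per-sample range.
#' @slot donorSigma sd (log scale) of the per-gene donor random effect
#'   shared between a donor's two samples.
#' @export
setClass("CohortSpec",
    representation(nDonors = "integer", ageGroups = "data.frame",
                   nFemale = "integer", locations = "character",
                   libSizeRange = "numeric", donorSigma = "numeric"),
    prototype(
        nDonors = 27L,
        ageGroups = data.frame(
            group = c("Young", "Middle", "Old"),
            minAge = c(18L, 35L, 60L), maxAge = c(25L, 49L, 67L),
            nDonors = c(9L, 9L, 9L)),
        nFemale = 13L,
        locations = c("sun_exposed", "sun_protected"),
        libSizeRange = c(18e6, 30e6),
        donorSigma = 0.3
    )
)

setValidity("CohortSpec", function(object) {
    msg <- character()
    ag <- object@ageGroups
    need <- c("group", "minAge", "maxAge", "nDonors")
    if (!all(need %in% colnames(ag)))
        msg <- c(msg, "ageGroups needs columns group/minAge/maxAge/nDonors")
    else if (sum(ag$nDonors) != object@nDonors)
        msg <- c(msg, "age-group donor counts must sum to nDonors")
    if (length(object@locations) != 2L)
        msg <- c(msg, "exactly two locations (one sample per donor per location)")
    if (object@nFemale < 0L || object@nFemale > object@nDonors)
        msg <- c(msg, "'nFemale' must be between 0 and nDonors")
    if (!(length(object@libSizeRange) == 2L && all(object@libSizeRange > 0) &&
          object@libSizeRange[1] <= object@libSizeRange[2]))
        msg <- c(msg, "'libSizeRange' must be a positive range")
    if (!(length(object@donorSigma) == 1L && object@donorSigma >= 0))
        msg <- c(msg, "'donorSigma' must be a single value >= 0")
    if (length(msg)) msg else TRUE
})

#' Specification of a simulated expression effect
#'
#' One per-gene perturbation injected into the synthetic cohort.
#' \code{monotone_up}/\code{monotone_down} multiply the mean by
#' \code{ratio} per adjacent age-group step (the signal the MALDR filter is
#' built to find); \code{outlier_donors} multiplies the listed donors'
#' expression by \code{outlierFold}, emulating the observed pattern where a
#' handful of donors with strongly elevated transcript levels create an
#' apparent group trend; \code{gender_biased}/\code{location_biased} apply
#' \code{ratio} to male / sun-exposed samples; \code{null} does nothing.
#'
#' @slot geneId gene the effect applies to.
#' @slot kind one of \code{null}, \code{monotone_up}, \code{monotone_down},
#'   \code{outlier_donors}, \code{gender_biased}, \code{location_biased}.
#' @slot ratio per-step (or per-level) fold change, \code{>= 1}.
#' @slot outlierDonors donor ids (only for \code{outlier_donors}).
#' @slot outlierFold multiplier for outlier donors.
#' @export
setClass("EffectSpec",
    representation(geneId = "character", kind = "character",
                   ratio = "numeric", outlierDonors = "character",
                   outlierFold = "numeric"),
    prototype(kind = "null", ratio = 1, outlierDonors = character(0),
              outlierFold = 1)
)

setValidity("EffectSpec", function(object) {
    kinds <- c("null", "monotone_up", "monotone_down", "outlier_donors",
               "gender_biased", "location_biased")
    msg <- character()
    if (!(length(object@kind) == 1L && object@kind %in% kinds))
        msg <- c(msg, paste("'kind' must be one of:", paste(kinds, collapse = ", ")))
    if (!(length(object@ratio) == 1L && object@ratio >= 1))
        msg <- c(msg, "'ratio' must be >= 1")
    if (object@kind != "outlier_donors" &&
        (length(object@outlierDonors) > 0L || object@outlierFold != 1))
        msg <- c(msg, "outlier fields only apply when kind = 'outlier_donors'")
    if (object@kind == "outlier_donors" && length(object@outlierDonors) == 0L)
        msg <- c(msg, "'outlier_donors' effect needs at least one donor id")
    if (!(length(object@outlierFold) == 1L && object@outlierFold > 0))
        msg <- c(msg, "'outlierFold' must be positive")
    if (length(msg)) msg else TRUE
})
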