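#' Remove intronic positions defined by observed gap-sites
#'
#' First cut of the gene region: every position strictly inside an observed
#' gap interval \code{(leftEnd, rightStart)} is intronic and removed; the
#' union over the gene's gap-sites is taken, so overlapping gaps remove a
#' position once. Positions equal to the inner borders themselves (the last
#' and first aligned bases) are exonic and stay. With no gap-sites the
#' region is returned unchanged. Observed gap-sites, not annotation, define
#' the introns: the cut follows the splicing events actually present in
#' the alignments.
#'
#' @param positions sorted numeric vector of genomic positions.
#' @param gapSites gap-sites of the gene: a \code{GRanges} (ranges spanning
#'   leftEnd..rightStart) or a data.frame with \code{left_end},
#'   \code{right_start}.
#' @return numeric vector of kept positions; removed positions are attached
#'   as attribute \code{"removed_intronic"}.
#' @examples
#' restrictIntrons(1:100, data.frame(left_end = 40, right_start = 61))
#' @export
restrictIntrons <- function(positions, gapSites) {
    if (is(gapSites, "SummarizedExperiment"))
        gapSites <- SummarizedExperiment::rowRanges(gapSites)
    if (is(gapSites, "GRanges")) {
        le <- GenomicRanges::start(gapSites)
        rs <- GenomicRanges::end(gapSites)
    } else {
        le <- gapSites$left_end
        rs <- gapSites$right_start
    }
    intronic <- rep(FALSE, length(positions))
    for (k in seq_along(le))
        intronic <- intronic | (positions > le[k] & positions < rs[k])
    structure(positions[!intronic],
              removed_intronic = positions[intronic])
}

#' Group-wise mean depth
#'
#' Arithmetic mean of raw per-base depth across each group's samples.
#'
#' @param profile matrix positions x samples (rownames = positions).
#' @param groups factor along the columns; empty levels are an error.
#' @return matrix groups x positions, rows in factor-level order.
#' @export
groupMeanDepth <- function(profile, groups) {
    groups <- as.factor(groups)  # keep declared levels: empty group = error
    if (any(table(groups) == 0L))
        stop("empty group(s): ",
             paste(levels(groups)[table(groups) == 0L], collapse = ", "))
    out <- t(vapply(levels(groups), function(g)
        rowMeans(profile[, groups == g, drop = FALSE]),
        numeric(nrow(profile))))
    colnames(out) <- rownames(profile)
    out
}

#' Local-linear (loess-style) smoothing of a depth curve
#'
#' Degree-1 local regression with tricube weights over the
#' \code{ceiling(span * n)} nearest neighbours (by genomic distance),
#' evaluated at every input position and clipped at zero — depth cannot be
#' negative. Distances respect genomic coordinates, so positions on either
#' side of an excised intron are as far apart as they are on the
#' chromosome. With fewer than 5 positions smoothing is skipped with a
#' warning and the input is passed through.
#'
#' @param x sorted numeric positions.
#' @param y values at \code{x}.
#' @param span fraction of points in each local window, in (0, 1].
#' @return smoothed values at \code{x}.
#' @examples
#' loessSmooth(1:20, 2 + 3 * (1:20), span = 0.5)  # reproduces the line
#' @export
loessSmooth <- function(x, y, span = 0.3) {
    n <- length(x)
    stopifnot(length(y) == n, span > 0, span <= 1)
    if (n < 5L) {
        warning("fewer than 5 positions: smoothing skipped")
        return(pmax(y, 0))
    }
    if (is.unsorted(x)) stop("'x' must be sorted increasingly")
    q <- max(2L, ceiling(span * n))
    out <- numeric(n)
    lo <- 1L
    hi <- q
    for (i in seq_len(n)) {
        # slide the contiguous window of q points to the nearest neighbours
        while (hi < n && (x[hi + 1L] - x[i]) < (x[i] - x[lo])) {
            lo <- lo + 1L; hi <- hi + 1L
        }
        while (lo > 1L && (x[i] - x[lo - 1L]) < (x[hi] - x[i])) {
            lo <- lo - 1L; hi <- hi - 1L
        }
        idx <- lo:hi
        d <- abs(x[idx] - x[i])
        dmax <- max(d)
        w <- if (dmax > 0) (1 - (d / dmax)^3)^3 else rep(1, length(idx))
        sw <- sum(w)
        xc <- x[idx] - x[i]          # centre at the target position
        swx <- sum(w * xc)
        swxx <- sum(w * xc * xc)
        swy <- sum(w * y[idx])
        swxy <- sum(w * xc * y[idx])
        denom <- sw * swxx - swx * swx
        out[i] <- if (abs(denom) < 1e-300 * max(1, swxx))
            swy / sw
        else (swxx * swy - swx * swxy) / denom
    }
    pmax(out, 0)
}

#' Remove low-coverage positions
#'
#' Second cut of the gene region: with \code{M} the maximum smoothed depth
#' over all groups and kept positions, a position is removed when all
#' groups lie strictly below \code{lowCoverageFrac * M} (default 2%).
#' One well-covered group keeps a position.
#'
#' @param curves matrix groups x positions of (smoothed) depth.
#' @param params a [MaldrParameters-class].
#' @return logical vector along the columns: \code{TRUE} = kept. All-FALSE
#'   marks the gene unevaluable (handled by [runMaldr()]).
#' @export
restrictLowCoverage <- function(curves, params = MaldrParameters()) {
    M <- max(curves)
    apply(curves >= params@lowCoverageFrac * M, 2L, any)
}

#' Monotone adjacent-group ratio fraction
#'
#' The core decision of the filter. At each kept position the three group
#' curves (ordered youngest to oldest) are compared: the position is
#' increasing-monotone when \code{mid/young > ratioThreshold} and
#' \code{old/mid > ratioThreshold} (both strict), decreasing-monotone with
#' the reciprocal ratios. The monotone fraction is the count of positions
#' of the dominant direction over all kept positions; the gene passes when
#' that fraction strictly exceeds \code{fractionThreshold}. Zero
#' denominators are guarded by a pseudo-depth of 1e-9.
#'
#' @param curves matrix with exactly 3 rows (groups, youngest first) and
#'   one column per kept position.
#' @param params a [MaldrParameters-class].
#' @return list with \code{direction} (\code{"increasing"},
#'   \code{"decreasing"} or \code{"none"}), \code{monotoneFraction},
#'   \code{nIncreasing}, \code{nDecreasing}, \code{nKept}, \code{passes}.
#' @examples
#' cv <- rbind(Young = rep(10, 5), Middle = rep(13, 5), Old = rep(17, 5))
#' monotoneFraction(cv)$passes  # 1.3 and ~1.31 both exceed 1.2
#' @export
monotoneFraction <- function(curves, params = MaldrParameters()) {
    if (nrow(curves) != 3L)
        stop("exactly 3 ordered groups required (got ", nrow(curves), ")")
    if (ncol(curves) < 1L) stop("at least one kept position required")
    eps <- 1e-9
    guard <- function(x) ifelse(x <= 0, eps, x)
    y <- curves[1L, ]; m <- curves[2L, ]; o <- curves[3L, ]
    r <- params@ratioThreshold
    inc <- (m / guard(y) > r) & (o / guard(m) > r)
    dec <- (y / guard(m) > r) & (m / guard(o) > r)
    nInc <- sum(inc)
    nDec <- sum(dec)
    frac <- max(nInc, nDec) / ncol(curves)
    dir <- if (nInc > nDec) "increasing" else if (nDec > nInc) "decreasing"
        else "none"
    list(direction = dir, monotoneFraction = frac,
         nIncreasing = nInc, nDecreasing = nDec, nKept = ncol(curves),
         passes = frac > params@fractionThreshold)
}

#' Run the MALDR filter over a gene set
#'
#' The depth half of the pipeline, applied per gene to the pre-filtered
#' set: remove intronic positions (defined by the observed gap-sites),
#' average raw depth within each age group, smooth each group curve,
#' remove low-coverage positions, and measure the monotone adjacent-group
#' ratio fraction. Deterministic for fixed inputs.
#'
#' @param genes character vector of gene ids (the pre-filter output).
#' @param profiles a [DepthProfileList-class] covering the genes.
#' @param gapSites observed gap-sites with a \code{gene_id} annotation
#'   (a [GapSiteCounts-class], \code{GRanges}, or data.frame).
#' @param params a [MaldrParameters-class].
#' @param groupBy column of the profile sample annotation holding the age
#'   group (default \code{"age_group"}); must have exactly 3 levels,
#'   youngest first.
#' @param lowCoverageOn apply the 2% cut on the \code{"smoothed"} curves
#'   (default, following the listed order of the procedure) or on the
#'   \code{"raw"} group means before smoothing.
#' @param keepCurves store the restricted smoothed curves per gene.
#' @return a [MaldrResults-class] object. Genes without profiles or with
#'   no position surviving the cuts are skipped with a \code{message()}.
#' @export
runMaldr <- function(genes, profiles, gapSites,
                     params = MaldrParameters(), groupBy = "age_group",
                     lowCoverageOn = c("smoothed", "raw"),
                     keepCurves = TRUE) {
    lowCoverageOn <- match.arg(lowCoverageOn)
    sd <- sampleData(profiles)
    groups <- factor(sd[[groupBy]])
    if (nlevels(groups) != 3L)
        stop("'", groupBy, "' must have exactly 3 levels")
    if (is(gapSites, "SummarizedExperiment"))
        gapSites <- SummarizedExperiment::rowRanges(gapSites)
    siteGene <- if (is.data.frame(gapSites)) gapSites$gene_id
        else mcols(gapSites)$gene_id
    rows <- list(); curves <- list()
    for (g in genes) {
        if (!g %in% names(profiles)) {
            message("gene '", g, "' has no depth profile: skipped")
            next
        }
        prof <- depthProfile(profiles, g)
        pos <- as.numeric(rownames(prof))
        gsg <- gapSites[which(siteGene == g), , drop = FALSE]
        kept <- restrictIntrons(pos, gsg)
        if (!length(kept)) {
            message("gene '", g, "': no position left after intron cut")
            next
        }
        prof <- prof[match(kept, pos), , drop = FALSE]
        gm <- groupMeanDepth(prof, groups)
        if (lowCoverageOn == "raw") {
            keepLC <- restrictLowCoverage(gm, params)
            if (!any(keepLC)) {
                message("gene '", g, "': unevaluable (all low coverage)")
                next
            }
            gm <- gm[, keepLC, drop = FALSE]
            kept <- kept[keepLC]
        }
        sm <- t(apply(gm, 1L, function(v)
            loessSmooth(kept, v, span = params@loessSpan)))
        colnames(sm) <- as.character(as.integer(kept))  # never scientific
        if (lowCoverageOn == "smoothed") {
            keepLC <- restrictLowCoverage(sm, params)
            if (!any(keepLC)) {
                message("gene '", g, "': unevaluable (all low coverage)")
                next
            }
            sm <- sm[, keepLC, drop = FALSE]
        }
        mf <- monotoneFraction(sm, params)
        rows[[g]] <- DataFrame(gene_id = g, direction = mf$direction,
                               monotoneFraction = mf$monotoneFraction,
                               nKept = mf$nKept, passes = mf$passes)
        if (keepCurves) curves[[g]] <- sm
    }
    res <- if (length(rows)) do.call(rbind, rows) else
        DataFrame(gene_id = character(0), direction = character(0),
                  monotoneFraction = numeric(0), nKept = integer(0),
                  passes = logical(0))
    rownames(res) <- NULL
    new("MaldrResults", results = res, parameters = params, curves = curves)
}
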