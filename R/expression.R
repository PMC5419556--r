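#' Counts-per-million matrix
#'
#' Plain ratio CPM: \code{count * 1e6 / sample total}, with no prior count
#' and no model-based shrinkage — deliberately, so that the between-donor
#' variability of expression values stays visible instead of being
#' moderated away.
#'
#' @param x gene-level counts: matrix or [GapSiteCounts-class]-like
#'   \code{SummarizedExperiment} (assay \code{"counts"}).
#' @param libSizes totals to normalise by; default column sums of \code{x}
#'   (so each column of the result sums to exactly 1e6).
#' @return numeric matrix of CPM values.
#' @examples
#' cpmMatrix(cbind(s1 = c(1, 1, 2)))
#' @export
cpmMatrix <- function(x, libSizes = NULL) {
    y <- if (is(x, "SummarizedExperiment")) gapSiteCounts(x) else as.matrix(x)
    if (is.null(libSizes)) libSizes <- colSums(y)
    if (any(libSizes <= 0))
        stop("zero-total sample(s): ",
             paste(colnames(y)[libSizes <= 0], collapse = ", "))
    sweep(y, 2L, 1e6 / libSizes, `*`)
}

#' Aggregate gap-site counts to gene level
#'
#' @param x a [GapSiteCounts-class] with gene assignments in rowData.
#' @param fun \code{"sum"} over a gene's gap-sites, or \code{"max"} (the
#'   gene-wise maximum of junction-crossing reads, the junction-based
#'   expression estimate).
#' @return integer matrix genes x samples.
#' @export
geneCounts <- function(x, fun = c("sum", "max")) {
    fun <- match.arg(fun)
    gid <- SummarizedExperiment::rowData(x)$gene_id
    if (is.null(gid)) gid <- mcols(SummarizedExperiment::rowRanges(x))$gene_id
    if (is.null(gid)) stop("no gene_id annotation on the gap-sites")
    cts <- gapSiteCounts(x)
    if (fun == "sum") return(rowsum(cts, gid))
    do.call(rbind, lapply(split(seq_along(gid), gid), function(i)
        apply(cts[i, , drop = FALSE], 2L, max)))
}

#' Pairwise expression correlation
#'
#' Pearson (default) correlation of per-gene expression values across
#' samples. Genes with zero variance have undefined correlations; these
#' are reported as \code{NA} with a \code{message()}.
#'
#' @param cpm CPM matrix (genes x samples).
#' @param genes optional subset of gene ids.
#' @param method \code{"pearson"} (default) or \code{"spearman"}.
#' @param log correlate \code{log(cpm + 1)} instead of raw CPM.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
pairwiseCorrelation <- function(cpm, genes = NULL,
                                method = c("pearson", "spearman"),
                                log = FALSE) {
    method <- match.arg(method)
    if (!is.null(genes)) {
        missing <- setdiff(genes, rownames(cpm))
        if (length(missing))
            stop("genes not in matrix: ", paste(missing, collapse = ", "))
        cpm <- cpm[genes, , drop = FALSE]
    }
    if (ncol(cpm) < 3L) stop("need at least 3 samples")
    m <- if (log) log(cpm + 1) else cpm
    noVar <- apply(m, 1L, function(v) stats::sd(v) == 0)
    if (any(noVar))
        message("zero-variance gene(s), correlation undefined: ",
                paste(rownames(m)[noVar], collapse = ", "))
    r <- suppressWarnings(cor(t(m), method = method))
    diag(r) <- 1
    r
}

# exact branch-and-bound maximum clique; candidates explored in
# lexicographic id order, so the first maximum found is the
# lexicographically smallest one
.maxCliqueExact <- function(adj, ids) {
    ord <- order(ids)
    adj <- adj[ord, ord, drop = FALSE]
    ids <- ids[ord]
    n <- length(ids)
    best <- integer(0)
    recurse <- function(clique, cand) {
        if (length(clique) > length(best)) best <<- clique
        while (length(cand)) {
            if (length(clique) + length(cand) <= length(best)) return()
            v <- cand[1L]
            cand <- cand[-1L]
            recurse(c(clique, v), cand[adj[v, cand]])
        }
    }
    recurse(integer(0), seq_len(n))
    ids[best]
}

#' Largest gene set with all pairwise correlations above a threshold
#'
#' Finds the maximum clique of the graph whose edges connect gene pairs
#' with correlation strictly above \code{threshold}. The search is exact
#' (branch and bound) and intended for the small candidate sets this
#' screen produces (it refuses inputs above 64 genes); ties between
#' maximum cliques are broken toward the lexicographically smallest set of
#' gene ids. This is the screen that isolates the tightly co-expressed
#' TGF-beta-related subset from the monotone-filter hit list.
#'
#' @param correlation symmetric correlation matrix with gene ids as
#'   dimnames.
#' @param threshold edge threshold, strict (default 0.8).
#' @return character vector of gene ids (possibly of length 1).
#' @export
correlatedSet <- function(correlation, threshold = 0.8) {
    stopifnot(is.matrix(correlation),
              nrow(correlation) == ncol(correlation))
    if (nrow(correlation) == 0L) return(character(0))
    if (nrow(correlation) > 64L)
        stop("exact clique search is limited to 64 genes")
    ids <- rownames(correlation) %||% as.character(seq_len(nrow(correlation)))
    adj <- correlation > threshold
    adj[is.na(adj)] <- FALSE
    diag(adj) <- FALSE
    adj <- adj & t(adj)
    .maxCliqueExact(adj, ids)
}

#' Direction summary of a differential-expression result
#'
#' Among significant features, counts those higher in the second group
#' (positive log2 fold change) and those higher in the first, with
#' integer-rounded percentages of the significant total. With the gender
#' factor this is the male-biased / female-biased split.
#'
#' @param results a test result table with \code{log2_fold_change} and
#'   \code{fdr} columns (e.g. from [nbGroupTest()]).
#' @param fdrThreshold significance cut, strict (default 0.1).
#' @return data.frame with columns \code{direction} (\code{"positive"} =
#'   higher in the second group level), \code{n}, \code{percent}; zero
#'   rows when nothing is significant.
#' @examples
#' res <- data.frame(log2_fold_change = c(rep(1, 95), rep(-1, 73)),
#'                   fdr = 0.01)
#' biasSummary(res)  # 57% / 43%
#' @export
biasSummary <- function(results, fdrThreshold = 0.1) {
    sig <- results[results$fdr < fdrThreshold, , drop = FALSE]
    if (!nrow(sig))
        return(data.frame(direction = character(0), n = integer(0),
                          percent = numeric(0)))
    nPos <- sum(sig$log2_fold_change > 0)
    nNeg <- sum(sig$log2_fold_change < 0)
    data.frame(direction = c("positive", "negative"),
               n = c(nPos, nNeg),
               percent = round(100 * c(nPos, nNeg) / nrow(sig)))
}

#' Significant DE genes per chromosome
#'
#' Plain reporting group-by (no statistics): how many significant genes,
#' split by fold-change direction, sit on each chromosome.
#'
#' @param results test result table with \code{gene_id},
#'   \code{log2_fold_change}, \code{fdr}.
#' @param geneChrom named character vector mapping gene id to chromosome.
#' @param fdrThreshold significance cut, strict (default 0.1).
#' @return data.frame \code{chrom}, \code{n_positive}, \code{n_negative}.
#' @export
deCountsByChromosome <- function(results, geneChrom, fdrThreshold = 0.1) {
    sig <- results[results$fdr < fdrThreshold, , drop = FALSE]
    ch <- geneChrom[sig$gene_id]
    up <- table(ch[sig$log2_fold_change > 0])
    dn <- table(ch[sig$log2_fold_change < 0])
    chroms <- sort(unique(c(names(up), names(dn))))
    cnt <- function(tb) {
        v <- as.integer(tb[chroms])
        ifelse(is.na(v), 0L, v)
    }
    data.frame(chrom = chroms, n_positive = cnt(up), n_negative = cnt(dn))
}

#' TGF-beta-related members of the reference age-MAR hit list
#'
#' The bundled table lists the genes of the 42-gene age-MAR result set of
#' the dermal fibroblast ageing cohort (the data set this filter was
#' developed on) that are TGF-beta related: 8 TGF-beta-regulated genes,
#' SMAD7 (part of the signalling cascade), two SMAD interactors and the
#' lncRNA MEG3.
#'
#' @return data.frame with columns \code{gene} and \code{category}.
#' @export
ageMarTgfbGenes <- function() {
    read.delim(system.file("extdata", "age_mar_tgfb_genes.tsv",
                           package = "maldr"))
}

#' @rdname ageMarTgfbGenes
#' @param totalGenes size of the full hit list the members come from
#'   (default 42, the reference result set).
#' @return for \code{tgfbMembershipSummary}: list with \code{nRelated},
#'   \code{totalGenes} and \code{percent} (share of the hit list).
#' @export
tgfbMembershipSummary <- function(totalGenes = 42) {
    g <- ageMarTgfbGenes()
    n <- length(unique(g$gene))
    list(nRelated = n, totalGenes = totalGenes,
         percent = 100 * n / totalGenes)
}
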