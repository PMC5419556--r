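#' @importFrom utils read.delim write.table head
NULL

# reference-consuming CIGAR operations
.REF_OPS <- c("M", "D", "N", "=", "X")

#' Extract gap-sites from gapped alignments
#'
#' Walks the CIGAR string of each alignment record and emits one gap-site
#' per N operation: \code{leftEnd} is the last aligned base before the gap,
#' \code{rightStart} the first aligned base after it (both 1-based
#' inclusive). All reads covering the same splicing event share these inner
#' border coordinates, which makes the pair \code{(chrom, leftEnd,
#' rightStart)} the identity of the event. A read with several N gaps
#' contributes one count to each of its gap-sites.
#'
#' @param alignments a data.frame with columns \code{chrom}, \code{pos}
#'   (1-based leftmost aligned position) and \code{cigar}, or a path to a
#'   BAM file (read via \pkg{GenomicAlignments} when installed).
#' @return data.frame with columns \code{chrom}, \code{left_end},
#'   \code{right_start}, \code{count}, one row per distinct gap-site,
#'   ordered by coordinate. Records without usable coordinates are skipped;
#'   their number is reported via \code{message()}.
#' @examples
#' aln <- data.frame(chrom = "chr1", pos = 1, cigar = "10M100N10M")
#' extractGapSites(aln)  # leftEnd 10, rightStart 111
#' @export
extractGapSites <- function(alignments) {
    if (is.character(alignments) && length(alignments) == 1L) {
        if (!requireNamespace("GenomicAlignments", quietly = TRUE))
            stop("reading BAM requires the GenomicAlignments package")
        ga <- GenomicAlignments::readGAlignments(alignments)
        alignments <- data.frame(
            chrom = as.character(GenomicAlignments::seqnames(ga)),
            pos = GenomicAlignments::start(ga),
            cigar = GenomicAlignments::cigar(ga))
    }
    stopifnot(all(c("chrom", "pos", "cigar") %in% colnames(alignments)))
    bad <- is.na(alignments$pos) | is.na(alignments$chrom) |
        is.na(alignments$cigar)
    if (any(bad)) {
        message(sum(bad), " record(s) without reference coordinates skipped")
        alignments <- alignments[!bad, , drop = FALSE]
    }
    chromHits <- character(0)
    leHits <- integer(0)
    rsHits <- integer(0)
    tokList <- regmatches(alignments$cigar,
                          gregexpr("\\d+[MIDNSHP=X]", alignments$cigar))
    for (r in seq_len(nrow(alignments))) {
        toks <- tokList[[r]]
        if (!length(toks)) next
        lens <- as.integer(sub("[A-Z=]$", "", toks))
        ops <- substr(toks, nchar(toks), nchar(toks))
        ref <- as.integer(alignments$pos[r])
        for (j in seq_along(ops)) {
            if (ops[j] == "N") {
                chromHits <- c(chromHits, alignments$chrom[r])
                leHits <- c(leHits, ref - 1L)
                rsHits <- c(rsHits, ref + lens[j])
            }
            if (ops[j] %in% .REF_OPS) ref <- ref + lens[j]
        }
    }
    if (!length(leHits))
        return(data.frame(chrom = character(0), left_end = integer(0),
                          right_start = integer(0), count = integer(0)))
    df <- data.frame(chrom = chromHits, left_end = leHits,
                     right_start = rsHits)
    agg <- aggregate(list(count = rep(1L, nrow(df))),
                     df[c("chrom", "left_end", "right_start")], sum)
    agg <- agg[order(agg$chrom, agg$left_end, agg$right_start), , drop = FALSE]
    rownames(agg) <- NULL
    agg
}

#' Keep gap-sites present in every sample
#'
#' The first filter of the junction pipeline: a splicing event only enters
#' the analysis when at least one supporting read is seen in each sample.
#'
#' @param x a [GapSiteCounts-class] object (or a plain counts matrix).
#' @return the object subset to rows with \code{count >= 1} in all samples.
#' @export
filterUbiquitous <- function(x) {
    cts <- if (is(x, "SummarizedExperiment")) gapSiteCounts(x) else x
    keep <- rowSums(cts >= 1L) == ncol(cts)
    x[keep, , drop = FALSE]
}

#' Match gap-sites against annotated introns
#'
#' A gap-site is annotated iff its (chrom, leftEnd, rightStart) triple
#' exactly equals the boundaries of an intron of some gene model: leftEnd
#' must be the last base of the upstream exon and rightStart the first base
#' of the downstream exon. Off-by-one coordinates do not match. Sites whose
#' boundaries coincide with introns of several genes are assigned to all of
#' them and flagged ambiguous.
#'
#' @param sites a gap-site \code{GRanges}, a [GapSiteCounts-class], or a
#'   data.frame with \code{chrom}, \code{left_end}, \code{right_start}.
#' @param geneModels exon \code{GRangesList}.
#' @return the annotated subset of \code{sites}, with metadata columns
#'   \code{gene_id} (first matching gene), \code{gene_ids}
#'   (comma-separated, all matches) and \code{ambiguous}.
#' @export
matchAnnotation <- function(sites, geneModels) {
    ann <- annotatedGapSites(geneModels)
    annKey <- paste(as.character(seqnames(ann)), start(ann), end(ann))
    if (is.data.frame(sites)) {
        key <- paste(sites$chrom, sites$left_end, sites$right_start)
        chroms <- unique(sites$chrom)
    } else {
        gr <- if (is(sites, "SummarizedExperiment"))
            SummarizedExperiment::rowRanges(sites) else sites
        key <- paste(as.character(seqnames(gr)), start(gr), end(gr))
        chroms <- unique(as.character(seqnames(gr)))
    }
    if (length(key) && !any(chroms %in% unique(as.character(seqnames(ann)))))
        stop("no chromosome name shared between gap-sites (",
             paste(head(chroms, 3), collapse = ", "),
             ") and annotation - naming convention clash?")
    geneByKey <- split(mcols(ann)$gene_id, annKey)
    hit <- key %in% names(geneByKey)
    genes <- geneByKey[key[hit]]
    gene1 <- vapply(genes, function(g) sort(g)[1L], "")
    allg <- vapply(genes, function(g) paste(sort(unique(g)), collapse = ","), "")
    amb <- lengths(lapply(genes, unique)) > 1L
    out <- sites[hit, , drop = FALSE]
    if (is.data.frame(out)) {
        out$gene_id <- unname(gene1)
        out$gene_ids <- unname(allg)
        out$ambiguous <- unname(amb)
    } else if (is(out, "SummarizedExperiment")) {
        SummarizedExperiment::rowData(out)$gene_id <- unname(gene1)
        SummarizedExperiment::rowData(out)$gene_ids <- unname(allg)
        SummarizedExperiment::rowData(out)$ambiguous <- unname(amb)
    } else {
        mcols(out)$gene_id <- unname(gene1)
        mcols(out)$gene_ids <- unname(allg)
        mcols(out)$ambiguous <- unname(amb)
    }
    out
}

#' Assemble a gap-site count matrix across samples
#'
#' @param maps named list (by sample id) of per-sample gap-site tables as
#'   returned by [extractGapSites()].
#' @param sites the gap-sites to keep as rows: a \code{GRanges} (e.g. the
#'   annotated set) or a data.frame with \code{chrom}, \code{left_end},
#'   \code{right_start}; sites absent from a sample's map get count 0.
#' @param sampleData per-sample annotation; rownames (or a
#'   \code{sample_id} column) must cover \code{names(maps)}.
#' @return a [GapSiteCounts-class] object.
#' @export
assembleCountMatrix <- function(maps, sites, sampleData = NULL) {
    if (is.null(names(maps)) || anyDuplicated(names(maps)))
        stop("'maps' must be uniquely named by sample id")
    if (is.data.frame(sites)) {
        gr <- GRanges(sites$chrom, IRanges(sites$left_end, sites$right_start))
        if (!is.null(sites$gene_id)) mcols(gr)$gene_id <- sites$gene_id
        if (!is.null(sites$ambiguous)) mcols(gr)$ambiguous <- sites$ambiguous
        sites <- gr
    }
    key <- paste(as.character(seqnames(sites)), start(sites), end(sites))
    counts <- vapply(names(maps), function(s) {
        m <- maps[[s]]
        mk <- paste(m$chrom, m$left_end, m$right_start)
        as.integer(m$count[match(key, mk)])
    }, integer(length(sites)))
    counts[is.na(counts)] <- 0L
    counts <- matrix(counts, nrow = length(sites),
                     dimnames = list(NULL, names(maps)))
    if (!is.null(mcols(sites)$gene_id))
        rownames(counts) <- make.unique(paste0(mcols(sites)$gene_id, ".gs"))
    else
        rownames(counts) <- gsub(" ", ":", key)
    if (is.null(sampleData))
        sampleData <- DataFrame(row.names = names(maps))
    else {
        sampleData <- as(sampleData, "DataFrame")
        if (is.null(rownames(sampleData)) && !is.null(sampleData$sample_id))
            rownames(sampleData) <- sampleData$sample_id
        sampleData <- sampleData[names(maps), , drop = FALSE]
    }
    GapSiteCounts(counts, sites, sampleData)
}

#' Export gap-sites as BED
#'
#' Converts the internal 1-based inclusive coordinates to BED's 0-based
#' half-open convention via \pkg{rtracklayer}.
#'
#' @param sites gap-site \code{GRanges} (or [GapSiteCounts-class]).
#' @param path output file.
#' @export
writeGapSiteBed <- function(sites, path) {
    if (is(sites, "SummarizedExperiment"))
        sites <- SummarizedExperiment::rowRanges(sites)
    gr <- GRanges(seqnames(sites), IRanges(start(sites), end(sites)),
                  strand = strand(sites))
    if (!is.null(mcols(sites)$gene_id))
        names(gr) <- make.unique(mcols(sites)$gene_id)
    rtracklayer::export(gr, path, format = "bed")
    invisible(path)
}

#' Write / read a gap-site count matrix as TSV
#'
#' Round-trip safe: coordinates, gene assignment and all counts survive a
#' write/read cycle exactly.
#'
#' @param x a [GapSiteCounts-class] object.
#' @param path TSV path.
#' @export
writeCountMatrixTsv <- function(x, path) {
    gr <- SummarizedExperiment::rowRanges(x)
    df <- data.frame(chrom = as.character(seqnames(gr)),
                     left_end = start(gr), right_start = end(gr))
    if (!is.null(mcols(gr)$gene_id)) df$gene_id <- mcols(gr)$gene_id
    df <- cbind(df, as.data.frame(gapSiteCounts(x), check.names = FALSE))
    writeTsv(df, path)
}

#' @rdname writeCountMatrixTsv
#' @param sampleData optional per-sample annotation attached on read.
#' @export
readCountMatrixTsv <- function(path, sampleData = NULL) {
    df <- read.delim(path, check.names = FALSE)
    meta <- intersect(c("chrom", "left_end", "right_start", "gene_id"),
                      colnames(df))
    cts <- as.matrix(df[, setdiff(colnames(df), meta), drop = FALSE])
    gr <- GRanges(df$chrom, IRanges(df$left_end, df$right_start))
    if ("gene_id" %in% meta) mcols(gr)$gene_id <- df$gene_id
    rownames(cts) <- if ("gene_id" %in% meta)
        make.unique(paste0(df$gene_id, ".gs")) else
        paste0(df$chrom, ":", df$left_end, ":", df$right_start)
    GapSiteCounts(cts, gr, sampleData)
}
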