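#' @importFrom stats cor mad median
NULL

#' k-mer spectrum of a read set
#'
#' Counts every overlapping k-mer on the forward strand of every read and
#' normalises to relative frequencies. Windows containing non-ACGT symbols
#' (e.g. N calls) are skipped. Used as a cheap whole-sample fingerprint:
#' disturbed libraries (contamination, strong GC shifts) stand out in the
#' 6-mer spectrum before any alignment is done.
#'
#' @param reads a character vector, [Biostrings::DNAStringSet-class], or
#'   path to a FASTQ/FASTQ.gz file.
#' @param k word length (default 6, i.e. a 4096-dimensional spectrum).
#' @return numeric vector of length \code{4^k}, named by k-mer, summing to
#'   1; attribute \code{k} carries the word length and \code{nKmers} the
#'   total count.
#' @examples
#' kmerSpectrum("ACGT", k = 4)["ACGT"]
#' @export
kmerSpectrum <- function(reads, k = 6L) {
    k <- as.integer(k)
    if (k < 1L) stop("'k' must be >= 1")
    if (is.character(reads) && length(reads) == 1L && file.exists(reads))
        reads <- Biostrings::readDNAStringSet(reads, format = "fastq")
    if (!is(reads, "DNAStringSet"))
        reads <- Biostrings::DNAStringSet(reads)
    if (length(reads) == 0L) stop("empty read set")
    counts <- colSums(Biostrings::oligonucleotideFrequency(reads, width = k))
    total <- sum(counts)
    if (total == 0)
        stop("no countable ", k, "-mers: k exceeds every read length ",
             "(or reads are all-ambiguous)")
    structure(counts / total, k = k, nKmers = total)
}

#' Pairwise distances between k-mer spectra
#'
#' Distance between two samples is \code{1 - cor(log(f + p))} with pseudo-
#' frequency \code{p = 1/(4^k * 10)}: the log transform keeps rare words
#' from being drowned out by the most abundant ones.
#'
#' @param spectra named list of spectra from [kmerSpectrum()], all with the
#'   same \code{k}.
#' @return symmetric distance matrix with zero diagonal.
#' @export
spectrumDistanceMatrix <- function(spectra) {
    stopifnot(length(spectra) >= 1L)
    ks <- vapply(spectra, function(s) attr(s, "k"), 0L)
    if (length(unique(ks)) != 1L)
        stop("all spectra must share the same k (got: ",
             paste(unique(ks), collapse = ", "), ")")
    pseudo <- 1 / (4^ks[1L] * 10)
    lf <- vapply(spectra, function(s) log(as.numeric(s) + pseudo),
                 numeric(4^ks[1L]))
    d <- 1 - cor(lf)
    d[abs(d) < 1e-12] <- 0
    dimnames(d) <- list(names(spectra), names(spectra))
    d
}

#' Flag disturbed samples from spectrum distances
#'
#' A sample is flagged when its median distance to all other samples
#' exceeds the cohort median of that statistic by more than
#' \code{thresholdMad} MADs — a robust stand-in for the visual exclusion
#' of disturbed libraries. With \code{thresholdMad = Inf} nothing is
#' flagged.
#'
#' @param distances symmetric matrix from [spectrumDistanceMatrix()].
#' @param thresholdMad number of MADs above the cohort median (default 3.5).
#' @return character vector of flagged sample ids (possibly empty).
#' @export
flagOutlierSamples <- function(distances, thresholdMad = 3.5) {
    stopifnot(is.matrix(distances), nrow(distances) == ncol(distances))
    n <- nrow(distances)
    if (n < 3L) stop("need at least 3 samples to call outliers")
    medDist <- vapply(seq_len(n),
                      function(i) median(distances[i, -i]), 0)
    cutoff <- median(medDist) + thresholdMad * mad(medDist)
    if (is.nan(cutoff)) cutoff <- Inf   # MAD 0 with infinite threshold
    ids <- rownames(distances) %||% as.character(seq_len(n))
    ids[medDist > cutoff]
}
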