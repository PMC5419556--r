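#' Write a normalised TSV
#'
#' All pipeline outputs go through this writer so that manifests are
#' reproducible across platforms: LF line endings, no quoting, numeric
#' columns formatted to 6 significant digits without scientific notation.
#'
#' @param df data.frame-like object.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeTsv <- function(df, path) {
    df <- as.data.frame(df)
    for (j in seq_along(df)) {
        if (is.double(df[[j]]))
            df[[j]] <- format(signif(df[[j]], 6), trim = TRUE,
                              scientific = FALSE)
    }
    con <- file(path, open = "wb")   # binary: forces LF on every platform
    on.exit(close(con))
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                eol = "\n")
    invisible(path)
}

#' Write depth profiles as bedGraph
#'
#' One bedGraph per sample is wasteful at cohort scale; this writes a
#' per-gene TSV track (position, one depth column per sample) which
#' round-trips losslessly, plus optionally a true bedGraph for one sample.
#'
#' @param profiles a [DepthProfileList-class].
#' @param dir output directory (one file per gene).
#' @return the directory, invisibly.
#' @export
writeDepthTsv <- function(profiles, dir) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (g in names(profiles)) {
        m <- depthProfile(profiles, g)
        df <- data.frame(position = as.integer(rownames(m)), m,
                         check.names = FALSE)
        writeTsv(df, file.path(dir, paste0(g, ".depth.tsv")))
    }
    invisible(dir)
}

#' @rdname writeDepthTsv
#' @param sampleData sample annotation to attach.
#' @export
readDepthTsv <- function(dir, sampleData) {
    files <- sort(list.files(dir, pattern = "\\.depth\\.tsv$",
                             full.names = TRUE))
    profiles <- lapply(files, function(f) {
        df <- read.delim(f, check.names = FALSE)
        m <- as.matrix(df[, -1L, drop = FALSE])
        storage.mode(m) <- "integer"
        rownames(m) <- df$position
        m
    })
    names(profiles) <- sub("\\.depth\\.tsv$", "", basename(files))
    DepthProfileList(profiles, sampleData)
}
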