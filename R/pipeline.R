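#' @importFrom tools md5sum
NULL

#' Run the full synthetic-cohort analysis pipeline
#'
#' Orchestrates the six stages end to end on generated data: (1) simulate
#' gene models, cohort, gap-site counts, depth profiles and small FASTQ
#' files; (2) k-mer spectrum QC with outlier flagging; (3) gap-site
#' extraction from gapped-alignment records, ubiquitous-presence filter,
#' annotation matching and count-matrix assembly; (4) NB quasi-likelihood
#' pre-filter on the youngest vs oldest age group; (5) the MALDR depth
#' filter over the pre-selected genes; (6) CPM summaries, correlation-set
#' search and bias summary. Every output file is hashed into a manifest so
#' a rerun with the same configuration and seed reproduces identical
#' hashes.
#'
#' @param outDir output directory (created if missing).
#' @param genomeSpec a [SyntheticGenomeSpec-class].
#' @param cohort a [CohortSpec-class].
#' @param effects list of [EffectSpec-class] objects.
#' @param params a [MaldrParameters-class].
#' @param seed integer seed driving every random stage.
#' @param dispersion NB dispersion of the simulated counts.
#' @param qcReads reads per simulated FASTQ sample (QC stage fixture).
#' @param dropFlagged drop QC-flagged samples before testing (default
#'   TRUE).
#' @return invisibly, a list with the per-stage outputs and the manifest
#'   data.frame (stage, file, md5).
#' @seealso [verifyManifest()], [pipelineReport()]
#' @export
runPipeline <- function(outDir,
                        genomeSpec = syntheticGenomeSpec(nGenes = 20),
                        cohort = cohortSpec(),
                        effects = list(),
                        params = MaldrParameters(),
                        seed = 1L,
                        dispersion = 0.1,
                        qcReads = 100L,
                        dropFlagged = TRUE) {
    seed <- as.integer(seed)
    if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
    manifest <- data.frame(stage = character(0), file = character(0),
                           md5 = character(0))
    reg <- function(stage, path) {
        manifest <<- rbind(manifest, data.frame(
            stage = stage, file = basename(path),
            md5 = unname(md5sum(path))))
        path
    }

    ## stage 1: simulate ---------------------------------------------------
    models <- generateGeneModels(genomeSpec, seed = seed)
    samples <- simulateCohort(cohort, seed = seed + 1L)
    expr <- simulateExpression(names(models), samples, effects,
                               dispersion = dispersion,
                               donorSigma = cohort@donorSigma, seed = seed + 2L)
    gsc <- simulateGapSiteCounts(models, samples, effects,
                                 dispersion = dispersion, seed = seed + 2L,
                                 expression = expr)
    profiles <- simulateDepthProfiles(models, samples, effects,
                                      dispersion = dispersion,
                                      seed = seed + 2L, expression = expr)
    reg("simulate", writeGeneModelsGtf(models, file.path(outDir, "gene_models.gtf")))
    reg("simulate", writeTsv(as.data.frame(samples),
                             file.path(outDir, "samples.tsv")))
    fqDir <- file.path(outDir, "fastq")
    if (!dir.exists(fqDir)) dir.create(fqDir)
    gc <- seq(0.40, 0.60, length.out = nrow(samples))  # benign GC spread
    for (i in seq_len(nrow(samples))) {
        p <- (1 - gc[i]) / 2
        simulateFastq(file.path(fqDir, paste0(rownames(samples)[i], ".fastq")),
                      nReads = qcReads,
                      baseProb = c(A = p, C = gc[i] / 2, G = gc[i] / 2, T = p),
                      seed = seed + 100L + i)
    }

    ## stage 2: qc ---------------------------------------------------------
    spectra <- lapply(rownames(samples), function(s)
        kmerSpectrum(file.path(fqDir, paste0(s, ".fastq")), k = 6L))
    names(spectra) <- rownames(samples)
    dmat <- spectrumDistanceMatrix(spectra)
    flagged <- flagOutlierSamples(dmat)
    reg("qc", writeTsv(data.frame(sample_id = rownames(samples),
                                  flagged = rownames(samples) %in% flagged),
                       file.path(outDir, "qc_flags.tsv")))
    keep <- if (dropFlagged) setdiff(rownames(samples), flagged)
        else rownames(samples)
    samples <- samples[keep, , drop = FALSE]

    ## stage 3: gap-sites --------------------------------------------------
    # emit gapped alignment records per sample from the simulated junction
    # counts, then run the extraction path on them
    sites <- SummarizedExperiment::rowRanges(gsc)
    cts <- gapSiteCounts(gsc)[, keep, drop = FALSE]
    maps <- lapply(keep, function(s) {
        n <- cts[, s]
        data.frame(chrom = rep(as.character(seqnames(sites)), n),
                   pos = rep(start(sites) - 9L, n),
                   cigar = rep(sprintf("10M%dN10M", width(sites) - 2L), n))
    })
    names(maps) <- keep
    maps <- lapply(maps, extractGapSites)
    ubiq <- filterUbiquitous(assembleCountMatrix(
        maps, annotatedGapSites(models), samples))
    ann <- matchAnnotation(ubiq, models)
    reg("gapsites", writeCountMatrixTsv(ann, file.path(outDir, "gapsite_counts.tsv")))

    ## stage 4: prefilter --------------------------------------------------
    grp <- SummarizedExperiment::colData(ann)$age_group
    lv <- levels(grp)
    two <- factor(ifelse(grp == lv[1L], lv[1L],
                         ifelse(grp == lv[length(lv)], lv[length(lv)], NA)),
                  levels = c(lv[1L], lv[length(lv)]))
    res <- nbGroupTest(ann, two)
    sel <- selectPrefilteredGenes(res, params)
    reg("prefilter", writeTsv(as.data.frame(res),
                              file.path(outDir, "prefilter.tsv")))
    reg("prefilter", writeTsv(data.frame(gene_id = sel),
                              file.path(outDir, "prefilter_genes.tsv")))

    ## stage 5: maldr ------------------------------------------------------
    profiles <- DepthProfileList(
        lapply(profiles@profiles, function(m) m[, keep, drop = FALSE]),
        samples)
    mres <- runMaldr(sel, profiles, ann, params)
    reg("maldr", writeTsv(as.data.frame(mres),
                          file.path(outDir, "maldr_results.tsv")))
    curves <- smoothedCurves(mres)
    if (length(curves)) {
        cdf <- do.call(rbind, lapply(names(curves), function(g)
            data.frame(gene_id = g,
                       position = as.integer(colnames(curves[[g]])),
                       t(curves[[g]]), check.names = FALSE)))
        reg("maldr", writeTsv(cdf, file.path(outDir, "maldr_curves.tsv")))
    }

    ## stage 6: express ----------------------------------------------------
    gcts <- geneCounts(ann, fun = "sum")
    cpm <- cpmMatrix(gcts)
    reg("express", writeTsv(data.frame(gene_id = rownames(cpm), cpm,
                                       check.names = FALSE),
                            file.path(outDir, "cpm.tsv")))
    passSet <- maldrPass(mres)
    cset <- character(0)
    if (length(passSet) >= 2L) {
        pc <- pairwiseCorrelation(cpm, intersect(passSet, rownames(cpm)))
        cset <- correlatedSet(pc, params@correlationThreshold)
    } else if (length(passSet) == 1L) cset <- passSet
    reg("express", writeTsv(data.frame(gene_id = cset),
                            file.path(outDir, "correlated_set.tsv")))
    gres <- nbGroupTest(ann, factor(samples$gender))
    bias <- biasSummary(gres, params@prefilterFdr)
    reg("express", writeTsv(bias, file.path(outDir, "gender_bias.tsv")))

    writeTsv(manifest, file.path(outDir, "manifest.tsv"))
    invisible(list(samples = samples, counts = ann, prefilter = res,
                   selected = sel, maldr = mres, cpm = cpm,
                   correlatedSet = cset, genderBias = bias,
                   flagged = flagged, manifest = manifest,
                   outDir = outDir))
}

#' Verify a pipeline manifest
#'
#' Recomputes the MD5 of every file listed in \code{manifest.tsv} and
#' compares; tampered or missing intermediates are reported.
#'
#' @param outDir a directory written by [runPipeline()].
#' @return named logical vector, one entry per manifest file; \code{FALSE}
#'   for hash mismatches or missing files.
#' @export
verifyManifest <- function(outDir) {
    mf <- read.delim(file.path(outDir, "manifest.tsv"))
    cur <- unname(md5sum(file.path(outDir, mf$file)))
    ok <- !is.na(cur) & cur == mf$md5
    names(ok) <- mf$file
    ok
}

#' Human-readable pipeline report
#'
#' Deterministic text summary of a finished run: gene counts per stage,
#' the monotone-filter pass list, the correlated set, the bias summary.
#'
#' @param run the list returned by [runPipeline()] (or its \code{outDir}).
#' @return character vector of report lines (also printed).
#' @export
pipelineReport <- function(run) {
    if (is.character(run)) {
        outDir <- run
        pre <- read.delim(file.path(outDir, "prefilter_genes.tsv"))
        mres <- read.delim(file.path(outDir, "maldr_results.tsv"))
        cset <- read.delim(file.path(outDir, "correlated_set.tsv"))
        bias <- read.delim(file.path(outDir, "gender_bias.tsv"))
        qc <- read.delim(file.path(outDir, "qc_flags.tsv"))
        sel <- pre$gene_id
        pass <- mres$gene_id[mres$passes]
        flagged <- qc$sample_id[qc$flagged]
    } else {
        sel <- run$selected
        mres <- as.data.frame(run$maldr)
        pass <- maldrPass(run$maldr)
        cset <- data.frame(gene_id = run$correlatedSet)
        bias <- run$genderBias
        flagged <- run$flagged
    }
    lines <- c(
        "== maldr pipeline report ==",
        sprintf("QC-flagged samples:        %d (%s)", length(flagged),
                if (length(flagged)) paste(flagged, collapse = ", ") else "none"),
        sprintf("Pre-filter genes (FDR):    %d", length(sel)),
        sprintf("Genes evaluated by MALDR:  %d", nrow(mres)),
        sprintf("Monotone (age-MAR) genes:  %d gene%s", length(pass),
                if (length(pass) == 1L) "" else "s"),
        if (length(pass)) sprintf("  pass list: %s", paste(pass, collapse = ", ")),
        sprintf("Correlated set (r-screen): %d gene%s", nrow(cset),
                if (nrow(cset) == 1L) "" else "s"),
        if (nrow(bias) > 0)
            sprintf("Gender bias: %d positive (%d%%) / %d negative (%d%%)",
                    bias$n[1], bias$percent[1], bias$n[2], bias$percent[2])
        else "Gender bias: 0 significant genes")
    lines <- lines[!vapply(lines, is.null, TRUE)]
    cat(lines, sep = "\n")
    invisible(lines)
}
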