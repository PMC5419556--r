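test_that("gap-site extraction does the CIGAR arithmetic", {
    # 10M100N10M starting at 1: last aligned base 10, gap of 100,
    # first aligned base after the gap at 111
    one <- extractGapSites(data.frame(chrom = "chr1", pos = 1,
                                      cigar = "10M100N10M"))
    expect_equal(one$left_end, 10)
    expect_equal(one$right_start, 111)
    expect_equal(one$count, 1)

    # a doubly gapped read contributes to both its gap-sites
    two <- extractGapSites(data.frame(chrom = "c", pos = 1,
                                      cigar = "5M50N5M50N5M"))
    expect_equal(nrow(two), 2L)
    expect_equal(two$left_end, c(5, 60))
    expect_equal(two$right_start, c(56, 111))
    expect_equal(two$count, c(1, 1))

    # insertions do not consume reference, deletions do, clips do not
    mix <- extractGapSites(data.frame(chrom = "c", pos = 11,
                                      cigar = "3S5M2I3M1D2M40N4M"))
    expect_equal(mix$left_end, 11 + 5 + 3 + 1 + 2 - 1)
    expect_equal(mix$right_start, 21 + 40 + 1)

    # ungapped reads give an empty map
    expect_equal(nrow(extractGapSites(data.frame(chrom = "c", pos = 1,
                                                 cigar = "20M"))), 0L)

    # records without coordinates are skipped and reported
    expect_message(
        res <- extractGapSites(data.frame(chrom = c("c", NA),
                                          pos = c(1, NA),
                                          cigar = c("5M10N5M", "5M10N5M"))),
        "skipped")
    expect_equal(sum(res$count), 1)
})

test_that("extraction is additive over read subsets", {
    gm <- generateGeneModels(syntheticGenomeSpec(nGenes = 5), seed = 2)
    aln <- simulateGappedAlignments(gm, nPerJunction = 4, seed = 3)
    full <- extractGapSites(aln)
    half1 <- extractGapSites(aln[seq(1, nrow(aln), 2), ])
    half2 <- extractGapSites(aln[seq(2, nrow(aln), 2), ])
    key <- function(d) paste(d$chrom, d$left_end, d$right_start)
    merged <- merge(half1, half2, by = c("chrom", "left_end", "right_start"),
                    all = TRUE)
    merged[is.na(merged)] <- 0
    merged$count <- merged$count.x + merged$count.y
    expect_equal(merged$count[match(key(full), key(merged))], full$count)
})

test_that("ubiquitous-presence filter keeps only sites seen in every sample", {
    counts <- rbind(everywhere = c(1, 1, 1, 1),
                    almost     = c(3, 5, 0, 2),   # 53/54-style dropout
                    nowhere    = c(0, 0, 0, 0))
    gr <- GenomicRanges::GRanges("c", IRanges::IRanges(c(10, 50, 90),
                                                       c(20, 60, 100)))
    gsc <- GapSiteCounts(counts, gr,
                         S4Vectors::DataFrame(row.names = paste0("s", 1:4)))
    kept <- filterUbiquitous(gsc)
    expect_equal(rownames(kept), "everywhere")

    # empty intersection is allowed
    none <- filterUbiquitous(gsc[2:3, ])
    expect_equal(nrow(none), 0L)
})

test_that("annotation matching is exact on intron boundaries", {
    gm <- generateGeneModels(syntheticGenomeSpec(nGenes = 2,
                                                 exonsPerGene = c(2, 2)),
                             seed = 4)
    ann <- annotatedGapSites(gm)
    le <- GenomicRanges::start(ann)[1]
    rs <- GenomicRanges::end(ann)[1]

    sites <- data.frame(chrom = "chrS",
                        left_end = c(le, le + 1),
                        right_start = c(rs, rs + 1))
    hit <- matchAnnotation(sites, gm)
    expect_equal(nrow(hit), 1L)   # the off-by-one twin does not match
    expect_equal(hit$gene_id, "g0001")

    # chromosome naming clash is a hard error
    expect_error(matchAnnotation(data.frame(chrom = "1", left_end = le,
                                            right_start = rs), gm),
                 "naming")
})

test_that("simulated junction reads are recovered exactly, noise is not", {
    gm <- generateGeneModels(syntheticGenomeSpec(nGenes = 10,
                                                 exonsPerGene = c(3, 3)),
                             seed = 5)  # 20 annotated introns
    aln <- simulateGappedAlignments(gm, nPerJunction = 2, noiseSites = 5,
                                    seed = 6)
    sites <- extractGapSites(aln)
    expect_gte(nrow(sites), 25L - 1L)  # noise may rarely collide
    ann <- matchAnnotation(sites, gm)
    expect_equal(nrow(ann), 20L)
    expect_equal(sort(unique(ann$gene_id)), sort(names(gm)))
    expect_true(all(ann$count == 2))
})

test_that("count-matrix assembly preserves totals, order and round-trips", {
    gm <- generateGeneModels(syntheticGenomeSpec(nGenes = 3,
                                                 exonsPerGene = c(2, 2)),
                             seed = 7)
    samples <- paste0("s", 1:4)
    maps <- lapply(1:4, function(i)
        extractGapSites(simulateGappedAlignments(gm, nPerJunction = i,
                                                 seed = i)))
    names(maps) <- samples
    gsc <- assembleCountMatrix(maps, annotatedGapSites(gm),
                               S4Vectors::DataFrame(row.names = samples))
    expect_equal(dim(gsc), c(3L, 4L))
    expect_equal(unname(colSums(gapSiteCounts(gsc))),
                 vapply(maps, function(m) sum(m$count), 0, USE.NAMES = FALSE))

    # permuting the sample maps permutes columns only
    gsc2 <- assembleCountMatrix(maps[c(3, 1, 4, 2)], annotatedGapSites(gm),
                                S4Vectors::DataFrame(
                                    row.names = samples[c(3, 1, 4, 2)]))
    expect_equal(gapSiteCounts(gsc2), gapSiteCounts(gsc)[, c(3, 1, 4, 2)])

    expect_error(assembleCountMatrix(setNames(maps, rep("s1", 4)),
                                     annotatedGapSites(gm)),
                 "uniquely named")

    # TSV round trip preserves coordinates, genes and counts
    f <- tempfile(fileext = ".tsv")
    ann <- matchAnnotation(gsc, gm)
    writeCountMatrixTsv(ann, f)
    back <- readCountMatrixTsv(f)
    expect_equal(gapSiteCounts(back), gapSiteCounts(ann))
    expect_equal(leftEnd(back), leftEnd(ann))
    expect_equal(rightStart(back), rightStart(ann))

    # BED export is written (0-based half-open handled by rtracklayer)
    bed <- tempfile(fileext = ".bed")
    writeGapSiteBed(ann, bed)
    fields <- strsplit(readLines(bed)[1], "\t")[[1]]
    expect_equal(as.integer(fields[2]), leftEnd(ann)[1] - 1L)
    expect_equal(as.integer(fields[3]), rightStart(ann)[1])
})
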