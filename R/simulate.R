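#' @importFrom stats rpois rgamma rnorm runif rnbinom
NULL

#' Constructors for simulation specifications
#'
#' Thin validated constructors for the three specification classes of the
#' synthetic-data generator. See the class pages for slot semantics and
#' defaults.
#'
#' @param nGenes,exonsPerGene,exonLen,intronLen,chrom,chromLen see
#'   [SyntheticGenomeSpec-class].
#' @return a validated specification object.
#' @examples
#' syntheticGenomeSpec(nGenes = 5, exonsPerGene = c(2, 2))
#' @export
syntheticGenomeSpec <- function(nGenes = 10, exonsPerGene = c(4, 6),
                                exonLen = c(100, 250),
                                intronLen = c(200, 600),
                                chrom = "chrS", chromLen = 1e7) {
    new("SyntheticGenomeSpec", nGenes = as.integer(nGenes),
        exonsPerGene = as.integer(exonsPerGene),
        exonLen = as.integer(exonLen), intronLen = as.integer(intronLen),
        chrom = chrom, chromLen = as.integer(chromLen))
}

#' @rdname syntheticGenomeSpec
#' @param nDonors,ageGroups,nFemale,locations,libSizeRange,donorSigma see
#'   [CohortSpec-class].
#' @export
cohortSpec <- function(nDonors = 27,
                       ageGroups = NULL,
                       nFemale = NULL,
                       locations = c("sun_exposed", "sun_protected"),
                       libSizeRange = c(18e6, 30e6),
                       donorSigma = 0.3) {
    nDonors <- as.integer(nDonors)
    if (is.null(ageGroups)) {
        base <- nDonors %/% 3L
        extra <- nDonors %% 3L
        ageGroups <- data.frame(
            group = c("Young", "Middle", "Old"),
            minAge = c(18L, 35L, 60L), maxAge = c(25L, 49L, 67L),
            nDonors = base + c(extra, 0L, 0L))
    }
    if (is.null(nFemale))  # 13/27 of the reference cohort, rounded down
        nFemale <- as.integer(floor(nDonors * 13 / 27))
    new("CohortSpec", nDonors = nDonors, ageGroups = ageGroups,
        nFemale = as.integer(nFemale), locations = locations,
        libSizeRange = libSizeRange, donorSigma = donorSigma)
}

#' @rdname syntheticGenomeSpec
#' @param geneId,kind,ratio,outlierDonors,outlierFold see
#'   [EffectSpec-class].
#' @export
effectSpec <- function(geneId, kind = "null", ratio = 1,
                       outlierDonors = character(0), outlierFold = 1) {
    new("EffectSpec", geneId = geneId, kind = kind, ratio = ratio,
        outlierDonors = outlierDonors, outlierFold = outlierFold)
}

#' Generate synthetic gene models
#'
#' Lays out \code{nGenes} non-overlapping multi-exon gene models on an
#' artificial chromosome. Every intron between adjacent exons defines
#' exactly one annotated gap-site, mirroring how annotated splice sites
#' anchor the junction-count filter on real data.
#'
#' @param spec a [SyntheticGenomeSpec-class].
#' @param seed integer seed; identical spec + seed reproduce the layout
#'   exactly.
#' @return a named [GenomicRanges::GRangesList-class] of exons, one element
#'   per gene, ordered along the chromosome.
#' @seealso [annotatedGapSites()], [writeGeneModelsGtf()]
#' @examples
#' gm <- generateGeneModels(syntheticGenomeSpec(nGenes = 3), seed = 1)
#' annotatedGapSites(gm)
#' @export
generateGeneModels <- function(spec, seed) {
    stopifnot(is(spec, "SyntheticGenomeSpec"))
    validObject(spec)
    set.seed(as.integer(seed))
    n <- spec@nGenes
    rint <- function(rng, k) if (rng[1] == rng[2]) rep(rng[1], k) else
        sample(seq(rng[1], rng[2]), k, replace = TRUE)
    nEx <- rint(spec@exonsPerGene, n)
    gaps <- rint(c(500L, 2000L), n)   # intergenic spacing
    cur <- 1L
    exlist <- vector("list", n)
    ids <- sprintf("g%04d", seq_len(n))
    strands <- sample(c("+", "-"), n, replace = TRUE)
    for (i in seq_len(n)) {
        start <- cur + gaps[i]
        el <- rint(spec@exonLen, nEx[i])
        il <- if (nEx[i] > 1L) rint(spec@intronLen, nEx[i] - 1L) else integer(0)
        starts <- start + c(0L, cumsum(el[-nEx[i]] + il))
        ends <- starts + el - 1L
        exlist[[i]] <- GRanges(spec@chrom, IRanges(starts, ends),
                               strand = strands[i])
        cur <- ends[nEx[i]]
        if (cur > spec@chromLen)
            stop("gene models do not fit on chromosome '", spec@chrom,
                 "' of declared length ", spec@chromLen)
    }
    grl <- GRangesList(exlist)
    names(grl) <- ids
    grl
}

#' Annotated gap-sites of a set of gene models
#'
#' One gap-site per intron: range from the last base of the upstream exon
#' (leftEnd) to the first base of the downstream exon (rightStart).
#'
#' @param geneModels a \code{GRangesList} of exons as returned by
#'   [generateGeneModels()].
#' @return a \code{GRanges} with mcols \code{gene_id} and \code{intron_rank}.
#' @export
annotatedGapSites <- function(geneModels) {
    out <- lapply(names(geneModels), function(g) {
        ex <- geneModels[[g]]
        k <- length(ex)
        if (k < 2L) return(GRanges())
        gr <- GRanges(as.character(seqnames(ex))[1L],
                      IRanges(end(ex)[-k], start(ex)[-1L]),
                      strand = as.character(strand(ex))[1L])
        mcols(gr)$gene_id <- g
        mcols(gr)$intron_rank <- seq_len(k - 1L)
        gr
    })
    unlist(GRangesList(out), use.names = FALSE)
}

#' Write gene models as GTF
#'
#' @param geneModels exon \code{GRangesList}.
#' @param path output file; written through \pkg{rtracklayer}, so a fixed
#'   input yields byte-identical output.
#' @return the path, invisibly.
#' @export
writeGeneModelsGtf <- function(geneModels, path) {
    ex <- unlist(geneModels, use.names = TRUE)
    gid <- names(ex)
    names(ex) <- NULL
    mcols(ex)$source <- "maldr_synthetic"
    mcols(ex)$type <- "exon"
    mcols(ex)$gene_id <- gid
    mcols(ex)$transcript_id <- paste0(gid, ".t1")
    rtracklayer::export(ex, path, format = "gtf")
    invisible(path)
}

#' Simulate the donor cohort
#'
#' Produces the sample table of the paired design: each donor contributes
#' one sample per body-site location; donors are assigned to ordered age
#' groups with ages drawn uniformly inside each group's range. With the
#' default specification this reproduces the reference design: 27 donors,
#' 54 samples, 18 per age group, 13 female / 14 male donors.
#'
#' @param spec a [CohortSpec-class].
#' @param seed integer seed.
#' @return a \code{DataFrame} with one row per sample: \code{sample_id},
#'   \code{donor}, \code{age}, \code{age_group} (factor, youngest level
#'   first), \code{gender}, \code{location}, \code{lib_size}. The cohort's
#'   \code{donorSigma} and age-group order travel in \code{metadata()}.
#' @examples
#' samples <- simulateCohort(cohortSpec(), seed = 1)
#' table(samples$age_group) / 2  # donors per group
#' @export
simulateCohort <- function(spec = cohortSpec(), seed) {
    stopifnot(is(spec, "CohortSpec"))
    validObject(spec)
    set.seed(as.integer(seed))
    ag <- spec@ageGroups
    donors <- sprintf("d%02d", seq_len(spec@nDonors))
    grp <- rep(ag$group, ag$nDonors)
    age <- unlist(lapply(seq_len(nrow(ag)), function(i)
        sample(seq(ag$minAge[i], ag$maxAge[i]), ag$nDonors[i], replace = TRUE)))
    gender <- rep("male", spec@nDonors)
    if (spec@nFemale > 0)  # alternate so both genders appear in every group
        gender[seq(1L, by = 2L, length.out = spec@nFemale)] <- "female"
    sm <- expand.grid(location = spec@locations, donor = donors,
                      stringsAsFactors = FALSE)[, 2:1]
    i <- match(sm$donor, donors)
    out <- DataFrame(
        sample_id = paste0(sm$donor, "_", sm$location),
        donor = sm$donor,
        age = age[i],
        age_group = factor(grp[i], levels = ag$group),
        gender = gender[i],
        location = sm$location,
        lib_size = round(runif(nrow(sm), spec@libSizeRange[1],
                               spec@libSizeRange[2])))
    rownames(out) <- out$sample_id
    metadata(out)$donorSigma <- spec@donorSigma
    metadata(out)$ageGroupOrder <- ag$group
    out
}

# per-sample multiplier for one effect, NULL-safe
.effectMultiplier <- function(effect, samples) {
    grpIdx <- as.integer(samples$age_group)
    nG <- nlevels(samples$age_group)
    switch(effect@kind,
        null = rep(1, nrow(samples)),
        monotone_up = effect@ratio^(grpIdx - 1L),
        monotone_down = effect@ratio^(nG - grpIdx),
        outlier_donors = ifelse(samples$donor %in% effect@outlierDonors,
                                effect@outlierFold, 1),
        gender_biased = ifelse(samples$gender == "male", effect@ratio, 1),
        location_biased = ifelse(samples$location ==
                                     sort(unique(samples$location))[1L],
                                 effect@ratio, 1),
        stop("unknown effect kind: ", effect@kind))
}

#' Latent per-sample expression levels
#'
#' The common generative core shared by the count and depth simulators:
#' \code{lambda[g, s] = baseCpm[g] * effect[g, s] * donorEffect[g, donor(s)]
#' * gamma[g, s]}, where the donor effect is log-normal with sd
#' \code{donorSigma} and is identical for a donor's two samples, and the
#' gamma term has shape \code{1/dispersion} (so that Poisson sampling of
#' counts given \code{lambda} is marginally negative binomial with
#' \code{Var = mu + dispersion * mu^2}). Calling this with the same
#' arguments and seed from both simulators keeps junction counts and depth
#' profiles consistent up to Poisson sampling error.
#'
#' @param geneIds character vector of gene ids.
#' @param samples sample table from [simulateCohort()].
#' @param effects list of [EffectSpec-class] objects.
#' @param dispersion NB dispersion \eqn{\phi} (default 0.1).
#' @param donorSigma sd of the log-normal donor effect; default taken from
#'   the sample table metadata (0.3).
#' @param baseCpm per-gene baseline expression in CPM units; a single value,
#'   a vector, or \code{NULL} to draw log-normal(log 8, 0.7).
#' @param seed integer seed.
#' @return matrix genes x samples of expected CPM.
#' @export
simulateExpression <- function(geneIds, samples, effects = list(),
                               dispersion = 0.1, donorSigma = NULL,
                               baseCpm = NULL, seed) {
    set.seed(as.integer(seed))
    if (is.null(donorSigma))
        donorSigma <- metadata(samples)$donorSigma %||% 0.3
    nG <- length(geneIds)
    nS <- nrow(samples)
    if (is.null(baseCpm))
        baseCpm <- exp(rnorm(nG, log(8), 0.7))
    baseCpm <- rep_len(baseCpm, nG)
    bad <- setdiff(vapply(effects, function(e) e@geneId, ""), geneIds)
    if (length(bad))
        stop("effects refer to unknown gene id(s): ",
             paste(bad, collapse = ", "))
    mult <- matrix(1, nG, nS, dimnames = list(geneIds, rownames(samples)))
    for (e in effects) {
        validObject(e)
        mult[e@geneId, ] <- mult[e@geneId, ] * .effectMultiplier(e, samples)
    }
    donors <- unique(samples$donor)
    dEff <- matrix(exp(rnorm(nG * length(donors), 0, donorSigma)),
                   nG, length(donors), dimnames = list(geneIds, donors))
    gEff <- if (dispersion > 0)
        matrix(rgamma(nG * nS, shape = 1 / dispersion, rate = 1 / dispersion),
               nG, nS)
    else matrix(1, nG, nS)
    baseCpm * mult * dEff[, samples$donor, drop = FALSE] * gEff
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# expected reads per junction as a share of gene reads: a read crosses a
# given junction when it starts within readLen-1 bases upstream of it
.junctionWeight <- function(exonicLen, readLen) {
    pmin(1, (readLen - 1) / pmax(exonicLen, 1))
}

#' Simulate gap-site counts for a cohort
#'
#' Draws junction read counts as Poisson given the latent expression of
#' [simulateExpression()], hence marginally negative binomial with
#' dispersion \code{dispersion} (plus the donor-effect component). Expected
#' gene-level reads are \code{lambda * lib_size / 1e6}; each junction
#' captures the fraction of gene reads that cross it given the read length.
#'
#' @inheritParams simulateExpression
#' @param geneModels exon \code{GRangesList} from [generateGeneModels()].
#' @param readLen read length in bases (default 101).
#' @param expression optional precomputed latent expression matrix; when
#'   supplied, \code{seed} only drives the Poisson sampling.
#' @return a [GapSiteCounts-class] with one row per annotated gap-site.
#' @export
simulateGapSiteCounts <- function(geneModels, samples, effects = list(),
                                  dispersion = 0.1, donorSigma = NULL,
                                  baseCpm = NULL, readLen = 101, seed,
                                  expression = NULL) {
    sites <- annotatedGapSites(geneModels)
    geneIds <- names(geneModels)
    if (is.null(expression))
        expression <- simulateExpression(geneIds, samples, effects,
                                         dispersion, donorSigma, baseCpm,
                                         seed = seed)
    set.seed(as.integer(seed) + 1L)
    exonicLen <- vapply(geneModels, function(ex) sum(width(ex)), 0)
    w <- .junctionWeight(exonicLen[mcols(sites)$gene_id], readLen)
    geneReads <- sweep(expression, 2L, samples$lib_size / 1e6, `*`)
    mu <- geneReads[mcols(sites)$gene_id, , drop = FALSE] * w
    counts <- matrix(rpois(length(mu), mu), nrow(mu), ncol(mu))
    dimnames(counts) <- list(
        paste0(mcols(sites)$gene_id, ".i", mcols(sites)$intron_rank),
        rownames(samples))
    GapSiteCounts(counts, sites, samples)
}

#' Simulate per-base depth profiles
#'
#' Per-position depth is Poisson around \code{coverage = geneReads *
#' readLen / exonicLength} on exonic bases and \code{leakage} times that on
#' intronic bases (pre-mRNA background, so the intron-removal step of the
#' filter has an observable effect). The latent expression is shared with
#' [simulateGapSiteCounts()] when the same seed and effects are used.
#'
#' @inheritParams simulateGapSiteCounts
#' @param leakage intronic depth as a fraction of exonic depth (default 0.01).
#' @return a [DepthProfileList-class], one profile matrix per gene covering
#'   the full gene span.
#' @export
simulateDepthProfiles <- function(geneModels, samples, effects = list(),
                                  dispersion = 0.1, donorSigma = NULL,
                                  baseCpm = NULL, readLen = 101,
                                  leakage = 0.01, seed, expression = NULL) {
    geneIds <- names(geneModels)
    if (is.null(expression))
        expression <- simulateExpression(geneIds, samples, effects,
                                         dispersion, donorSigma, baseCpm,
                                         seed = seed)
    set.seed(as.integer(seed) + 2L)
    geneReads <- sweep(expression, 2L, samples$lib_size / 1e6, `*`)
    profiles <- vector("list", length(geneIds))
    names(profiles) <- geneIds
    for (g in geneIds) {
        ex <- geneModels[[g]]
        span <- seq(min(start(ex)), max(end(ex)))
        exonic <- span %in% unlist(lapply(seq_along(ex), function(i)
            seq(start(ex)[i], end(ex)[i])))
        cov <- geneReads[g, ] * readLen / sum(width(ex))
        mu <- outer(ifelse(exonic, 1, leakage), cov)
        m <- matrix(rpois(length(mu), mu), nrow(mu), ncol(mu))
        storage.mode(m) <- "integer"
        dimnames(m) <- list(span, rownames(samples))
        profiles[[g]] <- m
    }
    DepthProfileList(profiles, samples)
}

#' Emit gapped-alignment records over annotated junctions
#'
#' Test/fixture helper: produces alignment records (chrom, 1-based leftmost
#' position, CIGAR) whose N operations reproduce each annotated gap-site a
#' requested number of times, optionally plus unannotated noise junctions.
#'
#' @param geneModels exon \code{GRangesList}.
#' @param nPerJunction reads per annotated junction (single value or vector
#'   along the junctions).
#' @param noiseSites number of additional random junctions absent from the
#'   annotation.
#' @param anchor aligned bases on each side of the gap (default 10).
#' @param seed integer seed.
#' @return data.frame with columns \code{chrom}, \code{pos}, \code{cigar}.
#' @export
simulateGappedAlignments <- function(geneModels, nPerJunction = 1L,
                                     noiseSites = 0L, anchor = 10L, seed = 1L) {
    set.seed(as.integer(seed))
    sites <- annotatedGapSites(geneModels)
    n <- rep_len(as.integer(nPerJunction), length(sites))
    le <- GenomicRanges::start(sites)
    rs <- GenomicRanges::end(sites)
    chrom <- as.character(seqnames(sites))
    recs <- data.frame(
        chrom = rep(chrom, n),
        pos = rep(le - anchor + 1L, n),
        cigar = rep(sprintf("%dM%dN%dM", anchor, rs - le - 1L, anchor), n),
        stringsAsFactors = FALSE)
    if (noiseSites > 0L) {
        hi <- max(GenomicRanges::end(unlist(geneModels))) + 10000L
        npos <- sample.int(hi, noiseSites)
        recs <- rbind(recs, data.frame(
            chrom = rep(chrom[1L] %||% "chrS", noiseSites),
            pos = npos,
            cigar = sprintf("%dM%dN%dM", anchor,
                            sample(50:500, noiseSites, replace = TRUE),
                            anchor)))
    }
    recs[sample.int(nrow(recs)), , drop = FALSE]
}

#' Write a synthetic FASTQ file
#'
#' Fixture generator for the k-mer QC stage: random reads with a given
#' base composition, constant quality. Written through \pkg{Biostrings}.
#'
#' @param path output FASTQ path.
#' @param nReads number of reads.
#' @param readLen read length.
#' @param baseProb sampling probabilities for A, C, G, T; shift these to
#'   emulate a GC-disturbed sample.
#' @param seed integer seed.
#' @return the path, invisibly.
#' @export
simulateFastq <- function(path, nReads = 200L, readLen = 75L,
                          baseProb = c(A = .25, C = .25, G = .25, T = .25),
                          seed = 1L) {
    set.seed(as.integer(seed))
    mat <- matrix(sample(c("A", "C", "G", "T"), nReads * readLen,
                         replace = TRUE, prob = baseProb),
                  nReads, readLen)
    reads <- Biostrings::DNAStringSet(apply(mat, 1L, paste0, collapse = ""))
    names(reads) <- sprintf("read%05d", seq_len(nReads))
    qual <- Biostrings::BStringSet(rep(strrep("I", readLen), nReads))
    Biostrings::writeXStringSet(reads, path, format = "fastq",
                                qualities = qual)
    invisible(path)
}
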