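# Independent brute-force oracles. These deliberately share no code with
# the package implementations they check.

# BH step-up by direct definition: fdr_(i) = min_{j >= i} m * p_(j) / j
bruteForceBH <- function(p) {
    m <- length(p)
    o <- order(p)
    ps <- p[o]
    fdr <- numeric(m)
    for (i in seq_len(m)) {
        vals <- vapply(i:m, function(j) m * ps[j] / j, 0)
        fdr[i] <- min(1, min(vals))
    }
    out <- numeric(m)
    out[o] <- fdr
    out
}

# position-wise double loop over the monotone ratio definition
bruteForceMonotoneFraction <- function(curves, ratio = 1.2, eps = 1e-9) {
    nInc <- 0L
    nDec <- 0L
    for (j in seq_len(ncol(curves))) {
        y <- curves[1L, j]; m <- curves[2L, j]; o <- curves[3L, j]
        dy <- if (y <= 0) eps else y
        dm <- if (m <= 0) eps else m
        do <- if (o <= 0) eps else o
        if (m / dy > ratio && o / dm > ratio) nInc <- nInc + 1L
        if (y / dm > ratio && m / do > ratio) nDec <- nDec + 1L
    }
    list(nIncreasing = nInc, nDecreasing = nDec,
         fraction = max(nInc, nDec) / ncol(curves))
}

# local-linear tricube fit at each point via lm(), same window convention
# as the package smoother (contiguous window of the q nearest neighbours)
bruteForceLocalLinear <- function(x, y, span) {
    n <- length(x)
    q <- max(2L, ceiling(span * n))
    vapply(seq_len(n), function(i) {
        d <- abs(x - x[i])
        idx <- order(d)[seq_len(q)]
        # contiguity: the q nearest of a sorted vector form an interval
        idx <- seq(min(idx), max(idx))
        dmax <- max(abs(x[idx] - x[i]))
        w <- if (dmax > 0) (1 - (abs(x[idx] - x[i]) / dmax)^3)^3
             else rep(1, length(idx))
        if (sum(w > 0) < 2L) return(sum(w * y[idx]) / sum(w))
        xc <- x[idx] - x[i]   # centred: the intercept IS the prediction
        yy <- y[idx]
        unname(coef(lm(yy ~ xc, weights = w))[1L])
    }, 0)
}

# exhaustive maximum clique by subset enumeration (<= 15 vertices)
bruteForceClique <- function(adj, ids) {
    n <- length(ids)
    best <- character(0)
    for (size in n:1) {
        if (size < length(best)) break
        combos <- combn(n, size, simplify = FALSE)
        hits <- list()
        for (cb in combos) {
            sub <- adj[cb, cb, drop = FALSE]
            diag(sub) <- TRUE
            if (all(sub)) hits[[length(hits) + 1L]] <- sort(ids[cb])
        }
        if (length(hits)) {
            # lexicographically smallest set among the maximum cliques
            keys <- vapply(hits, paste, "", collapse = "\r")
            return(hits[[order(keys)[1L]]])
        }
    }
    best
}

# tiny reusable cohort for depth tests: nDonors donors, equal libraries
smallCohort <- function(nDonors = 9, seed = 1, libSize = c(2e6, 2e6),
                        donorSigma = 0.3) {
    per <- nDonors %/% 3
    simulateCohort(cohortSpec(
        nDonors = nDonors,
        ageGroups = data.frame(group = c("Young", "Middle", "Old"),
                               minAge = c(18, 35, 60), maxAge = c(25, 49, 67),
                               nDonors = c(nDonors - 2 * per, per, per)),
        libSizeRange = libSize, donorSigma = donorSigma), seed = seed)
}
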