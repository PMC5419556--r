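test_that("intron cut removes strict interiors, once, by union", {
    kept <- restrictIntrons(1:100, data.frame(left_end = 40,
                                              right_start = 61))
    expect_length(kept, 80L)
    expect_false(any(kept %in% 41:60))
    expect_true(all(c(40, 61) %in% kept))
    expect_equal(attr(kept, "removed_intronic"), 41:60)

    # no gap-sites: identity
    expect_equal(as.numeric(restrictIntrons(1:50, data.frame(
        left_end = numeric(0), right_start = numeric(0)))), 1:50)

    # overlapping gap intervals remove their union exactly once
    kept2 <- restrictIntrons(1:100, data.frame(left_end = c(30, 40),
                                               right_start = c(50, 70)))
    expect_length(kept2, 100L - length(31:69))
})

test_that("group means are plain arithmetic means", {
    prof <- matrix(c(10, 20, 30, 40), 2, 2,
                   dimnames = list(c("1", "2"), c("s1", "s2")))
    # position 1 has depths 10 and 30 across the two samples
    gm <- groupMeanDepth(prof, factor(c("g1", "g1")))
    expect_equal(unname(gm[1, ]), c(20, 30))

    # a group of one sample: the mean is that sample's depth
    one <- groupMeanDepth(prof, factor(c("g1", "g2")))
    expect_equal(unname(one["g2", ]), c(30, 40))

    expect_error(groupMeanDepth(prof, factor(c("a", "a"),
                                             levels = c("a", "b"))),
                 "empty group")

    # mean of equal-size subgroups equals mean of their means
    prof4 <- matrix(rpois(40, 50), 10, 4)
    rownames(prof4) <- 1:10
    all4 <- rowMeans(prof4)
    halves <- groupMeanDepth(prof4, factor(c("a", "a", "b", "b")))
    expect_equal(unname(colMeans(halves)), unname(all4))
})

test_that("local-linear smoother reproduces constants and lines", {
    x <- sort(sample(1:500, 60))
    expect_equal(loessSmooth(x, rep(3, 60), span = 0.3), rep(3, 60),
                 tolerance = 1e-12)
    y <- 2 + 0.5 * x
    expect_equal(loessSmooth(x, y, span = 0.3), y, tolerance = 1e-9)
    expect_warning(out <- loessSmooth(1:4, c(1, 2, 3, 4)), "skipped")
    expect_equal(out, 1:4)
})

test_that("smoother agrees with a brute-force weighted lm fit", {
    set.seed(21)
    for (span in c(0.2, 0.5, 0.9)) {
        x <- sort(sample(1:2000, 80))
        y <- pmax(0, 50 + 30 * (x > 900) + rnorm(80, 0, 4))  # noisy step
        mine <- loessSmooth(x, y, span = span)
        oracle <- pmax(bruteForceLocalLinear(x, y, span), 0)
        expect_equal(mine, oracle, tolerance = 1e-8)
        expect_true(all(mine >= min(y) - 1e-9 & mine <= max(y) + 5))
    }
    # cross-check against stats::loess on an interior smooth signal
    x <- seq_len(200)
    y <- 100 + 40 * sin(x / 30)
    mine <- loessSmooth(x, y, span = 0.3)
    ref <- predict(stats::loess(y ~ x, span = 0.3, degree = 1,
                                control = stats::loess.control(
                                    surface = "direct")))
    expect_lt(max(abs(mine - ref)[20:180]), 1)
})

test_that("low-coverage cut uses the all-groups rule at 2% of the maximum", {
    # flat gene: nothing removed
    flat <- rbind(rep(5, 10), rep(5, 10), rep(5, 10))
    expect_true(all(restrictLowCoverage(flat)))

    # depth 1 against a maximum of 1000 is below 2% -> removed
    cv <- rbind(c(1000, 1), c(500, 1), c(800, 1))
    keep <- restrictLowCoverage(cv)
    expect_equal(unname(keep), c(TRUE, FALSE))

    # one group at 1% but another at 50%: kept under the ALL-groups rule
    cv2 <- rbind(c(1000, 10), c(900, 500), c(850, 15))
    expect_true(all(restrictLowCoverage(cv2)))
})

test_that("monotone fraction applies strict ratio thresholds", {
    # 13/10 = 1.3 and 17/13 ~ 1.3077, both above 1.2 at every position
    up <- rbind(rep(10, 7), rep(13, 7), rep(17, 7))
    r <- monotoneFraction(up)
    expect_equal(r$direction, "increasing")
    expect_equal(r$monotoneFraction, 1)
    expect_true(r$passes)

    # 12/10 = 1.2 exactly is NOT > 1.2
    flat12 <- rbind(rep(10, 5), rep(12, 5), rep(20, 5))
    r2 <- monotoneFraction(flat12)
    expect_equal(r2$monotoneFraction, 0)
    expect_false(r2$passes)

    # equal curves: no direction, fraction 0
    eq <- rbind(rep(4, 6), rep(4, 6), rep(4, 6))
    r3 <- monotoneFraction(eq)
    expect_equal(r3$direction, "none")
    expect_equal(r3$monotoneFraction, 0)

    expect_error(monotoneFraction(up[1:2, ]), "3 ordered groups")
})

test_that("monotone fraction equals the brute-force oracle and its symmetries", {
    set.seed(22)
    for (i in 1:50) {
        n <- sample(5:60, 1)
        cv <- matrix(rgamma(3 * n, shape = 2, rate = 0.1), 3, n)
        if (i %% 7 == 0) cv[sample(length(cv), 5)] <- 0  # zero guards
        mine <- monotoneFraction(cv)
        oracle <- bruteForceMonotoneFraction(cv)
        expect_identical(mine$nIncreasing, oracle$nIncreasing)
        expect_identical(mine$nDecreasing, oracle$nDecreasing)
        expect_equal(mine$monotoneFraction, oracle$fraction)

        # scale invariance
        sc <- monotoneFraction(cv * 37.5)
        expect_equal(sc$monotoneFraction, mine$monotoneFraction)

        # reversing the group order swaps the direction, keeps the fraction
        rev <- monotoneFraction(cv[3:1, ])
        expect_equal(rev$monotoneFraction, mine$monotoneFraction)
        expect_identical(rev$nIncreasing, mine$nDecreasing)
    }
})

test_that("full depth filter recovers injected genes under low noise", {
    gm <- generateGeneModels(syntheticGenomeSpec(nGenes = 60), seed = 31)
    s <- simulateCohort(cohortSpec(donorSigma = 0.05), seed = 32)
    inj <- names(gm)[1:10]
    eff <- lapply(inj, function(g) effectSpec(g, "monotone_up", ratio = 1.5))
    expr <- simulateExpression(names(gm), s, eff, dispersion = 0.01,
                               baseCpm = 50, seed = 33)
    gsc <- simulateGapSiteCounts(gm, s, eff, dispersion = 0.01,
                                 seed = 33, expression = expr)
    prof <- simulateDepthProfiles(gm, s, eff, dispersion = 0.01,
                                  seed = 33, expression = expr)
    res <- runMaldr(names(gm), prof, gsc)
    pass <- maldrPass(res)
    expect_true(all(inj %in% pass))
    expect_lte(sum(!pass %in% inj), 1L)
    dirs <- maldrResults(res)
    expect_true(all(dirs$direction[dirs$gene_id %in% inj] == "increasing"))

    # identical rerun gives a bitwise-identical result table
    res2 <- runMaldr(names(gm), prof, gsc)
    expect_identical(as.data.frame(res), as.data.frame(res2))

    # genes without profiles are skipped with a message
    expect_message(res3 <- runMaldr(c("ghost", inj[1]), prof, gsc),
                   "no depth profile")
    expect_equal(nrow(maldrResults(res3)), 1L)
})

test_that("raw-first low-coverage variant is available and close", {
    gm <- generateGeneModels(syntheticGenomeSpec(nGenes = 10), seed = 41)
    s <- smallCohort(nDonors = 9, seed = 42, donorSigma = 0.05)
    eff <- list(effectSpec("g0001", "monotone_up", ratio = 1.6))
    expr <- simulateExpression(names(gm), s, eff, dispersion = 0.01,
                               baseCpm = 80, seed = 43)
    gsc <- simulateGapSiteCounts(gm, s, eff, dispersion = 0.01,
                                 seed = 43, expression = expr)
    prof <- simulateDepthProfiles(gm, s, eff, dispersion = 0.01,
                                  seed = 43, expression = expr)
    a <- runMaldr(names(gm), prof, gsc, lowCoverageOn = "smoothed")
    b <- runMaldr(names(gm), prof, gsc, lowCoverageOn = "raw")
    expect_true("g0001" %in% maldrPass(a))
    expect_true("g0001" %in% maldrPass(b))
})
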