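## uniform contact matrix with enough room for APA windows
uniformCM <- function(n = 40, value = 1, res = 10) {
    contactMatrix("chr1", (seq_len(n) - 1) * res,
                  matrix(value, n, n), res)
}

loopAt <- function(bin1, bin2, res = 10, chrom = "chr1") {
    ## anchors whose midpoints fall in the given (1-based) bins
    loopSet(GRanges(chrom, IRanges((bin1 - 1) * res + 2, width = 3)),
            GRanges(chrom, IRanges((bin2 - 1) * res + 2, width = 3)))
}

test_that("nucleation anchors are counted as per-anchor booleans", {
    nuc <- bedGR("chr1", c(1000, 5000, 5400), c(1200, 5200, 5600))
    loops <- loopSet(
        bedGR("chr1", c(900, 900, 30000, 4900), c(1100, 1100, 31000, 5700)),
        bedGR("chr1", c(5100, 40000, 50000, 60000), c(5300, 41000, 51000, 61000)))
    loops <- classifyLoopAnchors(loops, nuc)
    nn <- loopData(loops)$nNucleationAnchors
    ## both anchors / one anchor / neither / anchor covering two sites = 1
    expect_equal(nn, c(2L, 1L, 0L, 1L))
    expect_equal(sum(table(nn)), length(loops))
})

test_that("span ANOVA matches the classical oracle and t-squared relation", {
    mkLoops <- function(spans, groups) {
        n <- length(spans)
        l <- loopSet(GRanges("chr1", IRanges(1000, width = 100)[rep(1, n)]),
                     GRanges("chr1", IRanges(1000 + spans, width = 100)))
        l@loopData$nNucleationAnchors <- as.integer(groups)
        l
    }
    ## identical group values: no between-group variance
    same <- spanStats(mkLoops(c(1, 2, 3, 1, 2, 3) * 1000, rep(0:1, each = 3)))
    expect_equal(same$F, 0)
    expect_equal(same$p, 1)

    ## frozen from the aov() oracle for groups {1,2,3} and {4,5,6} (kb)
    two <- spanStats(mkLoops(c(1, 2, 3, 4, 5, 6) * 1000, rep(0:1, each = 3)))
    ref <- anova(lm(s ~ g, data.frame(s = c(1, 2, 3, 4, 5, 6) * 1000,
                                      g = factor(rep(0:1, each = 3)))))
    expect_equal(two$F, ref$`F value`[1], tolerance = 1e-12)
    expect_equal(two$p, ref$`Pr(>F)`[1], tolerance = 1e-12)
    expect_equal(two$F, 13.5)
    expect_equal(two$p, pf(13.5, 1, 4, lower.tail = FALSE), tolerance = 1e-12)

    ## for two groups F = t^2
    set.seed(101)
    spans <- c(rnorm(8, 5e4, 1e4), rnorm(6, 8e4, 1e4))
    grp <- rep(0:1, c(8, 6))
    l2 <- mkLoops(round(spans), grp)
    st <- spanStats(l2)
    sp <- loopSpan(l2)
    tt <- t.test(sp[grp == 1], sp[grp == 0], var.equal = TRUE)
    expect_equal(st$F, unname(tt$statistic)^2, tolerance = 1e-9)

    expect_error(spanStats(mkLoops(c(1000, 2000), 0:1)), "variance undefined")
})

test_that("APA scores a uniform matrix at exactly 1 and applies exclusions", {
    cm <- uniformCM()
    r <- apa(loopAt(10, 30), cm, w = 5)
    expect_equal(apaScore(r), 1)
    expect_equal(r@nLoops, 1L)
    expect_equal(dim(r@aggregate), c(11L, 11L))

    ## a loop 3 bins off the diagonal is excluded under w = 5
    expect_error(apa(loopAt(10, 13), cm, w = 5), "no loop passed")
    ## window leaving the matrix is excluded too
    expect_error(apa(loopAt(3, 30), cm, w = 5), "no loop passed")
    twoLoops <- loopSet(GRanges("chr1", IRanges(c(92, 92), width = 3)),
                        GRanges("chr1", IRanges(c(292, 122), width = 3)))
    mixed <- apa(twoLoops, cm, w = 5)
    expect_equal(mixed@nLoops, 1L)
    expect_equal(mixed@nExcluded, 1L)
})

test_that("APA score is invariant to global matrix scaling", {
    set.seed(111)
    n <- 50
    base <- 100 / (1 + abs(outer(1:n, 1:n, "-")))
    base[15, 40] <- base[15, 40] * 5; base[40, 15] <- base[15, 40]
    cm1 <- contactMatrix("chr1", (1:n - 1) * 10, base, 10)
    cm2 <- contactMatrix("chr1", (1:n - 1) * 10, base * 7.3, 10)
    l <- loopAt(15, 40)
    expect_equal(apaScore(apa(l, cm1)), apaScore(apa(l, cm2)),
                 tolerance = 1e-9)
})

test_that("virtual 4C extracts a masked, normalised viewpoint profile", {
    set.seed(121)
    n <- 30
    m <- 50 / (1 + abs(outer(1:n, 1:n, "-")))
    m[5, 20] <- m[5, 20] * 10; m[20, 5] <- m[5, 20]
    cm <- contactMatrix("chr1", (1:n - 1) * 100, m, 100)
    vp <- GRanges("chr1", IRanges(401, 500))  # bin 5
    prof <- virtual4C(cm, vp)
    expect_equal(sum(prof$value), 1)
    expect_equal(prof$value[5], 0)            # viewpoint masked
    ## the planted loop partner is the off-diagonal maximum away from the
    ## immediate diagonal neighbours
    far <- prof$value
    far[4:6] <- 0
    expect_equal(which.max(far), 20L)

    ## row and column profiles agree on a symmetric matrix
    profT <- contactValues(cm)[, 5]
    profT[5] <- 0
    expect_equal(prof$value, profT / sum(profT))

    expect_error(virtual4C(cm, GRanges("chr2", IRanges(1, 10))),
                 "does not match")
    expect_error(virtual4C(cm, GRanges("chr1", IRanges(100000, 100100))),
                 "outside the matrix")
    zero <- contactMatrix("chr1", (1:5 - 1) * 100, matrix(0, 5, 5), 100)
    expect_error(virtual4C(zero, GRanges("chr1", IRanges(1, 10))), "no signal")
})

test_that("per-chromosome loop summary partitions the loop set", {
    b <- simulateBundle(tinyConfig(5))
    nuc <- b$truth[b$truth$class == "nucleation"]
    lp <- classifyLoopAnchors(b$loops, nuc)
    sm <- loopSummaryByChrom(lp)
    expect_equal(sum(sm$nLoops), sum(!loopData(lp)$interchromosomal))
    expect_equal(sum(sm$anchors0 + sm$anchors1 + sm$anchors2), sum(sm$nLoops))
})
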