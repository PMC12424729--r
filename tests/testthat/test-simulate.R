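test_that("generators are pure functions of (config, seed)", {
    cfg <- tinyConfig(17)
    t1 <- simulateTruth(cfg)
    t2 <- simulateTruth(cfg)
    expect_identical(as.data.frame(t1), as.data.frame(t2))
    expect_identical(assay(simulateCounts(t1, cfg)),
                     assay(simulateCounts(t1, cfg)))
    g1 <- simulateGenome(cfg, t1)
    g2 <- simulateGenome(cfg, t1)
    expect_identical(as.character(g1$genome), as.character(g2$genome))
    ## a different seed changes the draw
    expect_false(identical(as.data.frame(t1),
                           as.data.frame(simulateTruth(tinyConfig(18)))))
})

test_that("planted truth has the configured class structure and occupancy", {
    cfg <- tinyConfig(19)
    truth <- simulateTruth(cfg)
    expect_equal(as.vector(table(truth$class)[c("nucleation", "persistent")]),
                 c(80L, 60L))
    ## peaks never overlap (gaps >= 1 bp by construction)
    expect_true(isDisjoint(truth))
    calls <- simulateCalls(truth)
    ## steady-state calls = nucleation + control_exclusive + persistent
    expect_equal(length(calls$steady_state), 80L + 200L + 60L)
    expect_equal(length(calls$auxin), 60L + 30L)

    ## genome shorter than the peaks it must host errors out
    tooSmall <- tinyConfig(19)
    tooSmall@chromLengths <- c(chrA = 5e4, chrB = 5e4)
    expect_error(simulateTruth(tooSmall), "genome shorter")
})

test_that("simulated counts follow the planted NB model", {
    ## near-Poisson limit with s = 1: mean of many draws within 2% of mu
    cfg <- tinyConfig(23)
    truth <- GRanges("chrA", IRanges((0:9999) * 100 + 1, width = 50))
    names(truth) <- paste0("peak_", 1:10000)
    truth$class <- "persistent"
    truth$lfc1 <- 0; truth$lfc2 <- 0
    truth$baselineMean <- 500
    truth$dispersion <- 1e-8
    cfg@sizeFactorLogSd <- 0
    pe <- simulateCounts(truth, cfg)
    expect_equal(mean(assay(pe)[, 1]), 500, tolerance = 0.02)

    ## planted contrast-1 LFC of -3 drops the auxin mean eight-fold
    truth$lfc1 <- -3
    pe2 <- simulateCounts(truth, cfg)
    cond <- colData(pe2)$condition
    expect_equal(mean(assay(pe2)[, cond == "auxin"]), 500 / 8,
                 tolerance = 0.03)
    expect_equal(mean(assay(pe2)[, cond == "steady_state"]), 500,
                 tolerance = 0.03)
})

test_that("synthetic genome has GC-rich CpG islands on a 0.42 background", {
    cfg <- tinyConfig(29)
    truth <- simulateTruth(cfg)
    g <- simulateGenome(cfg, truth)
    seqs <- g$genome
    ## every island is GC >= 0.65 with CpG density >= 0.06 by construction
    islSeq <- Biostrings::DNAStringSet(lapply(seq_along(g$cgi), function(k) {
        chr <- as.character(seqnames(g$cgi))[k]
        Biostrings::subseq(seqs[[chr]], start(g$cgi)[k], end(g$cgi)[k])
    }))
    expect_true(all(gcContent(islSeq) >= 0.65))
    cpg <- Biostrings::vcountPattern("CG", islSeq) / Biostrings::width(islSeq)
    expect_true(all(cpg >= 0.06))

    ## background GC concentrates near 0.42 (binomial bound at this length)
    bgRegion <- setdiff(GRanges("chrA", IRanges(1, cfg@chromLengths[["chrA"]])),
                        c(granges(g$cgi), granges(truth)))
    bgSeq <- paste(vapply(which(width(bgRegion) > 1000), function(k)
        as.character(Biostrings::subseq(seqs[["chrA"]], start(bgRegion)[k],
                                        end(bgRegion)[k])), character(1)),
        collapse = "")
    expect_equal(gcContent(bgSeq), 0.42, tolerance = 0.03 / 0.42)
})

test_that("methylation generator rounds-trip through the island caller", {
    b <- simulateBundle(tinyConfig(31))
    calls <- suppressWarnings(callIslandStatus(b$cgi, b$methylation))
    ok <- !is.na(b$islandTruth$plantedStatus)
    expect_identical(as.character(calls$status)[ok],
                     b$islandTruth$plantedStatus[ok])
    ## levels are valid methylation fractions
    expect_true(all(b$methylation$level >= 0 & b$methylation$level <= 1))
})

test_that("planted loops enrich the matrix at their pixels", {
    cfg <- tinyConfig(37)
    truth <- simulateTruth(cfg)
    lp <- simulateLoops(truth, cfg)
    expect_equal(as.vector(table(loopData(lp$loops)$plantedClass)[c("one", "two", "zero")]),
                 c(25L, 15L, 60L))
    ## all planted spans clear the 3-bin rejection rule
    expect_true(all(loopSpan(lp$loops) >= 3 * cfg@resolution))

    ## loop pixels exceed their local decay background
    cm <- lp$matrix
    onChr <- as.character(seqnames(anchorOne(lp$loops))) == "chrA"
    a1 <- anchorOne(lp$loops)[onChr]; a2 <- anchorTwo(lp$loops)[onChr]
    b1 <- floor((floor((start(a1) + end(a1)) / 2) - 1) / cfg@resolution) + 1
    b2 <- floor((floor((start(a2) + end(a2)) / 2) - 1) / cfg@resolution) + 1
    v <- contactValues(cm)
    nb <- length(binStarts(cm))
    keep <- b1 >= 1 & b1 <= nb & b2 >= 2 & b2 <= nb - 1
    pix <- v[cbind(b1, b2)][keep]
    side <- v[cbind(b1, pmin(b2 + 1, nb))][keep]
    expect_true(all(pix > side))

    ## APA on the planted loops recovers focal enrichment (> 1)
    nuc <- truth[truth$class == "nucleation"]
    loops <- classifyLoopAnchors(lp$loops, nuc)
    r <- apa(loops, cm, w = 3)
    expect_gt(apaScore(r), 1)

    ## zero loops configured -> pure decay matrix, APA undefined
    none <- tinyConfig(37)
    none@nLoops <- c(zero = 0L, one = 0L, two = 0L)
    lp0 <- simulateLoops(truth, none)
    expect_length(lp0$loops, 0L)
    expect_error(apa(lp0$loops, lp0$matrix), "no loop passed")
})

test_that("the written bundle is byte-identical across runs", {
    d1 <- file.path(tempdir(), "bundleA")
    d2 <- file.path(tempdir(), "bundleB")
    unlink(c(d1, d2), recursive = TRUE)
    simulateBundle(tinyConfig(41), d1)
    simulateBundle(tinyConfig(41), d2)
    f1 <- list.files(d1)
    expect_true(length(f1) >= 10)
    expect_identical(f1, list.files(d2))
    for (f in f1)
        expect_identical(unname(tools::md5sum(file.path(d1, f))),
                         unname(tools::md5sum(file.path(d2, f))),
                         label = paste("md5 of", f))
})
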