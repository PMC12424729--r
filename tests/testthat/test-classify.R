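callsFor <- function(union, ss = GRanges(), aux = GRanges(), re = GRanges()) {
    list(steady_state = ss, auxin = aux, reintroduction = re)
}

test_that("flagPresence requires all conditions and uses 1-bp overlap", {
    union <- bedGR("chr1", c(100, 1000), c(200, 1100), names = c("u1", "u2"))
    calls <- callsFor(union, ss = bedGR("chr1", 199, 300))  # 1-bp overlap of u1
    pres <- flagPresence(union, calls)
    expect_identical(unname(pres[, "steady_state"]), c(TRUE, FALSE))
    expect_false(any(pres[, c("auxin", "reintroduction")]))
    expect_error(flagPresence(union, calls[1:2]), "missing condition")
})

test_that("the dual-contrast rule classifies each dynamics pattern", {
    union <- bedGR("chr1", (0:5) * 1000, (0:5) * 1000 + 500,
                   names = paste0("u", 1:6))
    ## u1 nucleation; u2 fails lfc1 boundary (strict); u3 persistent;
    ## u4 control-exclusive; u5 new in auxin; u6 new in reintroduction
    calls <- list(
        steady_state = union[1:4],
        auxin = union[c(3, 5)],
        reintroduction = union[c(1, 3, 5, 6)])
    c1 <- makeContrast(names(union),
                       lfc = c(-3, -1.5, 0, -0.2, 3, 0),
                       padj = c(1e-6, 1e-6, 0.8, 0.5, 1e-6, 1))
    c2 <- makeContrast(names(union),
                       lfc = c(2.5, 2.5, 0, 0.1, 0, 3),
                       padj = c(1e-5, 1e-5, 0.9, 0.6, 1, 1e-5))
    cl <- classifyPeaks(union, flagPresence(union, calls), c1, c2)
    expect_identical(as.character(cl$label),
                     c("nucleation", "control_exclusive", "persistent",
                       "control_exclusive", "new_in_auxin", "new_in_reintro"))

    ## labels are a partition of the union
    expect_equal(sum(table(cl$label)), length(union))

    ## feature mismatch is rejected
    expect_error(classifyPeaks(union, flagPresence(union, calls),
                               makeContrast(rev(names(union)), rep(0, 6), rep(1, 6)),
                               c2),
                 "must match the union")
})

test_that("raising thresholds never increases the nucleation count", {
    set.seed(71)
    n <- 400
    union <- bedGR("chr1", (0:(n - 1)) * 2000, (0:(n - 1)) * 2000 + 800,
                   names = paste0("u", seq_len(n)))
    calls <- list(steady_state = union, auxin = union[1:50],
                  reintroduction = union)
    c1 <- makeContrast(names(union), lfc = rnorm(n, -1.5, 1.5),
                       padj = runif(n)^2)
    c2 <- makeContrast(names(union), lfc = rnorm(n, 1.5, 1.5),
                       padj = runif(n)^2)
    pres <- flagPresence(union, calls)
    nNuc <- function(lfcMin, padjMax)
        sum(classifyPeaks(union, pres, c1, c2,
                          classifierThresholds(lfcMin, padjMax))$label ==
            "nucleation")
    base <- nNuc(1.5, 0.005)
    expect_lte(nNuc(2.0, 0.005), base)
    expect_lte(nNuc(1.5, 0.001), base)
})

test_that("width summaries handle the usual and degenerate cases", {
    gr <- bedGR("chr1", c(0, 1000, 3000, 9000), c(100, 1200, 3300, 9050))
    gr$label <- factor(c("nucleation", "nucleation", "nucleation", "persistent"),
                       levels = c("nucleation", "control_exclusive", "persistent"))
    ws <- widthStats(gr)
    expect_equal(ws$median[ws$class == "nucleation"], 200)
    expect_equal(ws$median[ws$class == "persistent"], 50)
    expect_equal(ws$n[ws$class == "control_exclusive"], 0L)
    expect_true(is.na(ws$median[ws$class == "control_exclusive"]))
})

test_that("interpeak distances are nearest-neighbour edge gaps", {
    gr <- bedGR("chr1", c(100, 500), c(200, 600))
    expect_equal(interpeakDistances(gr), c(300, 300))

    ## overlapping pair -> 0
    expect_equal(interpeakDistances(bedGR("chr1", c(100, 150), c(300, 400))),
                 c(0, 0))

    ## lone peak per chromosome -> undefined
    d <- interpeakDistances(bedGR(c("chr1", "chr2"), c(0, 0), c(10, 10)))
    expect_true(all(is.na(d)))
    expect_error(interpeakDistances(bedGR("chr1", 1, 10)), "at least 2")
})

test_that("genomic context follows promoter > exon > intron > intergenic", {
    genes <- GRanges("chr1", IRanges(10001, 30000), strand = "+",
                     gene_id = "g1", tss = 10001L)
    exons <- GRanges("chr1", IRanges(c(10001, 25000), c(12000, 26000)))
    peaks <- bedGR("chr1",
                   c(9000, 25400, 20000, 500000),
                   c(10000, 25600, 20200, 500200))
    ctx <- annotateGenomicContext(peaks, genes, exons)
    expect_identical(ctx, c("promoter", "exon", "intron", "intergenic"))
    ## without exon annotation the gene body is intron
    expect_identical(annotateGenomicContext(peaks[2], genes), "intron")
})

test_that("nearest gene picks the closest TSS with deterministic ties", {
    genes <- GRanges("chr1", IRanges(c(1000, 5000), c(3000, 8000)),
                     strand = c("+", "-"),
                     gene_id = c("geneB", "geneA"),
                     tss = c(1000L, 8000L))
    ## midpoint exactly at a TSS
    atTss <- nearestGene(bedGR("chr1", 999, 1000), genes)
    expect_identical(atTss$gene_id, "geneB")
    expect_equal(atTss$distance, 0)

    ## equidistant between the two TSSs (midpoint 4500): lexicographic tie
    tie <- nearestGene(bedGR("chr1", 4499, 4500), genes)
    expect_identical(tie$gene_id, "geneA")

    ## signed distance respects strand: 500 bp left of a minus-strand TSS is
    ## downstream (positive)
    g2 <- genes[2]
    near <- nearestGene(bedGR("chr1", 7499, 7500), g2)
    expect_equal(near$distance, 500)

    ## peaks on a chromosome with no genes report a missing gene
    none <- nearestGene(bedGR("chr9", 0, 100), genes)
    expect_true(is.na(none$gene_id))

    ## single-gene genome maps every peak to it
    all1 <- nearestGene(bedGR("chr1", c(0, 9000), c(10, 9100)), genes[1])
    expect_identical(all1$gene_id, rep("geneB", 2))
})
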