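suppressPackageStartupMessages({
    library(GenomicRanges)
    library(SummarizedExperiment)
    library(S4Vectors)
})

## Build a GRanges from BED-style (0-based half-open) coordinates, the way
## the on-disk examples are written.
bedGR <- function(chrom, start0, end, names = NULL, ...) {
    gr <- GRanges(chrom, IRanges(start = start0 + 1L, end = end), ...)
    if (!is.null(names)) names(gr) <- names
    gr
}

writeTmp <- function(lines, ext = ".bed") {
    f <- tempfile(fileext = ext)
    writeLines(lines, f)
    f
}

## A ContrastResult with chosen statistics (pvalue set equal to padj).
makeContrast <- function(features, lfc, padj, condA = "a", condB = "b") {
    new("ContrastResult", conditionA = condA, conditionB = condB,
        results = DataFrame(feature = features, baseMean = rep(100, length(features)),
                            log2FoldChange = lfc, lfcSE = rep(0.2, length(features)),
                            dispersion = rep(0.05, length(features)),
                            pvalue = padj, padj = padj))
}

## Desk-scale simulation config used by module tests (the default-scale
## bundle is exercised in the acceptance suite).
tinyConfig <- function(seed) {
    simConfig(seed,
              nPeaks = c(nucleation = 80L, control_exclusive = 200L,
                         persistent = 60L, new_in_auxin = 30L,
                         new_in_reintro = 30L),
              chromLengths = c(chrA = 8e5, chrB = 8e5),
              nCGI = 80L, cgiWidth = 600,
              nLoops = c(zero = 60L, one = 25L, two = 15L),
              loopSpanMeans = c(zero = 3e4, one = 5e4, two = 8e4),
              resolution = 5000, decayScale = 50)
}

## NB counts for an explicit design: one row per feature, columns cond/rep.
nbCounts <- function(mu, lfcB = 0, alpha = 0.05, nRep = 2, s = NULL) {
    n <- length(mu)
    cond <- rep(c("A", "B"), each = nRep)
    if (is.null(s)) s <- rep(1, 2 * nRep)
    counts <- vapply(seq_along(cond), function(j) {
        m <- s[j] * mu * if (cond[j] == "B") 2^lfcB else 1
        as.numeric(rnbinom(n, mu = m, size = 1 / alpha))
    }, numeric(n))
    peakExperiment(counts, condition = cond)
}
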