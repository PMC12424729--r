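#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- mcols mcols<-
#' @importFrom BiocGenerics start end width strand
#' @import GenomicRanges
#' @import SummarizedExperiment
#' @importFrom IRanges IRanges
NULL

## Condition labels used throughout the degron design.
CONDITIONS <- c("steady_state", "auxin", "reintroduction")

## Peak classes assigned by the dual-contrast classifier; "background" only
## appears in simulated truth tables (peaks planted with no dynamics at all).
PEAK_CLASSES <- c("nucleation", "control_exclusive", "persistent",
                  "new_in_auxin", "new_in_reintro", "excluded")

#' PeakExperiment: peak-by-sample counts with sample metadata
#'
#' A thin subclass of [SummarizedExperiment::RangedSummarizedExperiment]
#' holding a single `"counts"` assay of non-negative integers over union
#' peaks, a `condition` / `replicate` column pair in `colData`, and (after
#' [estimateSizeFactors()]) a `sizeFactor` column of per-sample
#' median-of-ratios scale factors.
#'
#' @slot .  inherits all slots from `RangedSummarizedExperiment`.
#' @seealso [peakExperiment()], [estimateSizeFactors()], [waldContrast()]
#' @export
setClass("PeakExperiment", contains = "RangedSummarizedExperiment")

setValidity("PeakExperiment", function(object) {
    msg <- NULL
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'counts' is required")
    else {
        k <- SummarizedExperiment::assay(object, "counts")
        if (any(k < 0)) msg <- c(msg, "counts must be non-negative")
        if (any(k != round(k))) msg <- c(msg, "counts must be integers")
    }
    cd <- SummarizedExperiment::colData(object)
    for (col in c("condition", "replicate"))
        if (!col %in% colnames(cd)) msg <- c(msg, sprintf("colData column '%s' is required", col))
    if ("sizeFactor" %in% colnames(cd) && any(cd$sizeFactor <= 0, na.rm = TRUE))
        msg <- c(msg, "size factors must be positive")
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "feature names must be unique")
    if (is.null(msg)) TRUE else msg
})

#' Construct a PeakExperiment
#'
#' @param counts integer matrix of fragment counts, peaks in rows, samples in
#'   columns. Row names are peak identifiers; auto-generated when absent.
#' @param rowRanges `GRanges` of the union peaks (parallel to rows), or `NULL`
#'   to use unannotated placeholder ranges.
#' @param condition character vector assigning each sample to one of
#'   `"steady_state"`, `"auxin"`, `"reintroduction"` (any label set is
#'   accepted; these are the degron design's levels).
#' @param replicate integer replicate index per sample.
#' @return A [PeakExperiment-class] object.
#' @export
peakExperiment <- function(counts, rowRanges = NULL, condition, replicate = NULL) {
    counts <- as.matrix(counts)
    storage.mode(counts) <- "integer"
    if (is.null(rownames(counts)))
        rownames(counts) <- paste0("peak_", seq_len(nrow(counts)))
    if (is.null(colnames(counts)))
        colnames(counts) <- paste0(condition, "_rep",
                                   ave(seq_along(condition), condition, FUN = seq_along))
    if (is.null(replicate))
        replicate <- as.integer(ave(seq_along(condition), condition, FUN = seq_along))
    if (is.null(rowRanges))
        rowRanges <- GRanges("un", IRanges(start = seq_len(nrow(counts)), width = 1L))
    names(rowRanges) <- rownames(counts)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts),
        rowRanges = rowRanges,
        colData = DataFrame(condition = as.character(condition),
                            replicate = as.integer(replicate),
                            row.names = colnames(counts)))
    new("PeakExperiment", se)
}

#' ContrastResult: per-peak differential-binding statistics
#'
#' Holds the output of the negative-binomial Wald test for one contrast
#' (condition B over condition A): base mean, log2 fold change with its
#' standard error, the dispersion used, and raw/BH-adjusted p-values.
#'
#' @slot conditionA,conditionB character; the reference and test condition.
#' @slot results `DataFrame` with columns `feature`, `baseMean`,
#'   `log2FoldChange`, `lfcSE`, `dispersion`, `pvalue`, `padj`.
#' @export
setClass("ContrastResult",
         representation(conditionA = "character", conditionB = "character",
                        results = "DataFrame"))

setValidity("ContrastResult", function(object) {
    msg <- NULL
    need <- c("feature", "baseMean", "log2FoldChange", "lfcSE",
              "dispersion", "pvalue", "padj")
    miss <- setdiff(need, colnames(object@results))
    if (length(miss)) msg <- c(msg, paste("missing results columns:", paste(miss, collapse = ", ")))
    else {
        r <- object@results
        if (any(r$padj < r$pvalue - 1e-12, na.rm = TRUE))
            msg <- c(msg, "padj must be >= pvalue")
        if (any(r$padj < 0 | r$padj > 1, na.rm = TRUE))
            msg <- c(msg, "padj must lie in [0, 1]")
    }
    if (is.null(msg)) TRUE else msg
})

#' ResamplingResult: observed statistic against a resampling null
#'
#' @slot observed observed statistic on the query set.
#' @slot nullDraws numeric vector of the statistic over N random draws.
#' @slot expected mean of the null draws.
#' @slot oeRatio observed / expected.
#' @slot pEmpirical add-one empirical p-value, `(1 + #{null >= obs})/(N + 1)`
#'   (`<=` for the depletion alternative); never exactly zero.
#' @slot N number of draws.
#' @slot seed seed used for the draws.
#' @slot alternative `"enrichment"` or `"depletion"`.
#' @export
setClass("ResamplingResult",
         representation(observed = "numeric", nullDraws = "numeric",
                        expected = "numeric", oeRatio = "numeric",
                        pEmpirical = "numeric", N = "integer",
                        seed = "integer", alternative = "character"))

setValidity("ResamplingResult", function(object) {
    msg <- NULL
    if (object@N < 1L) msg <- c(msg, "N must be >= 1")
    if (length(object@nullDraws) != object@N) msg <- c(msg, "nullDraws length must equal N")
    if (object@pEmpirical <= 0 || object@pEmpirical > 1)
        msg <- c(msg, "pEmpirical must lie in (0, 1]")
    if (!is.na(object@oeRatio) && object@oeRatio < 0)
        msg <- c(msg, "oeRatio must be >= 0")
    if (!object@alternative %in% c("enrichment", "depletion"))
        msg <- c(msg, "alternative must be 'enrichment' or 'depletion'")
    if (is.null(msg)) TRUE else msg
})

#' ContactMatrix: dense symmetric binned contacts for one chromosome
#'
#' @slot chrom chromosome name.
#' @slot resolution bin width in bp.
#' @slot bins 0-based start coordinate of each bin (uniform spacing).
#' @slot values symmetric non-negative square matrix of contact counts.
#' @export
setClass("ContactMatrix",
         representation(chrom = "character", resolution = "numeric",
                        bins = "numeric", values = "matrix"))

setValidity("ContactMatrix", function(object) {
    msg <- NULL
    v <- object@values
    if (nrow(v) != ncol(v)) msg <- c(msg, "values must be square")
    if (nrow(v) != length(object@bins)) msg <- c(msg, "bin count must match matrix dimension")
    if (any(v < 0)) msg <- c(msg, "contact values must be non-negative")
    if (max(abs(v - t(v))) > 1e-6 * max(1, max(abs(v))))
        msg <- c(msg, "values must be symmetric")
    d <- diff(object@bins)
    if (length(d) && any(abs(d - object@resolution) > 0.5))
        msg <- c(msg, "bins must be uniformly spaced at 'resolution'")
    if (is.null(msg)) TRUE else msg
})

#' LoopSet: paired anchors of chromatin loops
#'
#' Anchors are normalised so that `anchor1` precedes `anchor2` in
#' (chrom, start) order. `span` is the midpoint-to-midpoint distance, defined
#' for intrachromosomal loops only; interchromosomal pairs are retained with
#' `interchromosomal = TRUE` and `span = NA`.
#'
#' @slot anchor1,anchor2 `GRanges`, parallel.
#' @slot loopData `DataFrame` with columns `span`, `interchromosomal` and,
#'   after [classifyLoopAnchors()], `nNucleationAnchors`.
#' @export
setClass("LoopSet",
         representation(anchor1 = "GRanges", anchor2 = "GRanges",
                        loopData = "DataFrame"))

setValidity("LoopSet", function(object) {
    msg <- NULL
    n <- length(object@anchor1)
    if (length(object@anchor2) != n) msg <- c(msg, "anchors must be parallel")
    if (nrow(object@loopData) != n) msg <- c(msg, "loopData must be parallel to anchors")
    if (n) {
        c1 <- as.character(GenomicRanges::seqnames(object@anchor1))
        c2 <- as.character(GenomicRanges::seqnames(object@anchor2))
        same <- c1 == c2
        bad <- same & start(object@anchor1) > start(object@anchor2)
        if (any(bad)) msg <- c(msg, "anchor1 must precede anchor2 in genomic order")
        if (!all(object@loopData$interchromosomal == !same))
            msg <- c(msg, "interchromosomal flag inconsistent with anchors")
    }
    nn <- object@loopData$nNucleationAnchors
    if (!is.null(nn) && !all(nn %in% c(0L, 1L, 2L, NA)))
        msg <- c(msg, "nNucleationAnchors must be 0, 1 or 2")
    if (is.null(msg)) TRUE else msg
})

#' APAResult: aggregate peak analysis summary
#'
#' @slot w window half-width in bins.
#' @slot aggregate `(2w+1) x (2w+1)` mean contact submatrix, anchor1 on rows.
#' @slot nLoops number of loops averaged.
#' @slot nExcluded loops dropped (window off-matrix or too near the diagonal).
#' @slot score centre pixel over the mean of the 3x3 lower-left corner (the
#'   short-genomic-distance background quadrant).
#' @export
setClass("APAResult",
         representation(w = "integer", aggregate = "matrix",
                        nLoops = "integer", nExcluded = "integer",
                        score = "numeric"))

setValidity("APAResult", function(object) {
    msg <- NULL
    side <- 2L * object@w + 1L
    if (!all(dim(object@aggregate) == c(side, side)))
        msg <- c(msg, "aggregate must be (2w+1) x (2w+1)")
    if (!all(is.finite(object@aggregate))) msg <- c(msg, "aggregate must be finite")
    if (is.null(msg)) TRUE else msg
})

#' SimConfig: parameters of the synthetic degron ChIP-seq bundle
#'
#' Defaults emulate the scale and statistical structure of the mESC
#' Suz12-degron study design: ~1.1k nucleation peaks among ~5.8k steady-state
#' peaks, |log2FC| = 3 planted dynamics, log-normal peak widths with medians
#' 1342 bp (nucleation) and 714 bp (control-exclusive), 2 replicates per
#' condition, GC-rich CpG islands on a background of GC 0.42, loops with
#' 0/1/2 nucleation anchors (3892/260/102) and a 10 kb contact matrix with
#' 5x focal enrichment at loop pixels.
#'
#' @export
setClass("SimConfig",
         representation(seed = "integer", nPeaks = "integer",
                        replicates = "integer", chromLengths = "numeric",
                        widthMedians = "numeric", widthLogSd = "numeric",
                        effectSize = "numeric", baselineLogMean = "numeric",
                        baselineLogSd = "numeric", newPeakBaseline = "numeric",
                        dispersionRange = "numeric", sizeFactorLogSd = "numeric",
                        nCGI = "integer", cgiWidth = "numeric",
                        gcBackground = "numeric", gcIsland = "numeric",
                        cgiNucleationFraction = "numeric",
                        cgiControlFraction = "numeric",
                        probUnmethylatedNucleation = "numeric",
                        probUnmethylatedElsewhere = "numeric",
                        nLoops = "integer", loopSpanMeans = "numeric",
                        resolution = "numeric", focalEnrichment = "numeric",
                        decayScale = "numeric"))

setValidity("SimConfig", function(object) {
    msg <- NULL
    if (length(object@seed) != 1L || is.na(object@seed))
        msg <- c(msg, "a scalar seed is mandatory")
    want <- c("nucleation", "control_exclusive", "persistent",
              "new_in_auxin", "new_in_reintro")
    if (!identical(sort(names(object@nPeaks)), sort(want)))
        msg <- c(msg, paste("nPeaks must be named:", paste(want, collapse = ", ")))
    if (any(object@nPeaks < 0L)) msg <- c(msg, "peak counts must be >= 0")
    if (object@replicates < 1L) msg <- c(msg, "replicates must be >= 1")
    if (any(object@dispersionRange <= 0)) msg <- c(msg, "dispersions must be > 0")
    if (!identical(sort(names(object@nLoops)), c("one", "two", "zero")))
        msg <- c(msg, "nLoops must be named zero/one/two")
    if (object@resolution <= 0) msg <- c(msg, "resolution must be > 0")
    probs <- c(object@gcBackground, object@gcIsland,
               object@probUnmethylatedNucleation, object@probUnmethylatedElsewhere,
               object@cgiNucleationFraction, object@cgiControlFraction)
    if (any(probs < 0 | probs > 1)) msg <- c(msg, "probabilities must lie in [0, 1]")
    if (is.null(msg)) TRUE else msg
})
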