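#' @include AllClasses.R AllGenerics.R
NULL

#' Merge per-condition peak sets into a non-redundant union
#'
#' Intervals overlapping by at least 1 bp, or book-ended (one ending exactly
#' where the next begins), are merged across all input sets. Each union peak
#' records which input sets contributed to it.
#'
#' @param peaksets a named list of `GRanges` (one per condition / antibody).
#' @return A sorted, disjoint `GRanges` named `peak_<i>` with a `sources`
#'   metadata column (comma-separated contributing set names).
#' @export
mergeUnion <- function(peaksets) {
    if (!length(peaksets)) stop("at least one peak set is required")
    if (is.null(names(peaksets)))
        names(peaksets) <- paste0("set", seq_along(peaksets))
    pooled <- unlist(GRangesList(lapply(peaksets, GenomicRanges::granges)))
    ## reduce() merges overlapping and book-ended ranges (min.gapwidth = 1)
    union <- GenomicRanges::reduce(sort(pooled, ignore.strand = TRUE),
                                   ignore.strand = TRUE)
    names(union) <- paste0("peak_", seq_along(union))
    src <- character(length(union))
    for (lab in names(peaksets)) {
        hit <- overlapsAny(union, peaksets[[lab]], ignore.strand = TRUE)
        src[hit] <- ifelse(nzchar(src[hit]), paste0(src[hit], ",", lab), lab)
    }
    union$sources <- src
    union
}

#' Count per-sample fragments over union peaks
#'
#' A fragment is assigned to every union peak it overlaps by at least 1 bp
#' (a fragment spanning two adjacent peaks increments both), and is counted
#' at most once per peak.
#'
#' @param union `GRanges` of union peaks (from [mergeUnion()]).
#' @param fragments named list of `GRanges`, one element per sample.
#' @param condition,replicate sample metadata, parallel to `fragments`.
#' @return A [PeakExperiment-class] with a `counts` assay.
#' @export
countFragments <- function(union, fragments, condition, replicate = NULL) {
    counts <- vapply(fragments,
                     function(fr) GenomicRanges::countOverlaps(union, fr, ignore.strand = TRUE),
                     integer(length(union)))
    if (length(union) == 1L) counts <- matrix(counts, nrow = 1L)
    rownames(counts) <- names(union)
    colnames(counts) <- names(fragments)
    peakExperiment(counts, rowRanges = union, condition = condition,
                   replicate = replicate)
}

.sizeFactorsFromMatrix <- function(counts) {
    ok <- rowSums(counts > 0) == ncol(counts)
    if (!any(ok))
        stop("no feature has positive counts in every sample; ",
             "median-of-ratios is undefined (pseudo-reference fallback is disabled)")
    logGeo <- rowMeans(log(counts[ok, , drop = FALSE]))
    apply(counts[ok, , drop = FALSE], 2L,
          function(k) stats::median(exp(log(k) - logGeo)))
}

#' Median-of-ratios size factors
#'
#' Computed over features with all-positive counts as
#' `s_j = median_i k_ij / geomean(k_i.)`; factors are not renormalised
#' further. Errors when no feature is positive in every sample (the
#' pseudo-reference fallback is deliberately disabled).
#'
#' @param object a [PeakExperiment-class] (factors stored in `colData`) or a
#'   count matrix (factors returned).
#' @param ... unused.
#' @rdname estimateSizeFactors-methods
#' @export
setMethod("estimateSizeFactors", "PeakExperiment", function(object, ...) {
    s <- .sizeFactorsFromMatrix(SummarizedExperiment::assay(object, "counts"))
    SummarizedExperiment::colData(object)$sizeFactor <- unname(s)
    validObject(object)
    object
})

#' @rdname estimateSizeFactors-methods
#' @export
setMethod("estimateSizeFactors", "matrix", function(object, ...) {
    .sizeFactorsFromMatrix(object)
})

.normalizedCounts <- function(pe) {
    s <- sizeFactors(pe)
    if (is.null(s)) stop("size factors not estimated; run estimateSizeFactors() first")
    sweep(SummarizedExperiment::assay(pe, "counts"), 2L, s, "/")
}

#' Method-of-moments NB dispersion with shrinkage to the median
#'
#' On size-factor-normalised counts with per-group means removed, the raw
#' per-feature estimate is `alpha_hat = max((Var - mu)/mu^2, 1e-8)` (NB
#' variance convention `Var = mu + alpha mu^2`), where `Var` is the pooled
#' residual variance and `mu` the overall normalised mean. The final value
#' is shrunk half-way to the across-feature median:
#' `alpha = 0.5 alpha_hat + 0.5 median(alpha_hat)`.
#'
#' @param object a [PeakExperiment-class] with size factors estimated.
#' @param alphaMin floor for the raw estimate (default `1e-8`).
#' @param ... unused.
#' @return The object with a per-feature `dispersion` column in its row data.
#' @export
setMethod("estimateDispersions", "PeakExperiment",
          function(object, alphaMin = 1e-8, ...) {
    pe <- object
    k <- .normalizedCounts(pe)
    grp <- SummarizedExperiment::colData(pe)$condition
    groups <- unique(grp)
    G <- length(groups)
    n <- ncol(k)
    if (n - G < 1L)
        stop("dispersion estimation requires replicates (n samples > n groups)")
    groupMeans <- vapply(groups,
                         function(g) rowMeans(k[, grp == g, drop = FALSE]),
                         numeric(nrow(k)))
    if (nrow(k) == 1L) groupMeans <- matrix(groupMeans, nrow = 1L)
    fitted <- groupMeans[, match(grp, groups), drop = FALSE]
    residVar <- rowSums((k - fitted)^2) / (n - G)
    mu <- rowMeans(k)
    alphaHat <- ifelse(mu > 0, pmax((residVar - mu) / mu^2, alphaMin), alphaMin)
    alphaMed <- stats::median(alphaHat)
    SummarizedExperiment::rowData(pe)$dispersion <- 0.5 * alphaHat + 0.5 * alphaMed
    pe
})

#' Benjamini-Hochberg step-up adjustment
#'
#' Validates the inputs and applies the standard BH step-up rule with
#' monotonicity enforcement (tied p-values share an adjusted value).
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order as `p`.
#' @export
bhAdjust <- function(p) {
    if (any(p < 0 | p > 1, na.rm = TRUE))
        stop("p-values must lie in [0, 1]")
    stats::p.adjust(p, method = "BH")
}

#' Negative-binomial Wald test between two conditions
#'
#' Group means `mu_g` are taken on size-factor-normalised counts; the fold
#' change is `log2((mu_B + c0)/(mu_A + c0))` with pseudo-count `c0 = 0.5`.
#' The delta-method standard error is
#' `se^2 = (1/ln 2)^2 * sum_g (1/n_g) (1/(mu_g + c0) + alpha_i)`, the Wald
#' statistic `z = log2FC / se` is referred to the standard normal
#' (two-sided), and BH adjustment runs over all features (features with no
#' counts anywhere are assigned `p = 1` so the multiple-testing family stays
#' the full union).
#'
#' @param pe a [PeakExperiment-class] with size factors and dispersions.
#' @param conditionA reference condition label.
#' @param conditionB test condition label (fold change is B over A).
#' @param pseudocount `c0`, default 0.5.
#' @return A [ContrastResult-class].
#' @export
waldContrast <- function(pe, conditionA, conditionB, pseudocount = 0.5) {
    grp <- SummarizedExperiment::colData(pe)$condition
    for (cond in c(conditionA, conditionB))
        if (!cond %in% grp) stop("unknown condition label: ", cond)
    alpha <- SummarizedExperiment::rowData(pe)$dispersion
    if (is.null(alpha)) {
        pe <- estimateDispersions(pe)
        alpha <- SummarizedExperiment::rowData(pe)$dispersion
    }
    k <- .normalizedCounts(pe)
    inA <- grp == conditionA
    inB <- grp == conditionB
    nA <- sum(inA); nB <- sum(inB)
    muA <- rowMeans(k[, inA, drop = FALSE])
    muB <- rowMeans(k[, inB, drop = FALSE])
    c0 <- pseudocount
    lfc <- log2((muB + c0) / (muA + c0))
    se <- sqrt((1 / log(2))^2 *
               ((1 / nA) * (1 / (muA + c0) + alpha) +
                (1 / nB) * (1 / (muB + c0) + alpha)))
    z <- lfc / se
    p <- 2 * stats::pnorm(abs(z), lower.tail = FALSE)
    allZero <- rowSums(SummarizedExperiment::assay(pe, "counts")) == 0
    p[allZero] <- 1
    lfc[allZero] <- 0
    res <- DataFrame(feature = rownames(pe),
                     baseMean = unname(rowMeans(k)),
                     log2FoldChange = unname(lfc),
                     lfcSE = unname(se),
                     dispersion = unname(alpha),
                     pvalue = unname(p),
                     padj = unname(bhAdjust(p)))
    new("ContrastResult", conditionA = conditionA, conditionB = conditionB,
        results = res)
}
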