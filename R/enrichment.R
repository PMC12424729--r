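#' @include AllClasses.R AllGenerics.R
NULL

#' Count query intervals overlapping a feature set
#'
#' Each query interval is counted at most once, whenever it overlaps at
#' least one feature interval by >= 1 bp.
#'
#' @param query,feature `GRanges`.
#' @return Integer count.
#' @export
overlapCount <- function(query, feature) {
    sum(overlapsAny(query, feature, ignore.strand = TRUE))
}

#' Background-matched resampling enrichment
#'
#' Draws `N` random subsets of `|query|` intervals from the background
#' (uniformly, without replacement within a draw), evaluates the statistic on
#' each, and compares the observed statistic against this null: the
#' observed/expected ratio and the add-one empirical p-value
#' `(1 + #{null >= observed})/(N + 1)` (`<=` for `alternative =
#' "depletion"`). This mirrors the published procedure of drawing as many
#' random control-exclusive peaks as there are nucleation sites, 1,000 times.
#'
#' @param query `GRanges`; the set under test (e.g. nucleation sites).
#' @param background `GRanges` with at least `|query|` intervals (e.g.
#'   control-exclusive peaks).
#' @param feature `GRanges`; the labelled feature set (chromatin state,
#'   cofactor peaks, CGI class, loop anchors, ...).
#' @param N number of draws (default 1000).
#' @param seed mandatory RNG seed.
#' @param statistic `NULL` for the default overlap count (computed by a fast
#'   indicator-resampling path), or `function(gr, feature)` returning a
#'   scalar.
#' @param alternative `"enrichment"` (default) or `"depletion"`.
#' @return A [ResamplingResult-class].
#' @export
resampleEnrichment <- function(query, background, feature, N = 1000L, seed,
                               statistic = NULL,
                               alternative = c("enrichment", "depletion")) {
    alternative <- match.arg(alternative)
    if (missing(seed)) stop("a seed is required for resampling")
    nq <- length(query)
    nb <- length(background)
    if (nb < nq)
        stop(sprintf("background (%d) smaller than query (%d)", nb, nq))
    N <- as.integer(N)
    seed <- as.integer(seed)
    set.seed(seed)
    if (is.null(statistic)) {
        observed <- overlapCount(query, feature)
        hit <- overlapsAny(background, feature, ignore.strand = TRUE)
        null <- vapply(seq_len(N),
                       function(i) sum(hit[sample.int(nb, nq)]), numeric(1))
    } else {
        observed <- statistic(query, feature)
        null <- vapply(seq_len(N),
                       function(i) statistic(background[sample.int(nb, nq)], feature),
                       numeric(1))
    }
    expected <- mean(null)
    oe <- if (expected > 0) observed / expected else NA_real_
    extreme <- if (alternative == "enrichment") sum(null >= observed)
               else sum(null <= observed)
    new("ResamplingResult", observed = as.numeric(observed), nullDraws = null,
        expected = expected, oeRatio = oe,
        pEmpirical = (1 + extreme) / (N + 1), N = N, seed = seed,
        alternative = alternative)
}

## Exact two-sided Fisher p by probability-mass ordering: sum of
## hypergeometric probabilities not exceeding the observed table's (with the
## customary 1e-7 relative guard against ties lost to rounding).
.fisherP <- function(a, b, c, d) {
    k <- max(0L, a + b - (b + d)):min(a + b, a + c)
    probs <- stats::dhyper(k, a + c, b + d, a + b)
    pObs <- stats::dhyper(a, a + c, b + d, a + b)
    min(1, sum(probs[probs <= pObs * (1 + 1e-7)]))
}

#' Fisher's exact test on interval-set overlap
#'
#' Builds the 2x2 table (query hit / query miss / background hit /
#' background miss) from [overlapCount()] on each set and computes the
#' two-sided exact p-value by probability-mass ordering. The odds ratio is
#' the sample odds ratio `(a d)/(b c)`, with the Haldane-Anscombe +0.5
#' correction to all cells when any cell is zero.
#'
#' @param query,background disjoint `GRanges` sets.
#' @param feature `GRanges` feature set.
#' @return A list with `table` (named a/b/c/d), `p` and `oddsRatio`.
#' @export
fisherOverlap <- function(query, background, feature) {
    if (!length(query) || !length(background))
        stop("query and background must be non-empty")
    if (sum(GenomicRanges::countOverlaps(query, background,
                                         ignore.strand = TRUE)) > 0)
        stop("query and background must be disjoint interval sets")
    a <- overlapCount(query, feature)
    b <- length(query) - a
    cc <- overlapCount(background, feature)
    d <- length(background) - cc
    orr <- if (any(c(a, b, cc, d) == 0))
        ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (cc + 0.5))
    else (a * d) / (b * cc)
    list(table = c(a = a, b = b, c = cc, d = d),
         p = .fisherP(a, b, cc, d),
         oddsRatio = orr)
}

#' Binned mean signal profile over intervals
#'
#' Each interval is rescaled to `nBins` equal sub-windows and the per-base
#' bedGraph signal (missing bases count as 0) is averaged within each bin.
#' Intervals narrower than `nBins` are computed with repeated-base windows
#' and flagged.
#'
#' @param intervals `GRanges` of regions to profile.
#' @param signal sorted, disjoint `GRanges` with a `score` column (a
#'   bedGraph, e.g. from [readBedGraph()]).
#' @param nBins number of sub-windows per interval (default 100).
#' @return A list with `profile` (mean per-bin signal across intervals),
#'   `perInterval` (interval x bin matrix), `mean` (scalar mean over all
#'   bins) and `narrow` (logical flag per interval).
#' @export
signalDensity <- function(intervals, signal, nBins = 100L) {
    cov <- GenomicRanges::coverage(signal, weight = signal$score)
    nBins <- as.integer(nBins)
    chroms <- as.character(GenomicRanges::seqnames(intervals))
    mat <- matrix(0, nrow = length(intervals), ncol = nBins)
    narrow <- width(intervals) < nBins
    for (i in seq_along(intervals)) {
        chr <- chroms[i]
        rle <- if (chr %in% names(cov)) cov[[chr]] else S4Vectors::Rle(0, 0)
        s <- start(intervals)[i]; e <- end(intervals)[i]
        wd <- e - s + 1L
        ## equal sub-windows over [s, e], floating boundaries floored to bases
        b0 <- s + floor((seq_len(nBins) - 1L) * wd / nBins)
        b1 <- s + ceiling(seq_len(nBins) * wd / nBins) - 1L
        b1 <- pmax(b1, b0)
        vals <- vapply(seq_len(nBins), function(k) {
            lo <- b0[k]; hi <- min(b1[k], length(rle))
            if (lo > length(rle)) return(0)
            mean(as.numeric(S4Vectors::window(rle, lo, hi)))
        }, numeric(1))
        ## bases beyond the chromosome's covered end carry signal 0
        beyond <- b1 > length(rle) & b0 <= length(rle)
        if (any(beyond)) {
            vals[beyond] <- vapply(which(beyond), function(k) {
                nIn <- length(rle) - b0[k] + 1L
                nTot <- b1[k] - b0[k] + 1L
                sum(as.numeric(S4Vectors::window(rle, b0[k], length(rle)))) / nTot
            }, numeric(1))
        }
        vals[b0 > length(rle)] <- 0
        mat[i, ] <- vals
    }
    list(profile = colMeans(mat), perInterval = mat,
         mean = mean(mat), narrow = narrow)
}
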