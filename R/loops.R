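#' @include AllClasses.R AllGenerics.R io.R
NULL

#' Count nucleation anchors per loop
#'
#' An anchor counts as a nucleation anchor iff it overlaps at least one
#' nucleation interval by >= 1 bp (per-anchor boolean: an anchor covering
#' two nucleation peaks still counts once).
#'
#' @param loops a [LoopSet-class].
#' @param nucleation `GRanges` of nucleation sites.
#' @return The LoopSet with `nNucleationAnchors` filled (0, 1 or 2).
#' @export
classifyLoopAnchors <- function(loops, nucleation) {
    h1 <- overlapsAny(anchorOne(loops), nucleation, ignore.strand = TRUE)
    h2 <- overlapsAny(anchorTwo(loops), nucleation, ignore.strand = TRUE)
    loops@loopData$nNucleationAnchors <- as.integer(h1) + as.integer(h2)
    validObject(loops)
    loops
}

#' Loop span statistics by anchor class, with one-way ANOVA
#'
#' Intrachromosomal loops are grouped by `nNucleationAnchors`; per-group
#' sizes and mean spans are reported together with the classical one-way
#' ANOVA F statistic (between-group over within-group mean square) and its
#' p-value.
#'
#' @param loops a [LoopSet-class] after [classifyLoopAnchors()].
#' @return A list with `groups` (data.frame of class, n, mean span), `F`,
#'   `df` and `p`.
#' @export
spanStats <- function(loops) {
    dat <- loopData(loops)
    keep <- !dat$interchromosomal
    span <- dat$span[keep]
    grp <- dat$nNucleationAnchors[keep]
    if (is.null(grp)) stop("run classifyLoopAnchors() first")
    tab <- table(grp)
    if (length(tab) < 2L) stop("ANOVA requires at least 2 non-empty groups")
    n <- length(span)
    G <- length(tab)
    if (n == G) stop("within-group variance undefined (one loop per group)")
    gm <- tapply(span, grp, mean)
    grand <- mean(span)
    ssb <- sum(tab * (gm - grand)^2)
    ssw <- sum((span - gm[as.character(grp)])^2)
    Fstat <- (ssb / (G - 1)) / (ssw / (n - G))
    p <- stats::pf(Fstat, G - 1, n - G, lower.tail = FALSE)
    list(groups = data.frame(nNucleationAnchors = as.integer(names(tab)),
                             n = as.integer(tab), meanSpan = as.numeric(gm)),
         F = Fstat, df = c(G - 1L, n - G), p = p)
}

.binIndex <- function(cm, pos) {
    ## 1-based genomic position -> 1-based bin index
    idx <- floor(((pos - 1) - cm@bins[1L]) / cm@resolution) + 1L
    idx[idx < 1L | idx > length(cm@bins)] <- NA_integer_
    idx
}

#' Aggregate Peak Analysis
#'
#' For each intrachromosomal loop whose chromosome has a matrix, the loop
#' pixel is (bin of anchor1 midpoint, bin of anchor2 midpoint), anchor1 on
#' rows. Loops are excluded (and counted in `nExcluded`) when the
#' `(2w+1) x (2w+1)` window leaves the matrix or when the pixel lies within
#' `2w` bins of the diagonal. The aggregate is the element-wise mean of the
#' included windows; the score is the centre pixel over the mean of the
#' 3x3 lower-left corner (rows beyond the centre, columns before it — the
#' shorter-genomic-distance background quadrant).
#'
#' @param loops a [LoopSet-class].
#' @param matrices a [ContactMatrix-class] or a list of them (one
#'   resolution; keyed by chromosome).
#' @param w window half-width in bins (default 5).
#' @return An [APAResult-class].
#' @export
apa <- function(loops, matrices, w = 5L) {
    if (is(matrices, "ContactMatrix")) matrices <- list(matrices)
    chromOf <- vapply(matrices, function(m) m@chrom, "")
    names(matrices) <- chromOf
    res <- unique(vapply(matrices, binResolution, numeric(1)))
    if (length(res) != 1L) stop("all matrices must share one resolution")
    w <- as.integer(w)
    side <- 2L * w + 1L
    acc <- matrix(0, side, side)
    nUsed <- 0L
    nExcl <- 0L
    dat <- loopData(loops)
    a1 <- anchorOne(loops); a2 <- anchorTwo(loops)
    mid1 <- floor((start(a1) + end(a1)) / 2)
    mid2 <- floor((start(a2) + end(a2)) / 2)
    chr <- as.character(GenomicRanges::seqnames(a1))
    for (i in seq_len(length(loops))) {
        if (dat$interchromosomal[i] || !chr[i] %in% names(matrices)) {
            nExcl <- nExcl + 1L
            next
        }
        cm <- matrices[[chr[i]]]
        i1 <- .binIndex(cm, mid1[i])
        i2 <- .binIndex(cm, mid2[i])
        nb <- length(cm@bins)
        if (is.na(i1) || is.na(i2) ||
            i1 - w < 1L || i1 + w > nb || i2 - w < 1L || i2 + w > nb ||
            abs(i2 - i1) <= 2L * w) {
            nExcl <- nExcl + 1L
            next
        }
        acc <- acc + cm@values[(i1 - w):(i1 + w), (i2 - w):(i2 + w)]
        nUsed <- nUsed + 1L
    }
    if (nUsed == 0L) stop("no loop passed the APA inclusion rules")
    agg <- acc / nUsed
    corner <- agg[(2L * w - 1L):(2L * w + 1L), 1:3]
    score <- agg[w + 1L, w + 1L] / mean(corner)
    new("APAResult", w = w, aggregate = agg, nLoops = nUsed,
        nExcluded = nExcl, score = score)
}

#' Virtual 4C profile from a contact matrix
#'
#' Extracts the contact-matrix row of the viewpoint bin, masks the viewpoint
#' bin itself to zero, and normalises the profile to sum to 1.
#'
#' @param cm a [ContactMatrix-class].
#' @param viewpoint `GRanges` (length 1) whose midpoint selects the bin.
#' @return `data.frame` with columns `binStart` (0-based) and `value`.
#' @export
virtual4C <- function(cm, viewpoint) {
    stopifnot(length(viewpoint) == 1L)
    if (as.character(GenomicRanges::seqnames(viewpoint)) != cm@chrom)
        stop("viewpoint chromosome does not match the matrix")
    mid <- floor((start(viewpoint) + end(viewpoint)) / 2)
    i <- .binIndex(cm, mid)
    if (is.na(i)) stop("viewpoint midpoint falls outside the matrix span")
    row <- cm@values[i, ]
    row[i] <- 0
    tot <- sum(row)
    if (tot <= 0) stop("no signal in the viewpoint row after masking")
    data.frame(binStart = cm@bins, value = row / tot)
}

#' Per-chromosome loop and anchor summary
#'
#' @param loops a [LoopSet-class] after [classifyLoopAnchors()].
#' @return `data.frame` with, per chromosome: loop count and counts with
#'   0/1/2 nucleation anchors (intrachromosomal loops only).
#' @export
loopSummaryByChrom <- function(loops) {
    dat <- loopData(loops)
    keep <- !dat$interchromosomal
    chr <- as.character(GenomicRanges::seqnames(anchorOne(loops)))[keep]
    nn <- dat$nNucleationAnchors[keep]
    out <- do.call(rbind, lapply(sort(unique(chr)), function(cc) {
        sel <- chr == cc
        data.frame(chrom = cc, nLoops = sum(sel),
                   anchors0 = sum(nn[sel] == 0L), anchors1 = sum(nn[sel] == 1L),
                   anchors2 = sum(nn[sel] == 2L))
    }))
    out
}
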