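#' @include AllClasses.R
NULL

#' Classifier thresholds
#'
#' The published selection thresholds: `|log2FoldChange| > 1.5` and adjusted
#' p-value `< 0.005`, both strict inequalities (boundary values excluded).
#'
#' @param lfcMin minimum absolute log2 fold change (default 1.5).
#' @param padjMax maximum BH-adjusted p-value (default 0.005).
#' @return A validated list of thresholds.
#' @export
classifierThresholds <- function(lfcMin = 1.5, padjMax = 0.005) {
    stopifnot(lfcMin > 0, padjMax > 0, padjMax < 1)
    list(lfcMin = lfcMin, padjMax = padjMax)
}

#' Flag per-condition presence of union peaks
#'
#' A union peak is present in a condition iff it overlaps at least one peak
#' independently called in that condition by >= 1 bp.
#'
#' @param union `GRanges` of union peaks.
#' @param calls named list of per-condition `GRanges` of peak calls; names
#'   must include `"steady_state"`, `"auxin"`, `"reintroduction"`.
#' @return Logical matrix, one row per union peak, one column per condition.
#' @export
flagPresence <- function(union, calls) {
    miss <- setdiff(CONDITIONS, names(calls))
    if (length(miss))
        stop("missing condition peak calls: ", paste(miss, collapse = ", "))
    pres <- vapply(CONDITIONS,
                   function(cond) overlapsAny(union, calls[[cond]], ignore.strand = TRUE),
                   logical(length(union)))
    if (length(union) == 1L)
        pres <- matrix(pres, nrow = 1L, dimnames = list(NULL, CONDITIONS))
    rownames(pres) <- names(union)
    pres
}

#' Classify union peaks from the dual-contrast degron dynamics
#'
#' Newly acquired peaks (absent from steady-state calls) are labelled first:
#' `new_in_auxin` if present in auxin calls, else `new_in_reintro` if present
#' in reintroduction calls; both are excluded from the nucleation /
#' control-exclusive bookkeeping. Among steady-state-present peaks, a
#' nucleation site must show a significant signal loss under auxin
#' (`log2FC < -lfcMin`, `padj < padjMax` in contrast 1) AND a significant
#' rebound upon reintroduction (`log2FC > +lfcMin`, `padj < padjMax` in
#' contrast 2). Non-nucleation steady-state peaks still present in auxin
#' calls are `persistent`; the remainder are `control_exclusive`. Peaks
#' present in no condition are `excluded`.
#'
#' @param union `GRanges` of union peaks.
#' @param presence logical matrix from [flagPresence()].
#' @param contrast1 [ContrastResult-class] for auxin vs steady state.
#' @param contrast2 [ContrastResult-class] for reintroduction vs auxin.
#' @param thresholds from [classifierThresholds()].
#' @return `union` with metadata columns `label`, `lfc1`, `padj1`, `lfc2`,
#'   `padj2` and the three presence flags. Labels are mutually exclusive and
#'   cover every peak.
#' @export
classifyPeaks <- function(union, presence, contrast1, contrast2,
                          thresholds = classifierThresholds()) {
    r1 <- resultsTable(contrast1)
    r2 <- resultsTable(contrast2)
    if (!identical(as.character(r1$feature), names(union)) ||
        !identical(as.character(r2$feature), names(union)))
        stop("contrast feature sets must match the union peaks (same order)")
    if (!identical(rownames(presence), names(union)))
        stop("presence flags must be computed on the same union peaks")

    inSS <- presence[, "steady_state"]
    inAux <- presence[, "auxin"]
    inRe <- presence[, "reintroduction"]

    label <- rep("excluded", length(union))
    newAux <- !inSS & inAux
    newRe <- !inSS & !newAux & inRe
    label[newAux] <- "new_in_auxin"
    label[newRe] <- "new_in_reintro"

    nucl <- inSS &
        r1$log2FoldChange < -thresholds$lfcMin & r1$padj < thresholds$padjMax &
        r2$log2FoldChange > +thresholds$lfcMin & r2$padj < thresholds$padjMax
    label[inSS] <- "control_exclusive"
    label[inSS & inAux & !nucl] <- "persistent"
    label[nucl] <- "nucleation"

    mcols(union) <- DataFrame(label = factor(label, levels = PEAK_CLASSES),
                              lfc1 = r1$log2FoldChange, padj1 = r1$padj,
                              lfc2 = r2$log2FoldChange, padj2 = r2$padj,
                              present_steady_state = inSS,
                              present_auxin = inAux,
                              present_reintroduction = inRe)
    union
}

#' Per-class peak width summaries
#'
#' @param classified classified union peaks from [classifyPeaks()] (or any
#'   `GRanges` with a `label` column).
#' @return `data.frame` with one row per class: `n`, `median`, `q1`, `q3` of
#'   peak widths in bp (`NA` for empty classes).
#' @export
widthStats <- function(classified) {
    lab <- classified$label
    classes <- if (is.factor(lab)) levels(lab) else unique(lab)
    out <- lapply(classes, function(cl) {
        w <- width(classified[lab == cl])
        if (!length(w))
            data.frame(class = cl, n = 0L, median = NA_real_,
                       q1 = NA_real_, q3 = NA_real_)
        else
            data.frame(class = cl, n = length(w),
                       median = stats::median(w),
                       q1 = unname(stats::quantile(w, 0.25)),
                       q3 = unname(stats::quantile(w, 0.75)))
    })
    do.call(rbind, out)
}

#' Nearest-neighbour interpeak distances
#'
#' For each peak, the minimum edge-to-edge gap to any other peak on the same
#' chromosome (0 for overlapping or book-ended peaks). A sole peak on its
#' chromosome gets `NA` and is excluded from summaries.
#'
#' @param peaks a `GRanges` with at least 2 peaks.
#' @return Numeric vector of distances in bp, parallel to `peaks`.
#' @export
interpeakDistances <- function(peaks) {
    if (length(peaks) < 2L)
        stop("interpeak distances require at least 2 peaks")
    hits <- GenomicRanges::distanceToNearest(peaks, ignore.strand = TRUE)
    d <- rep(NA_real_, length(peaks))
    d[S4Vectors::queryHits(hits)] <- mcols(hits)$distance
    d
}

#' Annotate peaks with their genomic context
#'
#' The peak midpoint is tested against annotations in priority order:
#' promoter (TSS +/- `promoterHalfwidth`) > exon > intron (gene body outside
#' exons) > intergenic. Each peak receives exactly one label.
#'
#' @param peaks `GRanges` of peaks.
#' @param genes gene model `GRanges` from [readGeneModel()] (bodies with a
#'   `tss` column).
#' @param exons optional `GRanges` of exons; when absent, no peak is
#'   labelled `exon`.
#' @param promoterHalfwidth promoter window half-width in bp (default 2000).
#' @return Character vector of context labels, parallel to `peaks`.
#' @export
annotateGenomicContext <- function(peaks, genes, exons = NULL,
                                   promoterHalfwidth = 2000) {
    mid <- GRanges(GenomicRanges::seqnames(peaks),
                   IRanges(start = floor((start(peaks) + end(peaks)) / 2), width = 1L))
    prom <- GRanges(GenomicRanges::seqnames(genes),
                    IRanges(start = pmax(1L, genes$tss - promoterHalfwidth),
                            end = genes$tss + promoterHalfwidth))
    label <- rep("intergenic", length(peaks))
    inBody <- overlapsAny(mid, genes, ignore.strand = TRUE)
    label[inBody] <- "intron"
    if (!is.null(exons))
        label[overlapsAny(mid, exons, ignore.strand = TRUE)] <- "exon"
    label[overlapsAny(mid, prom, ignore.strand = TRUE)] <- "promoter"
    label
}

#' Nearest gene per peak
#'
#' Finds the gene whose TSS is closest to the peak midpoint on the same
#' chromosome. Ties go to the lexicographically smallest `gene_id`. The
#' reported distance is signed relative to the TSS, respecting strand
#' (positive = downstream of the TSS in the gene's orientation).
#'
#' @param peaks `GRanges` of peaks.
#' @param genes gene model `GRanges` with `gene_id` and `tss` columns.
#' @return `data.frame` with columns `peak`, `gene_id`, `distance`
#'   (`NA` gene for peaks on chromosomes without genes).
#' @export
nearestGene <- function(peaks, genes) {
    if (!length(genes)) stop("at least one gene is required")
    pmid <- floor((start(peaks) + end(peaks)) / 2)
    pchr <- as.character(GenomicRanges::seqnames(peaks))
    gchr <- as.character(GenomicRanges::seqnames(genes))
    out <- data.frame(peak = if (is.null(names(peaks))) seq_along(peaks) else names(peaks),
                      gene_id = NA_character_, distance = NA_real_,
                      stringsAsFactors = FALSE)
    for (i in seq_along(peaks)) {
        j <- which(gchr == pchr[i])
        if (!length(j)) next
        dd <- abs(pmid[i] - genes$tss[j])
        best <- j[dd == min(dd)]
        if (length(best) > 1L)
            best <- best[order(genes$gene_id[best])][1L]
        raw <- pmid[i] - genes$tss[best]
        minus <- as.character(strand(genes)[best]) == "-"
        out$gene_id[i] <- genes$gene_id[best]
        out$distance[i] <- if (minus) -raw else raw
    }
    out
}
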