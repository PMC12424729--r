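#' @include AllClasses.R enrichment.R
NULL

#' Per-site methylation call
#'
#' A CpG site is methylated iff its level exceeds 0.5 (strict, per the
#' ">50% methylation" rule: a site at exactly 0.5 is not methylated).
#'
#' @param level numeric vector of methylation fractions in `[0, 1]` (or a
#'   `GRanges` with a `level` column).
#' @param cutoff site-level threshold (default 0.5).
#' @return Logical vector.
#' @export
callSiteMethylation <- function(level, cutoff = 0.5) {
    if (is(level, "GRanges")) level <- level$level
    if (any(level < 0 | level > 1, na.rm = TRUE))
        stop("methylation levels must lie in [0, 1]")
    level > cutoff
}

#' CpG-island methylation status
#'
#' For each island: `n_cpg` = covered CpG sites overlapping the island,
#' `n_meth` = those methylated per [callSiteMethylation()]. Islands with
#' >= 20% methylated CpGs are called `methylated` (inclusive boundary:
#' exactly 20% is methylated), < 20% `unmethylated`, and islands with no
#' covered CpGs `no_data` (excluded from enrichment denominators).
#'
#' @param islands `GRanges` of CpG islands.
#' @param records width-1 `GRanges` methylation table (see
#'   [readMethylationTable()]).
#' @param islandCutoff methylated-CpG fraction threshold (default 0.2).
#' @param siteCutoff per-site threshold passed to [callSiteMethylation()].
#' @return `islands` with metadata columns `n_cpg`, `n_meth`, `frac_meth`
#'   and `status`.
#' @export
callIslandStatus <- function(islands, records, islandCutoff = 0.2,
                             siteCutoff = 0.5) {
    methSite <- callSiteMethylation(records, cutoff = siteCutoff)
    nCpG <- GenomicRanges::countOverlaps(islands, records, ignore.strand = TRUE)
    nMeth <- GenomicRanges::countOverlaps(islands, records[methSite],
                                          ignore.strand = TRUE)
    frac <- ifelse(nCpG > 0, nMeth / nCpG, NA_real_)
    status <- ifelse(nCpG == 0L, "no_data",
                     ifelse(frac >= islandCutoff, "methylated", "unmethylated"))
    if (any(nCpG == 0L))
        warning(sum(nCpG == 0L), " island(s) with zero covered CpGs (no_data)")
    mcols(islands)$n_cpg <- nCpG
    mcols(islands)$n_meth <- nMeth
    mcols(islands)$frac_meth <- frac
    mcols(islands)$status <- factor(status,
                                    levels = c("methylated", "unmethylated", "no_data"))
    islands
}

#' GC content of sequences
#'
#' `(#G + #C) / (#A + #C + #G + #T)`, case-insensitive; `N` bases are
#' excluded from the denominator. Empty or all-N sequences return `NA`.
#'
#' @param sequence a character vector, `DNAString` or `DNAStringSet`.
#' @return Numeric vector of fractions in `[0, 1]` (or `NA`).
#' @export
gcContent <- function(sequence) {
    if (is.character(sequence))
        sequence <- Biostrings::DNAStringSet(toupper(sequence))
    if (is(sequence, "DNAString"))
        sequence <- Biostrings::DNAStringSet(sequence)
    freq <- Biostrings::letterFrequency(sequence, letters = c("A", "C", "G", "T"))
    denom <- rowSums(freq)
    ifelse(denom > 0, (freq[, "G"] + freq[, "C"]) / denom, NA_real_)
}

#' GC content of genomic regions
#'
#' Extracts each region's sequence from a genome and computes its GC
#' fraction (N excluded), without materialising per-region strings.
#'
#' @param genome a `DNAStringSet` keyed by chromosome.
#' @param gr `GRanges` of regions.
#' @return Numeric vector parallel to `gr`.
#' @export
regionGC <- function(genome, gr) {
    out <- rep(NA_real_, length(gr))
    chroms <- as.character(GenomicRanges::seqnames(gr))
    for (cc in unique(chroms)) {
        if (!cc %in% names(genome)) next
        sel <- chroms == cc
        v <- Biostrings::Views(genome[[cc]],
                               start = start(gr)[sel],
                               end = pmin(end(gr)[sel], length(genome[[cc]])))
        freq <- Biostrings::letterFrequency(v, letters = c("A", "C", "G", "T"))
        denom <- rowSums(freq)
        out[sel] <- ifelse(denom > 0, (freq[, "G"] + freq[, "C"]) / denom,
                           NA_real_)
    }
    out
}

#' CGI methylation-status enrichment at nucleation sites
#'
#' Runs [resampleEnrichment()] twice, with the feature set restricted to
#' unmethylated and to methylated islands (islands with `no_data` never
#' enter either feature set), reporting the observed/expected ratio per
#' status.
#'
#' @param nucleation query `GRanges` (nucleation sites).
#' @param background `GRanges` (control-exclusive peaks).
#' @param islandCalls output of [callIslandStatus()].
#' @param N resampling draws (default 1000); @param seed RNG seed.
#' @return Named list of [ResamplingResult-class]: `unmethylated`,
#'   `methylated`.
#' @export
cgiEnrichment <- function(nucleation, background, islandCalls, N = 1000L, seed) {
    out <- lapply(c(unmethylated = "unmethylated", methylated = "methylated"),
                  function(st) {
        resampleEnrichment(nucleation, background,
                           islandCalls[!is.na(islandCalls$status) &
                                       islandCalls$status == st],
                           N = N, seed = seed)
    })
    out
}
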