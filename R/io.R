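#' @include AllClasses.R
NULL

## On-disk coordinates follow the BED convention (0-based, half-open);
## in memory everything is a GRanges (1-based, closed), the Bioconductor
## currency. The two conversions below are the only places the base changes;
## no other operation re-interprets coordinates.
.bedToGRanges <- function(chrom, start0, end, ...) {
    GRanges(chrom, IRanges(start = start0 + 1L, end = end), ...)
}
.grangesToBedStart <- function(gr) start(gr) - 1L

.isDataLine <- function(lines) {
    !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
}

#' Read peak intervals from a BED or narrowPeak file
#'
#' Accepts BED3+ and ENCODE narrowPeak (tab-separated). Column 4, when
#' present, supplies peak names; otherwise names `peak_<i>` are generated
#' after sorting. Column 5 is kept as `score`, column 6 as strand. Extra
#' narrowPeak columns (signalValue, pValue, qValue, summit) are ignored.
#' `track`, `browser` and `#` comment lines are skipped.
#'
#' @param path path to the file.
#' @param label optional set label stored in `metadata(gr)$label`.
#' @return A sorted `GRanges` with unique names.
#' @export
readPeakBed <- function(path, label = basename(path)) {
    lines <- readLines(path)
    keep <- .isDataLine(lines)
    lineno <- which(keep)
    lines <- lines[keep]
    if (!length(lines))
        return(GRanges())
    fields <- strsplit(lines, "\t", fixed = TRUE)
    ncol <- lengths(fields)
    if (any(ncol < 3L))
        stop(sprintf("parse error at line %d: fewer than 3 tab-separated columns",
                     lineno[which(ncol < 3L)[1L]]))
    chrom <- vapply(fields, `[[`, "", 1L)
    start0 <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
    end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
    bad <- is.na(start0) | is.na(end)
    if (any(bad))
        stop(sprintf("parse error at line %d: non-integer coordinates", lineno[which(bad)[1L]]))
    bad <- start0 >= end | start0 < 0L
    if (any(bad))
        stop(sprintf("parse error at line %d: requires 0 <= start < end", lineno[which(bad)[1L]]))
    nm <- ifelse(ncol >= 4L, vapply(fields, function(f) f[min(4L, length(f))], ""), NA_character_)
    score <- ifelse(ncol >= 5L,
                    suppressWarnings(as.numeric(vapply(fields, function(f) f[min(5L, length(f))], ""))),
                    NA_real_)
    strand <- ifelse(ncol >= 6L, vapply(fields, function(f) f[min(6L, length(f))], ""), "*")
    strand[!strand %in% c("+", "-")] <- "*"
    gr <- .bedToGRanges(chrom, start0, end, strand = strand)
    ord <- order(as.character(GenomicRanges::seqnames(gr)), start(gr), end(gr))
    gr <- gr[ord]
    nm <- nm[ord]
    score <- score[ord]
    if (all(is.na(nm))) nm <- paste0("peak_", seq_along(gr))
    if (anyDuplicated(nm))
        stop("duplicate interval names in ", path)
    names(gr) <- nm
    if (!all(is.na(score))) gr$score <- score
    metadata(gr)$label <- label
    gr
}

#' Write peak intervals as BED
#'
#' Coordinates are emitted 0-based half-open; name, score and strand columns
#' are written when present. Round-trips [readPeakBed()] output byte-for-byte
#' for sorted named input.
#'
#' @param gr a `GRanges` (names used as column 4).
#' @param path output path.
#' @param header optional comment lines (written prefixed with `#`).
#' @export
writePeakBed <- function(gr, path, header = NULL) {
    cols <- list(as.character(GenomicRanges::seqnames(gr)),
                 format(.grangesToBedStart(gr), scientific = FALSE, trim = TRUE),
                 format(end(gr), scientific = FALSE, trim = TRUE),
                 if (is.null(names(gr))) paste0("peak_", seq_along(gr)) else names(gr))
    if (!is.null(gr$score)) {
        cols <- c(cols, list(gr$score))
        st <- as.character(strand(gr))
        if (any(st != "*")) { st[st == "*"] <- "."; cols <- c(cols, list(st)) }
    }
    lines <- do.call(paste, c(cols, sep = "\t"))
    if (!is.null(header)) lines <- c(paste0("# ", header), lines)
    writeLines(lines, path)
    invisible(path)
}

#' Read chromatin loops from a BEDPE file
#'
#' Requires >= 6 tab-separated columns (chrom1, start1, end1, chrom2, start2,
#' end2). Anchors are normalised so anchor1 precedes anchor2 by
#' (chrom, start); interchromosomal pairs are flagged and retained with
#' `span = NA`.
#'
#' @param path path to the BEDPE file.
#' @return A [LoopSet-class].
#' @export
readBedpe <- function(path) {
    lines <- readLines(path)
    keep <- .isDataLine(lines)
    lineno <- which(keep)
    lines <- lines[keep]
    fields <- strsplit(lines, "\t", fixed = TRUE)
    ncol <- lengths(fields)
    if (any(ncol < 6L))
        stop(sprintf("parse error at line %d: BEDPE requires >= 6 columns",
                     lineno[which(ncol < 6L)[1L]]))
    g <- function(i) vapply(fields, `[[`, "", i)
    num <- function(i) {
        v <- suppressWarnings(as.numeric(g(i)))
        if (anyNA(v))
            stop(sprintf("parse error at line %d: non-numeric coordinate",
                         lineno[which(is.na(v))[1L]]))
        v
    }
    a1 <- .bedToGRanges(g(1), num(2), num(3))
    a2 <- .bedToGRanges(g(4), num(5), num(6))
    loopSet(a1, a2)
}

#' Construct a LoopSet from two parallel anchor GRanges
#'
#' @param anchor1,anchor2 parallel `GRanges`; reordered so anchor1 comes
#'   first in (chrom, start) order.
#' @return A [LoopSet-class] with spans (midpoint distance) computed.
#' @export
loopSet <- function(anchor1, anchor2) {
    stopifnot(length(anchor1) == length(anchor2))
    c1 <- as.character(GenomicRanges::seqnames(anchor1))
    c2 <- as.character(GenomicRanges::seqnames(anchor2))
    swap <- (c1 > c2) | (c1 == c2 & start(anchor1) > start(anchor2))
    if (any(swap)) {
        tmp <- anchor1[swap]
        anchor1[swap] <- anchor2[swap]
        anchor2[swap] <- tmp
    }
    inter <- as.character(GenomicRanges::seqnames(anchor1)) !=
        as.character(GenomicRanges::seqnames(anchor2))
    mid <- function(gr) (start(gr) + end(gr)) / 2
    span <- ifelse(inter, NA_real_, abs(mid(anchor2) - mid(anchor1)))
    new("LoopSet", anchor1 = GenomicRanges::granges(anchor1),
        anchor2 = GenomicRanges::granges(anchor2),
        loopData = DataFrame(span = span, interchromosomal = inter))
}

#' Write a LoopSet as BEDPE
#' @param loops a [LoopSet-class]; @param path output path.
#' @export
writeBedpe <- function(loops, path) {
    a1 <- anchorOne(loops); a2 <- anchorTwo(loops)
    lines <- paste(as.character(GenomicRanges::seqnames(a1)),
                   .grangesToBedStart(a1), end(a1),
                   as.character(GenomicRanges::seqnames(a2)),
                   .grangesToBedStart(a2), end(a2), sep = "\t")
    writeLines(lines, path)
    invisible(path)
}

#' Read a single-base CpG methylation table
#'
#' TSV with columns chrom, pos (0-based position of the CpG cytosine), level
#' (methylation fraction in `[0, 1]`). A header row is detected by a
#' non-numeric `pos` field and skipped.
#'
#' @param path path to the TSV.
#' @return A sorted width-1 `GRanges` with metadata column `level`.
#' @export
readMethylationTable <- function(path) {
    lines <- readLines(path)
    lines <- lines[.isDataLine(lines)]
    if (length(lines) && {
        f1 <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
        length(f1) >= 2L && is.na(suppressWarnings(as.numeric(f1[2L])))
    }) lines <- lines[-1L]
    if (!length(lines)) return(GRanges(level = numeric(0)))
    fields <- strsplit(lines, "\t", fixed = TRUE)
    if (any(lengths(fields) < 3L))
        stop("parse error: methylation table requires 3 columns (chrom, pos, level)")
    chrom <- vapply(fields, `[[`, "", 1L)
    pos <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
    level <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
    if (anyNA(pos) || anyNA(level))
        stop("parse error: non-numeric pos or level in methylation table")
    if (any(level < 0 | level > 1))
        stop("parse error: methylation level outside [0, 1] at line ",
             which(level < 0 | level > 1)[1L])
    gr <- GRanges(chrom, IRanges(start = pos + 1L, width = 1L), level = level)
    sort(gr, ignore.strand = TRUE)
}

#' Write a methylation table (chrom, pos 0-based, level)
#' @param meth width-1 `GRanges` with a `level` column; @param path output path.
#' @export
writeMethylationTable <- function(meth, path) {
    lines <- paste(as.character(GenomicRanges::seqnames(meth)),
                   start(meth) - 1L, format(meth$level, trim = TRUE), sep = "\t")
    writeLines(c("chrom\tpos\tlevel", lines), path)
    invisible(path)
}

#' Read a dense per-chromosome contact matrix
#'
#' @param pathMatrix whitespace-separated square numeric grid.
#' @param pathBins BED file of uniform-width bins on one chromosome, in
#'   genomic order, one per matrix row/column.
#' @return A [ContactMatrix-class]; input is symmetrised as `(M + t(M))/2`
#'   and the resolution inferred from the bins.
#' @export
readContactMatrix <- function(pathMatrix, pathBins) {
    bins <- readPeakBed(pathBins)
    chrom <- unique(as.character(GenomicRanges::seqnames(bins)))
    if (length(chrom) != 1L)
        stop("bins file must cover exactly one chromosome")
    w <- width(bins)
    if (length(unique(w)) != 1L)
        stop("non-uniform bin width in ", pathBins)
    m <- as.matrix(data.table::fread(pathMatrix, header = FALSE))
    dimnames(m) <- NULL
    if (nrow(m) != ncol(m))
        stop("contact matrix must be square, got ", nrow(m), " x ", ncol(m))
    if (nrow(m) != length(bins))
        stop(sprintf("dimension mismatch: %d bins but %d x %d matrix",
                     length(bins), nrow(m), ncol(m)))
    m <- (m + t(m)) / 2
    contactMatrix(chrom, .grangesToBedStart(bins), m, resolution = w[1L])
}

#' Construct a ContactMatrix
#' @param chrom chromosome name; @param binStarts 0-based bin starts;
#' @param values symmetric square matrix; @param resolution bin width (bp).
#' @export
contactMatrix <- function(chrom, binStarts, values, resolution) {
    new("ContactMatrix", chrom = chrom, resolution = as.numeric(resolution),
        bins = as.numeric(binStarts), values = values)
}

#' Write a ContactMatrix as a dense TSV plus a bins BED
#' @param cm a [ContactMatrix-class]; @param pathMatrix,@param pathBins output paths.
#' @export
writeContactMatrix <- function(cm, pathMatrix, pathBins) {
    data.table::fwrite(data.table::as.data.table(contactValues(cm)),
                       pathMatrix, sep = "\t", col.names = FALSE)
    b <- binStarts(cm)
    writeLines(paste(cm@chrom, format(b, scientific = FALSE, trim = TRUE),
                     format(b + binResolution(cm), scientific = FALSE, trim = TRUE),
                     paste0("bin_", seq_along(b)), sep = "\t"), pathBins)
    invisible(pathMatrix)
}

#' Read a gene model table
#'
#' TSV with columns gene_id, chrom, tss (0-based), start, end (0-based
#' half-open gene body) and strand. For `+` genes the TSS must fall inside
#' the body; `-` genes use the `tss = end - 1` convention.
#'
#' @param path path to the TSV (header row detected and skipped).
#' @return A `GRanges` of gene bodies with metadata columns `gene_id` and
#'   `tss` (1-based position of the transcription start site).
#' @export
readGeneModel <- function(path) {
    dt <- data.table::fread(path, header = "auto",
                            col.names = c("gene_id", "chrom", "tss", "start", "end", "strand"))
    gr <- GRanges(dt$chrom, IRanges(start = dt$start + 1L, end = dt$end),
                  strand = dt$strand, gene_id = dt$gene_id, tss = dt$tss + 1L)
    bad <- gr$tss < start(gr) | gr$tss > end(gr)
    if (any(bad))
        stop("gene model TSS outside gene body for ", dt$gene_id[bad][1L])
    names(gr) <- gr$gene_id
    sort(gr, ignore.strand = TRUE)
}

#' Read a bedGraph signal track
#'
#' @param path 4-column bedGraph (chrom, start, end, value); intervals must
#'   be sorted and non-overlapping.
#' @return A `GRanges` with metadata column `score`.
#' @export
readBedGraph <- function(path) {
    lines <- readLines(path)
    lines <- lines[.isDataLine(lines)]
    fields <- strsplit(lines, "\t", fixed = TRUE)
    if (any(lengths(fields) < 4L))
        stop("bedGraph requires 4 columns")
    gr <- .bedToGRanges(vapply(fields, `[[`, "", 1L),
                        as.numeric(vapply(fields, `[[`, "", 2L)),
                        as.numeric(vapply(fields, `[[`, "", 3L)))
    gr$score <- as.numeric(vapply(fields, `[[`, "", 4L))
    gr <- sort(gr, ignore.strand = TRUE)
    if (!GenomicRanges::isDisjoint(gr))
        stop("bedGraph intervals overlap; a per-base signal must be disjoint")
    gr
}

#' Read a counts table and sample sheet into a PeakExperiment
#'
#' @param pathCounts TSV, header row = sample ids, first column = feature id.
#' @param pathSamples TSV with columns sample, condition, replicate.
#' @param peaks optional `GRanges` of the features (matched by name).
#' @return A [PeakExperiment-class].
#' @export
readCountsTable <- function(pathCounts, pathSamples, peaks = NULL) {
    dt <- data.table::fread(pathCounts, header = TRUE)
    feats <- as.character(dt[[1L]])
    m <- as.matrix(dt[, -1L])
    rownames(m) <- feats
    ss <- data.table::fread(pathSamples, header = TRUE)
    if (!all(colnames(m) %in% ss$sample))
        stop("sample sheet does not cover all count columns")
    ss <- ss[match(colnames(m), ss$sample), ]
    if (!is.null(peaks)) peaks <- peaks[feats]
    peakExperiment(m, rowRanges = peaks, condition = ss$condition,
                   replicate = ss$replicate)
}

#' Write a PeakExperiment's counts and sample sheet
#' @param pe a [PeakExperiment-class]; @param pathCounts,@param pathSamples output paths.
#' @export
writeCountsTable <- function(pe, pathCounts, pathSamples) {
    m <- SummarizedExperiment::assay(pe, "counts")
    dt <- data.table::data.table(feature = rownames(m))
    for (j in colnames(m)) dt[[j]] <- m[, j]
    data.table::fwrite(dt, pathCounts, sep = "\t")
    cd <- SummarizedExperiment::colData(pe)
    data.table::fwrite(data.table::data.table(sample = rownames(cd),
                                              condition = cd$condition,
                                              replicate = cd$replicate),
                       pathSamples, sep = "\t")
    invisible(pathCounts)
}

#' Write a ContrastResult as TSV
#' @param cr a [ContrastResult-class]; @param path output path;
#' @param header optional `#`-prefixed comment lines.
#' @export
writeContrastResults <- function(cr, path, header = NULL) {
    df <- as.data.frame(resultsTable(cr))
    con <- file(path, "w")
    on.exit(close(con))
    if (!is.null(header)) writeLines(paste0("# ", header), con)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
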