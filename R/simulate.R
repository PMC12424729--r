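#' @include AllClasses.R io.R
NULL

#' Build a synthetic-bundle configuration
#'
#' The defaults emulate the scale and planted structure of the mESC
#' Suz12-degron study design: 1,109 nucleation, 896 persistent and 3,832
#' control-exclusive steady-state peaks plus 372/448 newly acquired peaks;
#' 2 replicates per condition; planted dynamics of |log2FC| = 3; log-normal
#' peak widths with medians 1342 bp (nucleation) and 714 bp (all other
#' classes); CpG islands at GC >= 0.65 on a GC 0.42 background,
#' preferentially unmethylated at nucleation sites; 3892/260/102 loops with
#' 0/1/2 nucleation anchors and mean spans 0.18/0.33/0.86 Mb; and a 10 kb
#' contact matrix with 5x focal enrichment at loop pixels.
#'
#' @param seed mandatory RNG seed (scalar integer).
#' @param nPeaks named integer vector of peaks per class.
#' @param replicates replicates per condition (default 2).
#' @param chromLengths named numeric vector of chromosome lengths (bp).
#' @param widthMedians named (`nucleation`, `other`) log-normal width medians.
#' @param widthLogSd log-sd of peak widths.
#' @param effectSize planted |log2 fold change|.
#' @param baselineLogMean,baselineLogSd log-normal baseline mean parameters.
#' @param newPeakBaseline steady-state mean for newly acquired peaks.
#' @param dispersionRange uniform range for NB dispersion alpha
#'   (`Var = mu + alpha mu^2`).
#' @param sizeFactorLogSd log-sd of per-sample size factors.
#' @param nCGI,cgiWidth CpG island count and width (bp).
#' @param gcBackground,gcIsland GC fractions of background / island sequence.
#' @param cgiNucleationFraction,cgiControlFraction fraction of islands
#'   planted at nucleation / control-exclusive peaks (rest intergenic).
#' @param probUnmethylatedNucleation,probUnmethylatedElsewhere probability
#'   that an island is planted unmethylated, by location.
#' @param nLoops named (`zero`, `one`, `two`) loop counts by nucleation
#'   anchor class.
#' @param loopSpanMeans named (`zero`, `one`, `two`) mean spans in bp.
#' @param resolution contact-matrix bin width (default 10 kb).
#' @param focalEnrichment multiplicative enrichment at loop pixels.
#' @param decayScale scale `c` of the distance-decay background
#'   `c / (1 + |i - j|)`.
#' @return A validated [SimConfig-class].
#' @export
simConfig <- function(seed,
                      nPeaks = c(nucleation = 1109L, control_exclusive = 3832L,
                                 persistent = 896L, new_in_auxin = 372L,
                                 new_in_reintro = 448L),
                      replicates = 2L,
                      chromLengths = c(chr1 = 12e6, chr2 = 12e6,
                                       chr3 = 12e6, chr4 = 12e6),
                      widthMedians = c(nucleation = 1342, other = 714),
                      widthLogSd = 0.45,
                      effectSize = 3,
                      baselineLogMean = log(400), baselineLogSd = 0.6,
                      newPeakBaseline = 8,
                      dispersionRange = c(0.01, 0.1),
                      sizeFactorLogSd = 0.15,
                      nCGI = 1600L, cgiWidth = 1000,
                      gcBackground = 0.42, gcIsland = 0.70,
                      cgiNucleationFraction = 0.35, cgiControlFraction = 0.5,
                      probUnmethylatedNucleation = 0.9,
                      probUnmethylatedElsewhere = 0.5,
                      nLoops = c(zero = 3892L, one = 260L, two = 102L),
                      loopSpanMeans = c(zero = 0.18e6, one = 0.33e6, two = 0.86e6),
                      resolution = 10000, focalEnrichment = 5,
                      decayScale = 100) {
    if (missing(seed)) stop("a seed is mandatory for reproducible simulation")
    new("SimConfig", seed = as.integer(seed),
        nPeaks = stats::setNames(as.integer(nPeaks), names(nPeaks)),
        replicates = as.integer(replicates),
        chromLengths = chromLengths, widthMedians = widthMedians,
        widthLogSd = widthLogSd, effectSize = effectSize,
        baselineLogMean = baselineLogMean, baselineLogSd = baselineLogSd,
        newPeakBaseline = newPeakBaseline, dispersionRange = dispersionRange,
        sizeFactorLogSd = sizeFactorLogSd, nCGI = as.integer(nCGI),
        cgiWidth = cgiWidth, gcBackground = gcBackground, gcIsland = gcIsland,
        cgiNucleationFraction = cgiNucleationFraction,
        cgiControlFraction = cgiControlFraction,
        probUnmethylatedNucleation = probUnmethylatedNucleation,
        probUnmethylatedElsewhere = probUnmethylatedElsewhere,
        nLoops = stats::setNames(as.integer(nLoops), names(nLoops)),
        loopSpanMeans = loopSpanMeans, resolution = resolution,
        focalEnrichment = focalEnrichment, decayScale = decayScale)
}

## Which conditions a peak of each class is occupied (called) in.
.classOccupancy <- list(
    nucleation = c("steady_state", "reintroduction"),
    control_exclusive = "steady_state",
    persistent = c("steady_state", "auxin", "reintroduction"),
    new_in_auxin = "auxin",
    new_in_reintro = "reintroduction")

## Planted log2 fold changes (contrast1 = auxin vs steady state,
## contrast2 = reintroduction vs auxin), in units of the effect size.
## Only nucleation and newly acquired peaks carry count dynamics;
## control-exclusive status is encoded through the per-condition peak calls
## (absent from auxin/reintroduction), keeping a majority of features
## unchanged so that median-of-ratios normalisation stays identifiable.
.classLfc <- list(
    nucleation = c(-1, +1),
    control_exclusive = c(0, 0),
    persistent = c(0, 0),
    new_in_auxin = c(+1, 0),
    new_in_reintro = c(0, +1))

#' Plant the per-peak ground truth
#'
#' Places all configured peaks non-overlapping across the genome (random
#' exponential-like gaps scaled to tile each chromosome exactly), assigns
#' class labels at random positions, and draws each peak's baseline mean,
#' planted fold changes and NB dispersion.
#'
#' @param config a [SimConfig-class].
#' @return A sorted `GRanges` with metadata columns `class`, `lfc1`, `lfc2`,
#'   `baselineMean`, `dispersion`. Never read by the analysis modules.
#' @export
simulateTruth <- function(config) {
    set.seed(config@seed)
    classes <- rep(names(config@nPeaks), config@nPeaks)
    nTotal <- length(classes)
    wMed <- ifelse(classes == "nucleation",
                   config@widthMedians[["nucleation"]],
                   config@widthMedians[["other"]])
    widths <- round(stats::rlnorm(nTotal, meanlog = log(wMed),
                                  sdlog = config@widthLogSd))
    widths <- pmax(widths, 50)
    perm <- sample.int(nTotal)  # scatter classes over the genome
    classes <- classes[perm]
    widths <- widths[perm]
    chroms <- names(config@chromLengths)
    nPerChrom <- as.vector(stats::rmultinom(
        1, nTotal, prob = config@chromLengths / sum(config@chromLengths)))
    idx <- split(seq_len(nTotal),
                 factor(rep(seq_along(chroms), nPerChrom),
                        levels = seq_along(chroms)))
    grl <- lapply(seq_along(chroms), function(ci) {
        ii <- idx[[as.character(ci)]]
        if (is.null(ii) || !length(ii)) return(GRanges())
        len <- config@chromLengths[ci]
        w <- widths[ii]
        if (sum(w) + length(ii) + 1 >= len)
            stop("genome shorter than the total peak span on ", chroms[ci])
        slack <- len - sum(w) - (length(ii) + 1L)
        gapsRaw <- stats::rexp(length(ii) + 1L)
        ## gaps >= 1 bp so adjacent peaks are never book-ended and the union
        ## of the per-condition calls maps 1:1 onto the planted peaks
        gaps <- floor(gapsRaw / sum(gapsRaw) * slack) + 1L
        starts <- cumsum(gaps[-length(gaps)] + c(0, w[-length(w)])) + 1L
        GRanges(chroms[ci], IRanges(start = starts, width = w))
    })
    gr <- unlist(GRangesList(grl))
    ord <- order(match(as.character(GenomicRanges::seqnames(gr)), chroms), start(gr))
    gr <- gr[ord]
    classes <- unlist(lapply(seq_along(chroms),
                             function(ci) classes[idx[[as.character(ci)]]]))[ord]
    lfc <- do.call(rbind, .classLfc[classes]) * config@effectSize
    base <- stats::rlnorm(length(gr), config@baselineLogMean, config@baselineLogSd)
    isNew <- classes %in% c("new_in_auxin", "new_in_reintro")
    base[isNew] <- config@newPeakBaseline *
        exp(stats::rnorm(sum(isNew), 0, 0.2))
    mcols(gr) <- DataFrame(class = classes, lfc1 = lfc[, 1], lfc2 = lfc[, 2],
                           baselineMean = base,
                           dispersion = stats::runif(length(gr),
                                                     config@dispersionRange[1],
                                                     config@dispersionRange[2]))
    names(gr) <- paste0("peak_", seq_along(gr))
    gr
}

#' Per-condition peak calls derived from the planted occupancy
#'
#' @param truth output of [simulateTruth()].
#' @return Named list of `GRanges`, one per condition.
#' @export
simulateCalls <- function(truth) {
    out <- lapply(CONDITIONS, function(cond) {
        keep <- vapply(.classOccupancy[truth$class],
                       function(occ) cond %in% occ, logical(1))
        GenomicRanges::granges(truth[keep])
    })
    names(out) <- CONDITIONS
    out
}

#' Simulate the peak-by-sample count matrix
#'
#' Counts are drawn `k_ij ~ NB(mean = s_j mu_i 2^(planted LFC up to sample
#' j's condition), Var = mu + alpha mu^2)`: steady-state samples see the
#' baseline mean, auxin samples `mu 2^lfc1`, reintroduction samples
#' `mu 2^(lfc1 + lfc2)`.
#'
#' @param truth output of [simulateTruth()].
#' @param config the [SimConfig-class].
#' @return A [PeakExperiment-class]; the true size factors are stored in
#'   `metadata()$trueSizeFactors`.
#' @export
simulateCounts <- function(truth, config) {
    set.seed(config@seed + 1L)
    nRep <- config@replicates
    condition <- rep(CONDITIONS, each = nRep)
    nSamp <- length(condition)
    s <- exp(stats::rnorm(nSamp, 0, config@sizeFactorLogSd))
    condMean <- cbind(steady_state = truth$baselineMean,
                      auxin = truth$baselineMean * 2^truth$lfc1,
                      reintroduction = truth$baselineMean * 2^(truth$lfc1 + truth$lfc2))
    counts <- vapply(seq_len(nSamp), function(j) {
        mu <- s[j] * condMean[, condition[j]]
        as.numeric(stats::rnbinom(length(mu), mu = mu, size = 1 / truth$dispersion))
    }, numeric(length(truth)))
    colnames(counts) <- paste0(condition, "_rep", rep(seq_len(nRep), times = 3))
    rownames(counts) <- names(truth)
    pe <- peakExperiment(counts, rowRanges = GenomicRanges::granges(truth),
                         condition = condition,
                         replicate = rep(seq_len(nRep), times = 3))
    metadata(pe)$trueSizeFactors <- stats::setNames(s, colnames(counts))
    pe
}

.randomSeq <- function(n, gc) {
    p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
    c("A", "C", "G", "T")[sample.int(4L, n, replace = TRUE, prob = p)]
}

## CpG-rich island sequence: emit "CG" dinucleotides at rate cgRate,
## otherwise single bases at the island GC level. Guarantees GC >= 0.65 and
## CpG density >= 0.06 by construction.
.islandSeq <- function(n, gc, cgRate = 0.13) {
    emit <- stats::runif(n) < cgRate   # n emissions always produce >= n bases
    parts <- .randomSeq(n, gc)
    parts[emit] <- "CG"
    strsplit(paste(parts, collapse = ""), "", fixed = TRUE)[[1L]][seq_len(n)]
}

#' Simulate the genome sequence and its CpG islands
#'
#' Background sequence at GC `gcBackground`; islands (width `cgiWidth`) are
#' planted at a configured fraction of nucleation and control-exclusive
#' peaks (centred on the peak midpoint) and the rest at random intergenic
#' positions, with GC >= 0.65 and CpG dinucleotide density >= 0.06 by
#' construction.
#'
#' @param config a [SimConfig-class].
#' @param truth output of [simulateTruth()].
#' @return A list with `genome` (`DNAStringSet`) and `cgi` (`GRanges` with a
#'   planted `atClass` column).
#' @export
simulateGenome <- function(config, truth) {
    set.seed(config@seed + 2L)
    if (any(config@chromLengths < config@cgiWidth))
        stop("genome shorter than the features it must host")
    nNuc <- round(config@nCGI * config@cgiNucleationFraction)
    nCtl <- round(config@nCGI * config@cgiControlFraction)
    nBg <- config@nCGI - nNuc - nCtl
    w <- config@cgiWidth
    half <- floor(w / 2)
    nucPk <- truth[truth$class == "nucleation"]
    ctlPk <- truth[truth$class == "control_exclusive"]
    nucSel <- nucPk[sample.int(length(nucPk), min(nNuc, length(nucPk)))]
    ctlSel <- ctlPk[sample.int(length(ctlPk), min(nCtl, length(ctlPk)))]
    mkCgi <- function(sel, what) {
        mid <- floor((start(sel) + end(sel)) / 2)
        GRanges(GenomicRanges::seqnames(sel),
                IRanges(start = pmax(1L, mid - half), width = w),
                atClass = what)
    }
    cgi <- c(mkCgi(nucSel, "nucleation"), mkCgi(ctlSel, "control_exclusive"))
    ## remaining islands at random positions clear of all peaks
    chroms <- names(config@chromLengths)
    bg <- GRanges()
    tries <- 0L
    while (length(bg) < nBg && tries < 50L) {
        ci <- sample.int(length(chroms), nBg - length(bg), replace = TRUE)
        st <- floor(stats::runif(length(ci), 1, config@chromLengths[ci] - w))
        cand <- GRanges(chroms[ci], IRanges(start = st, width = w), atClass = "intergenic")
        cand <- cand[!overlapsAny(cand, truth, ignore.strand = TRUE)]
        bg <- c(bg, cand)
        tries <- tries + 1L
    }
    cgi <- sort(c(cgi, bg), ignore.strand = TRUE)
    names(cgi) <- paste0("cgi_", seq_along(cgi))
    genome <- Biostrings::DNAStringSet(vapply(chroms, function(cc) {
        len <- config@chromLengths[[cc]]
        seqchar <- .randomSeq(len, config@gcBackground)
        isl <- cgi[as.character(GenomicRanges::seqnames(cgi)) == cc]
        for (k in seq_along(isl)) {
            s <- start(isl)[k]; e <- min(end(isl)[k], len)
            seqchar[s:e] <- .islandSeq(e - s + 1L, config@gcIsland)
        }
        paste(seqchar, collapse = "")
    }, character(1)))
    names(genome) <- chroms
    list(genome = genome, cgi = cgi)
}

#' Simulate the single-CpG methylation landscape
#'
#' CpG positions are extracted from the genome within each island. Islands
#' overlapping nucleation peaks are planted unmethylated with probability
#' `probUnmethylatedNucleation`, others with `probUnmethylatedElsewhere`.
#' Methylated islands get >= 20% of their CpGs at level > 0.5, unmethylated
#' ones < 20%, so the downstream island caller recovers the planted status
#' exactly.
#'
#' @param cgi island `GRanges` (from [simulateGenome()]).
#' @param genome `DNAStringSet`.
#' @param truth output of [simulateTruth()].
#' @param config the [SimConfig-class].
#' @return A list with `records` (width-1 methylation `GRanges` with
#'   `level`) and `islandTruth` (`cgi` with a `plantedStatus` column).
#' @export
simulateMethylation <- function(cgi, genome, truth, config) {
    set.seed(config@seed + 3L)
    atNuc <- overlapsAny(cgi, truth[truth$class == "nucleation"],
                         ignore.strand = TRUE)
    pUn <- ifelse(atNuc, config@probUnmethylatedNucleation,
                  config@probUnmethylatedElsewhere)
    planted <- ifelse(stats::runif(length(cgi)) < pUn, "unmethylated", "methylated")
    recs <- GRanges()
    allRecs <- vector("list", length(cgi))
    for (k in seq_along(cgi)) {
        chr <- as.character(GenomicRanges::seqnames(cgi))[k]
        sub <- Biostrings::subseq(genome[[chr]], start(cgi)[k], end(cgi)[k])
        hits <- Biostrings::matchPattern("CG", sub)
        if (!length(hits)) {
            warning("island ", names(cgi)[k], " has zero CpGs; skipped")
            planted[k] <- NA_character_
            next
        }
        pos <- start(cgi)[k] + start(hits) - 1L  # cytosine position, 1-based
        n <- length(pos)
        fH <- if (planted[k] == "methylated") stats::runif(1, 0.5, 0.9)
              else stats::runif(1, 0, 0.15)
        nHigh <- if (planted[k] == "methylated") ceiling(fH * n) else floor(fH * n)
        high <- seq_len(n) %in% sample.int(n, nHigh)
        level <- ifelse(high, stats::runif(n, 0.6, 1), stats::runif(n, 0, 0.4))
        allRecs[[k]] <- GRanges(chr, IRanges(start = pos, width = 1L), level = level)
    }
    recs <- sort(unlist(GRangesList(allRecs[!vapply(allRecs, is.null, TRUE)])),
                 ignore.strand = TRUE)
    cgi$plantedStatus <- planted
    list(records = recs, islandTruth = cgi)
}

#' Simulate loops and the focal-enriched contact matrix
#'
#' Loops are planted with 0, 1 or 2 nucleation-site anchors at the
#' configured counts and log-normal spans; loops narrower than 3 matrix bins
#' are rejected and resampled. A dense contact matrix is built for the first
#' chromosome: distance-decay background `c / (1 + |i - j|)` with loop
#' pixels multiplied by the focal enrichment factor.
#'
#' @param truth output of [simulateTruth()].
#' @param config the [SimConfig-class].
#' @return A list with `loops` (a [LoopSet-class] with a `plantedClass`
#'   column) and `matrix` (a [ContactMatrix-class] for the first
#'   chromosome).
#' @export
simulateLoops <- function(truth, config) {
    set.seed(config@seed + 4L)
    res <- config@resolution
    minSpan <- 3 * res
    chroms <- names(config@chromLengths)
    nuc <- truth[truth$class == "nucleation"]
    nucChrom <- as.character(GenomicRanges::seqnames(nuc))
    nucMid <- floor((start(nuc) + end(nuc)) / 2)
    nucByChrom <- as.numeric(table(factor(nucChrom, chroms)))
    anchorW <- res
    drawSpan <- function(mean, n)
        stats::rlnorm(n, meanlog = log(mean) - 0.125, sdlog = 0.5)
    mkAnchor <- function(chr, mid)
        GRanges(chr, IRanges(start = pmax(1, floor(mid - anchorW / 2)),
                             width = anchorW))
    clearOfNucleation <- function(chr, mid)
        !overlapsAny(mkAnchor(chr, mid), nuc, ignore.strand = TRUE)

    chrV <- character(0); m1V <- numeric(0); m2V <- numeric(0); cls <- character(0)
    for (what in c("zero", "one", "two")) {
        nL <- config@nLoops[[what]]
        if (nL == 0L) next
        spanMean <- config@loopSpanMeans[[what]]
        prob <- if (what == "zero") as.numeric(config@chromLengths) else nucByChrom
        done <- 0L
        while (done < nL) {
            nb <- (nL - done) * 2L  # oversample; excess trimmed below
            chr <- sample(chroms, nb, replace = TRUE, prob = prob)
            span <- drawSpan(spanMean, nb)
            maxLen <- config@chromLengths[chr]
            ok <- span >= minSpan & span <= maxLen / 2
            if (what == "two") {
                m1 <- m2 <- rep(NA_real_, nb)
                for (k in which(ok)) {
                    mids <- nucMid[nucChrom == chr[k]]
                    if (length(mids) < 2L) next
                    i <- sample.int(length(mids), 1L)
                    target <- mids[i] + sample(c(-1, 1), 1L) * span[k]
                    j <- which.min(abs(mids - target))
                    realized <- abs(mids[j] - mids[i])
                    ## keep the realized span close to the drawn one so the
                    ## configured span distribution is honoured
                    if (j == i || realized < minSpan ||
                        abs(realized - span[k]) > 0.25 * span[k]) next
                    m1[k] <- mids[i]; m2[k] <- mids[j]
                }
                ok <- ok & !is.na(m1)
            } else if (what == "one") {
                m1 <- vapply(seq_len(nb), function(k) {
                    mids <- nucMid[nucChrom == chr[k]]
                    if (!length(mids)) return(NA_real_)
                    mids[sample.int(length(mids), 1L)]
                }, numeric(1))
                m2 <- m1 + sample(c(-1, 1), nb, replace = TRUE) * span
                ok <- ok & !is.na(m1) & m2 > anchorW & m2 < maxLen - anchorW
                ok[ok] <- clearOfNucleation(chr[ok], m2[ok])
            } else {
                m1 <- floor(stats::runif(nb, anchorW, maxLen - anchorW))
                m2 <- m1 + sample(c(-1, 1), nb, replace = TRUE) * span
                ok <- ok & m2 > anchorW & m2 < maxLen - anchorW
                ok[ok] <- clearOfNucleation(chr[ok], m1[ok]) &
                    clearOfNucleation(chr[ok], m2[ok])
            }
            take <- which(ok)[seq_len(min(sum(ok), nL - done))]
            chrV <- c(chrV, chr[take])
            m1V <- c(m1V, m1[take]); m2V <- c(m2V, m2[take])
            cls <- c(cls, rep(what, length(take)))
            done <- done + length(take)
        }
    }
    loops <- loopSet(mkAnchor(chrV, m1V), mkAnchor(chrV, m2V))
    loops@loopData$plantedClass <- cls

    ## dense matrix for the first chromosome
    mchr <- chroms[1L]
    nb <- floor(config@chromLengths[[mchr]] / res)
    ij <- abs(outer(seq_len(nb), seq_len(nb), "-"))
    vals <- config@decayScale / (1 + ij)
    onChr <- as.character(GenomicRanges::seqnames(loops@anchor1)) == mchr &
        !loops@loopData$interchromosomal
    mids1 <- floor((start(loops@anchor1) + end(loops@anchor1)) / 2)
    mids2 <- floor((start(loops@anchor2) + end(loops@anchor2)) / 2)
    b1 <- floor((mids1[onChr] - 1) / res) + 1L
    b2 <- floor((mids2[onChr] - 1) / res) + 1L
    keep <- b1 >= 1L & b1 <= nb & b2 >= 1L & b2 <= nb
    ## enrich each distinct pixel once, however many loops share it
    pix <- unique(cbind(b1[keep], b2[keep]))
    for (k in seq_len(nrow(pix))) {
        vals[pix[k, 1L], pix[k, 2L]] <- vals[pix[k, 1L], pix[k, 2L]] *
            config@focalEnrichment
        vals[pix[k, 2L], pix[k, 1L]] <- vals[pix[k, 1L], pix[k, 2L]]
    }
    cm <- contactMatrix(mchr, (seq_len(nb) - 1L) * res, vals, res)
    list(loops = loops, matrix = cm)
}

#' Generate and write the full synthetic bundle
#'
#' Runs every generator with sub-seeds derived from the configured seed and
#' writes the complete fixture set: genome FASTA, CGI BED, per-condition
#' peak-call BEDs, counts + sample sheet TSVs, methylation TSV, loops BEDPE,
#' dense contact matrix + bins BED, and the planted truth tables (never read
#' by the analysis modules). Byte-identical across runs for a given config.
#'
#' @param config a [SimConfig-class].
#' @param dir output directory (created if needed), or `NULL` to skip
#'   writing and return in-memory objects only.
#' @return (Invisibly) a list with `truth`, `calls`, `counts`, `genome`,
#'   `cgi`, `methylation`, `islandTruth`, `loops`, `matrix`, and `files`.
#' @export
simulateBundle <- function(config, dir = NULL) {
    truth <- simulateTruth(config)
    calls <- simulateCalls(truth)
    counts <- simulateCounts(truth, config)
    gen <- simulateGenome(config, truth)
    meth <- simulateMethylation(gen$cgi, gen$genome, truth, config)
    lp <- simulateLoops(truth, config)
    files <- character(0)
    if (!is.null(dir)) {
        dir.create(dir, recursive = TRUE, showWarnings = FALSE)
        fp <- function(x) file.path(dir, x)
        Biostrings::writeXStringSet(gen$genome, fp("genome.fa"))
        writePeakBed(gen$cgi, fp("cgi.bed"))
        for (cond in CONDITIONS) {
            gr <- calls[[cond]]
            names(gr) <- paste0(cond, "_", seq_along(gr))
            writePeakBed(gr, fp(paste0("calls_", cond, ".bed")))
        }
        writeCountsTable(counts, fp("counts.tsv"), fp("samples.tsv"))
        writeMethylationTable(meth$records, fp("methylation.tsv"))
        writeBedpe(lp$loops, fp("loops.bedpe"))
        writeContactMatrix(lp$matrix, fp("matrix_chr1.tsv"), fp("bins_chr1.bed"))
        truthDf <- data.frame(peak = names(truth),
                              chrom = as.character(GenomicRanges::seqnames(truth)),
                              start = start(truth) - 1L, end = end(truth),
                              class = truth$class, lfc1 = truth$lfc1,
                              lfc2 = truth$lfc2,
                              baselineMean = truth$baselineMean,
                              dispersion = truth$dispersion)
        utils::write.table(truthDf, fp("truth_peaks.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        islandDf <- data.frame(island = names(meth$islandTruth),
                               plantedStatus = meth$islandTruth$plantedStatus,
                               atClass = meth$islandTruth$atClass)
        utils::write.table(islandDf, fp("truth_islands.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        loopDf <- cbind(as.data.frame(loopData(lp$loops)))
        utils::write.table(loopDf, fp("truth_loops.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        files <- list.files(dir, full.names = TRUE)
    }
    invisible(list(truth = truth, calls = calls, counts = counts,
                   genome = gen$genome, cgi = gen$cgi,
                   methylation = meth$records, islandTruth = meth$islandTruth,
                   loops = lp$loops, matrix = lp$matrix, files = files))
}
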