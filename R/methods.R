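#' @include AllClasses.R AllGenerics.R
NULL

## ---- accessors -------------------------------------------------------------

#' Per-sample size factors of a PeakExperiment
#' @param object a [PeakExperiment-class].
#' @return Named numeric vector, or `NULL` before [estimateSizeFactors()].
#' @export
setMethod("sizeFactors", "PeakExperiment", function(object) {
    cd <- SummarizedExperiment::colData(object)
    if (!"sizeFactor" %in% colnames(cd)) return(NULL)
    stats::setNames(cd$sizeFactor, rownames(cd))
})

#' @rdname resultsTable
#' @export
setMethod("resultsTable", "ContrastResult", function(object) object@results)

#' @rdname oeRatio
#' @export
setMethod("oeRatio", "ResamplingResult", function(object) object@oeRatio)

#' @rdname pEmpirical
#' @export
setMethod("pEmpirical", "ResamplingResult", function(object) object@pEmpirical)

#' @rdname nullDraws
#' @export
setMethod("nullDraws", "ResamplingResult", function(object) object@nullDraws)

#' @rdname anchorOne
#' @export
setMethod("anchorOne", "LoopSet", function(object) object@anchor1)

#' @rdname anchorOne
#' @export
setMethod("anchorTwo", "LoopSet", function(object) object@anchor2)

#' @rdname loopSpan
#' @export
setMethod("loopSpan", "LoopSet", function(object) object@loopData$span)

#' @rdname loopData
#' @export
setMethod("loopData", "LoopSet", function(object) object@loopData)

#' @export
setMethod("length", "LoopSet", function(x) length(x@anchor1))

#' Subset a LoopSet
#' @param x a [LoopSet-class]; @param i index; @param j,...,drop ignored.
#' @export
setMethod("[", "LoopSet", function(x, i, j, ..., drop = FALSE) {
    new("LoopSet", anchor1 = x@anchor1[i], anchor2 = x@anchor2[i],
        loopData = x@loopData[i, , drop = FALSE])
})

#' @rdname contactValues
#' @export
setMethod("contactValues", "ContactMatrix", function(object) object@values)

#' @rdname contactValues
#' @export
setMethod("binStarts", "ContactMatrix", function(object) object@bins)

#' @rdname contactValues
#' @export
setMethod("binResolution", "ContactMatrix", function(object) object@resolution)

#' @rdname apaScore
#' @export
setMethod("apaScore", "APAResult", function(object) object@score)

## ---- show methods ----------------------------------------------------------

setMethod("show", "ContrastResult", function(object) {
    r <- object@results
    cat(sprintf("ContrastResult: %s vs %s (B over A)\n",
                object@conditionB, object@conditionA))
    cat(sprintf("  %d features; %d with padj < 0.05\n",
                nrow(r), sum(r$padj < 0.05, na.rm = TRUE)))
})

setMethod("show", "ResamplingResult", function(object) {
    cat(sprintf(paste0("ResamplingResult (%s): observed = %.4g, expected = %.4g, ",
                       "O/E = %.3f, p = %.4g (N = %d draws, seed = %d)\n"),
                object@alternative, object@observed, object@expected,
                object@oeRatio, object@pEmpirical, object@N, object@seed))
})

setMethod("show", "LoopSet", function(object) {
    n <- length(object)
    inter <- sum(object@loopData$interchromosomal)
    cat(sprintf("LoopSet: %d loops (%d interchromosomal)\n", n, inter))
    nn <- object@loopData$nNucleationAnchors
    if (!is.null(nn) && !all(is.na(nn)))
        cat(sprintf("  nucleation anchors 0/1/2: %d/%d/%d\n",
                    sum(nn == 0L, na.rm = TRUE), sum(nn == 1L, na.rm = TRUE),
                    sum(nn == 2L, na.rm = TRUE)))
})

setMethod("show", "ContactMatrix", function(object) {
    cat(sprintf("ContactMatrix: %s, %d bins at %g bp resolution\n",
                object@chrom, length(object@bins), object@resolution))
})

setMethod("show", "APAResult", function(object) {
    cat(sprintf("APAResult: score = %.3f over %d loops (%d excluded), w = %d\n",
                object@score, object@nLoops, object@nExcluded, object@w))
})

setMethod("show", "SimConfig", function(object) {
    cat("SimConfig (synthetic degron ChIP-seq bundle)\n")
    cat(sprintf("  seed %d; %d peaks (%s)\n", object@seed, sum(object@nPeaks),
                paste(sprintf("%s=%d", names(object@nPeaks), object@nPeaks),
                      collapse = ", ")))
    cat(sprintf("  %d chromosomes, %.1f Mb total; %d replicates/condition\n",
                length(object@chromLengths), sum(object@chromLengths) / 1e6,
                object@replicates))
    cat(sprintf("  %d CGIs; %d loops; %g bp matrix resolution\n",
                object@nCGI, sum(object@nLoops), object@resolution))
})
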