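#' @include AllClasses.R
NULL

## estimateSizeFactors and sizeFactors are BiocGenerics generics; methods for
## PeakExperiment are registered on those so they keep working whatever else
## is on the search path.

#' @importFrom BiocGenerics estimateSizeFactors
#' @export
BiocGenerics::estimateSizeFactors

#' @importFrom BiocGenerics sizeFactors
#' @export
BiocGenerics::sizeFactors

#' @importFrom BiocGenerics estimateDispersions
#' @export
BiocGenerics::estimateDispersions

#' Results table of a contrast or resampling analysis
#' @param object a [ContrastResult-class].
#' @export
setGeneric("resultsTable", function(object) standardGeneric("resultsTable"))

#' Observed / expected ratio of a resampling analysis
#' @param object a [ResamplingResult-class].
#' @export
setGeneric("oeRatio", function(object) standardGeneric("oeRatio"))

#' Add-one empirical p-value of a resampling analysis
#' @param object a [ResamplingResult-class].
#' @export
setGeneric("pEmpirical", function(object) standardGeneric("pEmpirical"))

#' Null draws of a resampling analysis
#' @param object a [ResamplingResult-class].
#' @export
setGeneric("nullDraws", function(object) standardGeneric("nullDraws"))

#' First / second loop anchors
#' @param object a [LoopSet-class].
#' @export
setGeneric("anchorOne", function(object) standardGeneric("anchorOne"))

#' @rdname anchorOne
#' @export
setGeneric("anchorTwo", function(object) standardGeneric("anchorTwo"))

#' Loop spans (midpoint distance, bp; NA for interchromosomal pairs)
#' @param object a [LoopSet-class].
#' @export
setGeneric("loopSpan", function(object) standardGeneric("loopSpan"))

#' Per-loop metadata DataFrame
#' @param object a [LoopSet-class].
#' @export
setGeneric("loopData", function(object) standardGeneric("loopData"))

#' Contact values / bin starts / resolution of a ContactMatrix
#' @param object a [ContactMatrix-class].
#' @export
setGeneric("contactValues", function(object) standardGeneric("contactValues"))

#' @rdname contactValues
#' @export
setGeneric("binStarts", function(object) standardGeneric("binStarts"))

#' @rdname contactValues
#' @export
setGeneric("binResolution", function(object) standardGeneric("binResolution"))

#' APA score (centre over lower-left corner background)
#' @param object an [APAResult-class].
#' @export
setGeneric("apaScore", function(object) standardGeneric("apaScore"))
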