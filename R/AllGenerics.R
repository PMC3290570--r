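#' @include AllClasses.R
NULL

#' @export
setGeneric("nClones", function(x) standardGeneric("nClones"))

#' @export
setGeneric("cloneIDs", function(x) standardGeneric("cloneIDs"))

#' @export
setGeneric("specimenIDs", function(x) standardGeneric("specimenIDs"))

#' @export
setGeneric("cloneSeqs", function(x) standardGeneric("cloneSeqs"))

#' @export
setGeneric("isAligned", function(x) standardGeneric("isAligned"))

#' @export
setGeneric("lociLabels", function(x) standardGeneric("lociLabels"))

#' @export
setGeneric("lociRanges", function(x) standardGeneric("lociRanges"))

#' @export
setGeneric("leftFlanks", function(x) standardGeneric("leftFlanks"))

#' @export
setGeneric("rightFlanks", function(x) standardGeneric("rightFlanks"))

#' @export
setGeneric("allowedLengths", function(x) standardGeneric("allowedLengths"))

#' @export
setGeneric("nAlleles", function(x) standardGeneric("nAlleles"))

#' @export
setGeneric("alleleTable", function(x) standardGeneric("alleleTable"))

#' @export
setGeneric("locusLabel", function(x) standardGeneric("locusLabel"))

#' @export
setGeneric("spaceSize", function(x) standardGeneric("spaceSize"))

#' @export
setGeneric("abundances", function(x) standardGeneric("abundances"))

#' @export
setGeneric("incompleteClones", function(x) standardGeneric("incompleteClones"))
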