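#' @include AllClasses.R
NULL

#' Extract the abundance matrix
#'
#' Returns the samples x taxa numeric matrix stored in an
#' \linkS4class{AbundanceTable}.
#'
#' @param x an object.
#' @param ... further arguments for methods.
#' @return A numeric matrix with samples as rows and taxa as columns.
#' @export
setGeneric("abundances", function(x, ...) standardGeneric("abundances"))

#' Sample identifiers of a container
#' @param x an object.
#' @return Character vector of sample ids.
#' @export
setGeneric("sampleIDs", function(x) standardGeneric("sampleIDs"))

#' Taxon identifiers of a container
#' @param x an object.
#' @return Character vector of taxon ids.
#' @export
setGeneric("taxonIDs", function(x) standardGeneric("taxonIDs"))

#' Abundance mode ("counts" or "relative")
#' @param x an object.
#' @return A length-one character string.
#' @export
setGeneric("abundanceMode", function(x) standardGeneric("abundanceMode"))

#' Number of samples
#' @param x an object.
#' @return Integer scalar.
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' Number of taxa
#' @param x an object.
#' @return Integer scalar.
#' @export
setGeneric("nTaxa", function(x) standardGeneric("nTaxa"))

#' Per-taxon classification labels
#' @param x an object carrying per-taxon labels.
#' @return Named character vector of labels.
#' @export
setGeneric("taxonLabels", function(x) standardGeneric("taxonLabels"))
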