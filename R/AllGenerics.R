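#' @import methods
NULL

#' Insertion-dosage matrix
#'
#' Accessor for the loci x samples matrix of insertion-allele counts
#' (0, 1, 2 or \code{NA} for a failed call).
#'
#' @param x a \linkS4class{DipGenotypes} object.
#' @return An integer matrix, loci in rows, samples in columns.
#' @export
setGeneric("dosage", function(x) standardGeneric("dosage"))

#' @rdname DipGenotypes-class
#' @export
setGeneric("populationLabels", function(x) standardGeneric("populationLabels"))

#' @rdname DipGenotypes-class
#' @export
setGeneric("continentLabels", function(x) standardGeneric("continentLabels"))

#' @rdname DipGenotypes-class
#' @export
setGeneric("markerClass", function(x) standardGeneric("markerClass"))

#' @rdname DipGenotypes-class
#' @export
setGeneric("autosomal", function(x) standardGeneric("autosomal"))

#' Insertion-allele frequencies
#'
#' Accessor for the loci x populations matrix of insertion-allele
#' frequencies of a \linkS4class{DipFrequencies} object. Deletion
#' frequencies are never stored; they are \code{1 - pIns(x)} by definition.
#'
#' @param x a \linkS4class{DipFrequencies} object.
#' @return A numeric matrix in [0, 1].
#' @export
setGeneric("pIns", function(x) standardGeneric("pIns"))

#' @rdname DipFrequencies-class
#' @export
setGeneric("sampleSizes", function(x) standardGeneric("sampleSizes"))

#' @rdname DipDistance-class
#' @export
setGeneric("metricName", function(x) standardGeneric("metricName"))

#' @rdname DipDistance-class
#' @export
setGeneric("isClamped", function(x) standardGeneric("isClamped"))
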