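#' @importFrom S4Vectors DataFrame SimpleList metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData colData
NULL

.VALID_MARKER_CLASSES <- c("autosomal_dip", "y_dip", "amelogenin")

#' Container for DIP panel genotypes
#'
#' \code{DipGenotypes} extends \linkS4class{SummarizedExperiment}: the
#' single assay \code{"dosage"} holds insertion-allele counts (0, 1, 2;
#' \code{NA} = no call) with loci in rows and samples in columns.
#' \code{rowData} carries the marker class of each locus
#' (\code{"autosomal_dip"}, \code{"y_dip"} or \code{"amelogenin"}); only
#' autosomal loci enter any statistic, the rest are metadata passthrough.
#' \code{colData} carries per-sample \code{population}, \code{continent}
#' and optional \code{sex} labels.
#'
#' @section Validity:
#' Non-missing autosomal dosages must lie in \{0, 1, 2\}; locus and sample
#' identifiers must be unique; each population must map to exactly one
#' continent.
#'
#' @param dosage integer/numeric matrix, loci x samples, values in
#'   \{0, 1, 2, NA\}. Row and column names are used as locus and sample ids.
#' @param population character vector of population labels, one per sample.
#' @param continent character vector of continent labels, one per sample.
#' @param sex optional character vector, one per sample.
#' @param markerClass character vector, one per locus; defaults to
#'   \code{"autosomal_dip"} for every locus.
#'
#' @return A \code{DipGenotypes} object.
#' @examples
#' m <- matrix(c(0L, 1L, 2L, 1L), nrow = 2,
#'             dimnames = list(c("rs1", "rs2"), c("s1", "s2")))
#' g <- DipGenotypes(m, population = c("P1", "P1"), continent = c("EA", "EA"))
#' dosage(g)
#' @aliases DipGenotypes
#' @export DipGenotypes
#' @exportClass DipGenotypes
setClass("DipGenotypes", contains = "SummarizedExperiment")

setValidity("DipGenotypes", function(object) {
    msg <- NULL
    if (!"dosage" %in% names(assays(object)))
        msg <- c(msg, "assay 'dosage' is required")
    else {
        d <- assay(object, "dosage")
        mc <- rowData(object)$marker_class
        auto <- if (is.null(mc)) rep(TRUE, nrow(d)) else mc == "autosomal_dip"
        v <- d[auto, , drop = FALSE]
        if (any(!is.na(v) & !(v %in% c(0, 1, 2))))
            msg <- c(msg, "non-missing autosomal dosages must be 0, 1 or 2")
    }
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "locus ids must be unique")
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, "sample ids must be unique")
    cd <- colData(object)
    if (!all(c("population", "continent") %in% names(cd)))
        msg <- c(msg, "colData must contain 'population' and 'continent'")
    else {
        map <- unique(data.frame(p = cd$population, k = cd$continent))
        if (anyDuplicated(map$p))
            msg <- c(msg, "each population must map to a single continent")
    }
    mc <- rowData(object)$marker_class
    if (!is.null(mc) && !all(mc %in% .VALID_MARKER_CLASSES))
        msg <- c(msg, paste("marker_class must be one of:",
                            paste(.VALID_MARKER_CLASSES, collapse = ", ")))
    if (is.null(msg)) TRUE else msg
})

DipGenotypes <- function(dosage, population, continent, sex = NULL,
                         markerClass = NULL) {
    dosage <- as.matrix(dosage)
    if (is.null(rownames(dosage)) && nrow(dosage))
        rownames(dosage) <- paste0("locus", seq_len(nrow(dosage)))
    if (is.null(colnames(dosage)) && ncol(dosage))
        colnames(dosage) <- paste0("sample", seq_len(ncol(dosage)))
    storage.mode(dosage) <- "integer"
    if (is.null(markerClass))
        markerClass <- rep("autosomal_dip", nrow(dosage))
    cd <- DataFrame(population = as.character(population),
                    continent = as.character(continent),
                    row.names = colnames(dosage))
    if (!is.null(sex)) cd$sex <- as.character(sex)
    se <- SummarizedExperiment(
        assays = SimpleList(dosage = dosage),
        rowData = DataFrame(marker_class = markerClass,
                            row.names = rownames(dosage)),
        colData = cd)
    new("DipGenotypes", se)
}

#' @rdname dosage
#' @export
setMethod("dosage", "DipGenotypes", function(x) assay(x, "dosage"))

#' @rdname DipGenotypes-class
#' @param x a \code{DipGenotypes} object.
#' @export
setMethod("populationLabels", "DipGenotypes",
          function(x) colData(x)$population)

#' @rdname DipGenotypes-class
#' @export
setMethod("continentLabels", "DipGenotypes",
          function(x) colData(x)$continent)

#' @rdname DipGenotypes-class
#' @export
setMethod("markerClass", "DipGenotypes",
          function(x) rowData(x)$marker_class)

#' @rdname DipGenotypes-class
#' @export
setMethod("autosomal", "DipGenotypes",
          function(x) x[rowData(x)$marker_class == "autosomal_dip", ])

setMethod("show", "DipGenotypes", function(object) {
    cat("DipGenotypes:", nrow(object), "loci x", ncol(object), "samples\n")
    cat("  marker classes:",
        paste(sprintf("%s (%d)", names(table(markerClass(object))),
                      table(markerClass(object))), collapse = ", "), "\n")
    cat("  populations:", length(unique(populationLabels(object))),
        " continents:", length(unique(continentLabels(object))), "\n")
})

#' Locus x population insertion-allele frequency table
#'
#' Holds insertion-allele frequencies for a panel of biallelic DIP loci
#' across one or more populations, together with the diploid sample size
#' behind each population's estimates. Deletion frequencies are defined as
#' \code{1 - pIns} and never stored independently.
#'
#' @param pIns numeric matrix in [0, 1], loci x populations; dimnames are
#'   used as locus and population identifiers.
#' @param n positive integer vector of diploid sample sizes, one per
#'   population (recycled if length 1).
#'
#' @return A \code{DipFrequencies} object.
#' @examples
#' f <- DipFrequencies(matrix(c(0.4, 0.6), 2, 1,
#'                     dimnames = list(c("rs1", "rs2"), "P1")), n = 100)
#' pIns(f)
#' @aliases DipFrequencies
#' @export DipFrequencies
#' @exportClass DipFrequencies
setClass("DipFrequencies",
         representation(pIns = "matrix", n = "integer"))

setValidity("DipFrequencies", function(object) {
    msg <- NULL
    p <- object@pIns
    if (any(!is.na(p) & (p < 0 | p > 1)))
        msg <- c(msg, "frequencies must lie in [0, 1]")
    if (length(object@n) != ncol(p))
        msg <- c(msg, "need one sample size per population")
    if (any(object@n < 1)) msg <- c(msg, "sample sizes must be positive")
    if (is.null(rownames(p)) || is.null(colnames(p)))
        msg <- c(msg, "pIns must have locus rownames and population colnames")
    if (is.null(msg)) TRUE else msg
})

DipFrequencies <- function(pIns, n) {
    pIns <- as.matrix(pIns)
    n <- rep_len(as.integer(n), ncol(pIns))
    names(n) <- colnames(pIns)
    new("DipFrequencies", pIns = pIns, n = n)
}

#' @rdname pIns
#' @export
setMethod("pIns", "DipFrequencies", function(x) x@pIns)

#' @rdname DipFrequencies-class
#' @param x a \code{DipFrequencies} object.
#' @export
setMethod("sampleSizes", "DipFrequencies", function(x) x@n)

setMethod("show", "DipFrequencies", function(object) {
    cat("DipFrequencies:", nrow(object@pIns), "loci x",
        ncol(object@pIns), "populations\n")
    cat("  diploid n:", paste(utils::head(object@n, 5), collapse = ", "),
        if (length(object@n) > 5) "..." else "", "\n")
})

#' Labelled population distance matrix
#'
#' A symmetric, zero-diagonal matrix of pairwise population distances
#' (Weir-Cockerham \eqn{F_{ST}}, Nei's \eqn{D_A}, or any other metric),
#' with a flag recording whether negative estimates were floored at zero
#' for geometry-consuming consumers (MDS, NJ).
#'
#' @param values symmetric numeric matrix with zero diagonal and dimnames.
#' @param metric short metric name, e.g. \code{"fst"} or \code{"da"}.
#' @param clamped logical; \code{TRUE} if negative estimates were floored.
#'
#' @return A \code{DipDistance} object.
#' @aliases DipDistance
#' @export DipDistance
#' @exportClass DipDistance
setClass("DipDistance",
         representation(values = "matrix", metric = "character",
                        clamped = "logical"))

setValidity("DipDistance", function(object) {
    v <- object@values
    msg <- NULL
    if (nrow(v) != ncol(v)) msg <- c(msg, "matrix must be square")
    else {
        if (max(abs(v - t(v))) > 1e-12) msg <- c(msg, "matrix must be symmetric")
        if (any(abs(diag(v)) != 0)) msg <- c(msg, "diagonal must be exactly 0")
    }
    if (is.null(rownames(v))) msg <- c(msg, "labels required")
    if (is.null(msg)) TRUE else msg
})

DipDistance <- function(values, metric = "other", clamped = FALSE) {
    values <- as.matrix(values)
    new("DipDistance", values = values, metric = metric, clamped = clamped)
}

#' @rdname DipDistance-class
#' @param x a \code{DipDistance} object.
#' @export
setMethod("metricName", "DipDistance", function(x) x@metric)

#' @rdname DipDistance-class
#' @export
setMethod("isClamped", "DipDistance", function(x) x@clamped)

#' @export
#' @method as.matrix DipDistance
as.matrix.DipDistance <- function(x, ...) x@values

setMethod("as.matrix", "DipDistance", function(x, ...) x@values)

#' @export
#' @method as.dist DipDistance
as.dist.DipDistance <- function(m, diag = FALSE, upper = FALSE)
    stats::as.dist(m@values, diag = diag, upper = upper)

setMethod("show", "DipDistance", function(object) {
    cat("DipDistance (", object@metric, "): ", nrow(object@values),
        " populations", if (object@clamped) ", negatives clamped to 0", "\n",
        sep = "")
})

#' Result of a full-sibling likelihood-ratio power study
#'
#' Holds the simulated log10 likelihood-ratio samples for full-sibling and
#' unrelated pairs, and the per-threshold identification accuracy
#' (fraction of sibling pairs with LR at or above the limit) and
#' false-positive ratio (fraction of unrelated pairs at or above it).
#'
#' @aliases KinshipSim
#' @seealso \code{\link{powerStudy}} which constructs these objects.
#' @exportClass KinshipSim
setClass("KinshipSim",
         representation(log10FS = "numeric", log10UN = "numeric",
                        limits = "numeric", accuracy = "numeric",
                        falsePositive = "numeric", nPairs = "integer",
                        seed = "integer"))

setValidity("KinshipSim", function(object) {
    msg <- NULL
    if (is.unsorted(rev(object@accuracy)) &&
        any(diff(object@accuracy) > 1e-12))
        msg <- c(msg, "accuracy must be non-increasing in the limit")
    if (any(object@accuracy < 0 | object@accuracy > 1) ||
        any(object@falsePositive < 0 | object@falsePositive > 1))
        msg <- c(msg, "rates must lie in [0, 1]")
    if (is.null(msg)) TRUE else msg
})

setMethod("show", "KinshipSim", function(object) {
    cat("KinshipSim:", object@nPairs, "pairs per hypothesis, seed",
        object@seed, "\n")
    print(data.frame(limit = object@limits,
                     accuracy = object@accuracy,
                     false_positive = object@falsePositive))
})

#' Per-threshold summary of a kinship power study
#'
#' @param x a \linkS4class{KinshipSim} object.
#' @return A data.frame with columns \code{limit}, \code{accuracy} and
#'   \code{false_positive} (proportions in [0, 1]).
#' @export
kinshipSummary <- function(x) {
    stopifnot(is(x, "KinshipSim"))
    data.frame(limit = x@limits, accuracy = x@accuracy,
               false_positive = x@falsePositive)
}

#' Simulated log10 likelihood-ratio samples
#'
#' @param x a \linkS4class{KinshipSim} object.
#' @param hypothesis \code{"full_sibling"} or \code{"unrelated"}.
#' @return Numeric vector of log10 LR values.
#' @export
log10LrSamples <- function(x, hypothesis = c("full_sibling", "unrelated")) {
    stopifnot(is(x, "KinshipSim"))
    if (match.arg(hypothesis) == "full_sibling") x@log10FS else x@log10UN
}
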