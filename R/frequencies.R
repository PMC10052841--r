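#' Estimate insertion-allele frequencies
#'
#' Tallies insertion-allele counts per locus within each group of samples:
#' \code{p_ins = (sum of dosages) / (2 * number of non-missing calls)}.
#' Missing calls are excluded locus-wise (pairwise deletion, never
#' imputation). Only autosomal loci are used.
#'
#' @param g a \linkS4class{DipGenotypes} object.
#' @param by grouping key: \code{"population"} (default),
#'   \code{"continent"}, or \code{"all"} for a single pooled group.
#' @return A \linkS4class{DipFrequencies}; the per-group \code{n} is the
#'   median non-missing diploid count across loci. Loci that are entirely
#'   missing in some group are dropped with a warning; monomorphic loci
#'   (frequency 0 or 1 in every group) are kept but reported via the
#'   \code{"monomorphic"} attribute.
#' @export
alleleFrequencies <- function(g, by = c("population", "continent", "all")) {
    by <- match.arg(by)
    g <- autosomal(g)
    if (nrow(g) == 0L) stop("no autosomal loci")
    d <- dosage(g)
    key <- switch(by,
                  population = populationLabels(g),
                  continent = continentLabels(g),
                  all = rep("all", ncol(d)))
    groups <- unique(key)
    p <- matrix(NA_real_, nrow(d), length(groups),
                dimnames = list(rownames(d), groups))
    nn <- matrix(0L, nrow(d), length(groups))
    for (k in seq_along(groups)) {
        dk <- d[, key == groups[k], drop = FALSE]
        cnt <- rowSums(!is.na(dk))
        p[, k] <- rowSums(dk, na.rm = TRUE) / (2 * cnt)
        nn[, k] <- cnt
    }
    dead <- rowSums(nn == 0L) > 0L
    if (any(dead)) {
        warning("dropping loci with no calls in some group: ",
                paste(rownames(d)[dead], collapse = ", "))
        p <- p[!dead, , drop = FALSE]
        nn <- nn[!dead, , drop = FALSE]
    }
    if (nrow(p) == 0L) stop("no locus has calls in every group")
    out <- DipFrequencies(p, n = as.integer(apply(nn, 2, stats::median)))
    mono <- rownames(p)[apply(p, 1, function(x) all(x %in% c(0, 1)))]
    attr(out, "monomorphic") <- mono
    out
}

#' Per-locus genotype counts within one group
#'
#' Counts of the three dosage classes (\code{n0} = deletion homozygote,
#' \code{n1} = heterozygote, \code{n2} = insertion homozygote) per
#' autosomal locus, optionally restricted to one population.
#'
#' @param g a \linkS4class{DipGenotypes} object.
#' @param population optional population label to subset to.
#' @return A data.frame with columns \code{locus}, \code{n0}, \code{n1},
#'   \code{n2}.
#' @export
genotypeCounts <- function(g, population = NULL) {
    g <- autosomal(g)
    if (!is.null(population))
        g <- g[, populationLabels(g) %in% population]
    d <- dosage(g)
    data.frame(locus = rownames(d),
               n0 = rowSums(d == 0L, na.rm = TRUE),
               n1 = rowSums(d == 1L, na.rm = TRUE),
               n2 = rowSums(d == 2L, na.rm = TRUE),
               row.names = NULL)
}
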