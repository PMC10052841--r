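## IBD-sharing (kappa) coefficients for full siblings
.KAPPA_FS <- c(k0 = 0.25, k1 = 0.5, k2 = 0.25)

#' Single-locus full-sibling likelihood ratio
#'
#' Likelihood ratio for the hypothesis pair "full siblings" versus
#' "unrelated" at one biallelic locus, via the IBD decomposition
#' \deqn{LR = \kappa_0 + \kappa_1 \frac{T_1(g_2 \mid g_1, p)}{P(g_2)}
#'   + \kappa_2 \frac{[g_1 = g_2]}{P(g_2)}}
#' with \eqn{\kappa = (0.25, 0.5, 0.25)}, Hardy-Weinberg genotype
#' probabilities \eqn{P(\cdot)}, and \eqn{T_1} the genotype transition
#' distribution given one shared allele.
#'
#' @param g1,g2 insertion dosages (0, 1 or 2) of the two individuals.
#' @param p insertion-allele frequency, strictly inside (0, 1).
#' @return The likelihood ratio (vectorised over the arguments).
#' @examples
#' sibLrLocus(2, 2, 0.5)   # 2.25
#' sibLrLocus(2, 0, 0.5)   # 0.25
#' @export
sibLrLocus <- function(g1, g2, p) {
    stopifnot(all(g1 %in% 0:2), all(g2 %in% 0:2))
    if (any(p <= 0 | p >= 1))
        stop("p must lie strictly inside (0, 1); fixed loci are uninformative")
    q <- 1 - p
    pg2 <- ifelse(g2 == 2, p^2, ifelse(g2 == 1, 2 * p * q, q^2))
    t1 <- .sibT1(g1, g2, p)
    unname(.KAPPA_FS["k0"] + .KAPPA_FS["k1"] * t1 / pg2 +
           .KAPPA_FS["k2"] * (g1 == g2) / pg2)
}

## T1(g2 | g1, p): distribution of the sib's genotype given exactly one
## allele shared IBD with g1 (the non-shared allele is a fresh HWE draw)
.sibT1 <- function(g1, g2, p) {
    q <- 1 - p
    ## P(transmitted allele = I | g1) is g1/2; the companion allele is I w.p. p
    pi <- g1 / 2
    ifelse(g2 == 2, pi * p,
    ifelse(g2 == 1, pi * q + (1 - pi) * p,
                    (1 - pi) * q))
}

#' Combined log10 likelihood ratio over a panel
#'
#' Sums per-locus log10 sibling LRs over the panel (valid for loci in
#' linkage equilibrium). Loci with a missing call in either individual,
#' or with a degenerate frequency (0 or 1), are skipped.
#'
#' @param g1,g2 dosage vectors over the panel's loci.
#' @param p vector of insertion frequencies, one per locus.
#' @return log10 of the combined LR; 0 (with a warning) if no locus is
#'   informative.
#' @export
panelLogLr <- function(g1, g2, p) {
    ok <- !is.na(g1) & !is.na(g2) & !is.na(p) & p > 0 & p < 1
    if (!any(ok)) {
        warning("no informative locus; combined LR is 1")
        return(0)
    }
    sum(log10(sibLrLocus(g1[ok], g2[ok], p[ok])))
}

#' Simulate a genotype pair under a relatedness hypothesis
#'
#' Unrelated pairs are two independent Hardy-Weinberg draws. Full-sibling
#' pairs are produced mechanistically: two parents are drawn from HWE and
#' each child independently receives one uniformly chosen allele from each
#' parent, per locus — so the (0.25, 0.5, 0.25) IBD pattern emerges from
#' Mendelian segregation rather than being imposed.
#'
#' @param p vector of insertion frequencies over loci, all inside (0, 1).
#' @param relationship \code{"unrelated"} or \code{"full_sibling"}.
#' @return A list with dosage vectors \code{g1}, \code{g2}.
#' @export
simulatePair <- function(p, relationship = c("unrelated", "full_sibling")) {
    relationship <- match.arg(relationship)
    if (!length(p)) stop("empty frequency vector")
    stopifnot(all(p > 0 & p < 1))
    L <- length(p)
    if (relationship == "unrelated")
        return(list(g1 = stats::rbinom(L, 2, p), g2 = stats::rbinom(L, 2, p)))
    mum <- stats::rbinom(L, 2, p)
    dad <- stats::rbinom(L, 2, p)
    gamete <- function(par) stats::rbinom(L, 1, par / 2)
    list(g1 = gamete(mum) + gamete(dad), g2 = gamete(mum) + gamete(dad))
}

#' Full-sibling identification power study
#'
#' Simulates \code{nPairs} full-sibling and \code{nPairs} unrelated pairs
#' from a population's allele frequencies, computes each pair's combined
#' sibling-vs-unrelated LR, and classifies pairs at each LR limit with the
#' inclusive rule \eqn{LR \ge limit}. Accuracy is the fraction of sibling
#' pairs at or above the limit; the false-positive ratio is the fraction
#' of unrelated pairs at or above it.
#'
#' @param freqs a \linkS4class{DipFrequencies} object or a bare numeric
#'   vector of insertion frequencies.
#' @param population population column of \code{freqs} to use (default:
#'   first).
#' @param nPairs pairs simulated per hypothesis (default 1000).
#' @param limits LR decision thresholds (default 1, 10, 100, 1000, 10000).
#' @param seed integer seed; all randomness in the study flows from it.
#' @return A \linkS4class{KinshipSim} object.
#' @examples
#' ks <- powerStudy(syntheticPanelFreqs(), nPairs = 200, seed = 7)
#' kinshipSummary(ks)
#' @export
powerStudy <- function(freqs, population = NULL, nPairs = 1000L,
                       limits = c(1, 10, 100, 1000, 10000), seed = 1L) {
    if (nPairs < 1) stop("nPairs must be at least 1")
    p <- .freqVector(freqs, population)
    drop <- p <= 0 | p >= 1
    if (any(drop)) {
        warning(sum(drop), " fixed loci excluded from the LR engine")
        p <- p[!drop]
    }
    set.seed(as.integer(seed))
    one <- function(rel) {
        pr <- simulatePair(p, rel)
        panelLogLr(pr$g1, pr$g2, p)
    }
    lfs <- if (length(p)) vapply(seq_len(nPairs),
                                 function(i) one("full_sibling"), 0)
           else rep(0, nPairs)
    lun <- if (length(p)) vapply(seq_len(nPairs),
                                 function(i) one("unrelated"), 0)
           else rep(0, nPairs)
    lt <- log10(limits)
    acc <- vapply(lt, function(t) mean(lfs >= t), 0)
    fp <- vapply(lt, function(t) mean(lun >= t), 0)
    new("KinshipSim", log10FS = lfs, log10UN = lun, limits = limits,
        accuracy = acc, falsePositive = fp, nPairs = as.integer(nPairs),
        seed = as.integer(seed))
}

.freqVector <- function(freqs, population = NULL) {
    if (is(freqs, "DipFrequencies")) {
        m <- pIns(freqs)
        col <- if (is.null(population)) 1L else {
            if (!population %in% colnames(m))
                stop("population '", population, "' not in frequency table")
            population
        }
        stats::setNames(m[, col], rownames(m))
    } else as.numeric(freqs)
}
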