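#' Balding-Nichols population allele frequencies
#'
#' Draws population-specific insertion frequencies around an ancestral
#' frequency under the Balding-Nichols beta model:
#' \deqn{p_{pop} \sim Beta\big(p_a (1-F)/F,\ (1-p_a)(1-F)/F\big)}
#' whose mean is \eqn{p_a} and variance \eqn{F p_a (1 - p_a)}.
#'
#' @param pAnc ancestral frequency(ies) in (0, 1).
#' @param F differentiation parameter in (0, 1).
#' @param n number of draws per ancestral frequency.
#' @return Numeric vector (or matrix if \code{length(pAnc) > 1} and
#'   \code{n > 1}) of frequencies, truncated into
#'   \code{[1e-4, 1 - 1e-4]} so every locus stays informative.
#' @export
bnFrequencies <- function(pAnc, F, n = 1L) {
    stopifnot(all(pAnc > 0 & pAnc < 1), F > 0, F < 1)
    draws <- stats::rbeta(length(pAnc) * n,
                          shape1 = rep(pAnc, n) * (1 - F) / F,
                          shape2 = rep(1 - pAnc, n) * (1 - F) / F)
    draws <- pmin(pmax(draws, 1e-4), 1 - 1e-4)
    if (length(pAnc) > 1 && n > 1) matrix(draws, length(pAnc), n) else draws
}

#' Configuration for the synthetic dataset generator
#'
#' Defaults emulate the shape of a worldwide forensic DIP reference
#' panel: 57 biallelic autosomal loci with ancestral insertion
#' frequencies uniform on [0.3, 0.72]; five continental groups whose
#' divergence from the ancestral pool is calibrated so that pairwise
#' Weir-Cockerham theta between an East Asian population and African,
#' European, American and South Asian populations lands near 0.18, 0.11,
#' 0.07 and 0.06 (pairwise theta under this hierarchy estimates roughly
#' the mean of the two continental divergences); 34 populations (13 East
#' Asian, 7 African, 5 European, 5 South Asian, 4 American) of ~142
#' diploid samples each, with within-continent differentiation 0.009
#' giving within-East-Asia pairwise theta near 0.01.
#'
#' @param nLoci number of loci.
#' @param continents named numeric vector: continent-to-ancestral FST.
#' @param popsPerContinent named integer vector, same names: populations
#'   per continent.
#' @param fstWithinContinent population-to-continent FST (recycled).
#' @param nSamples diploid samples per population (recycled).
#' @param ancestralRange range of the uniform ancestral-frequency sampler.
#' @return A list of class \code{"dipSimConfig"}.
#' @export
syntheticConfig <- function(nLoci = 57L,
                            continents = c(Africa = 0.30, Europe = 0.17,
                                           East_Asia = 0.05, America = 0.09,
                                           South_Asia = 0.06),
                            popsPerContinent = c(Africa = 7L, Europe = 5L,
                                                 East_Asia = 13L,
                                                 America = 4L,
                                                 South_Asia = 5L),
                            fstWithinContinent = 0.009,
                            nSamples = 142L,
                            ancestralRange = c(0.3, 0.72)) {
    stopifnot(nLoci >= 1, all(continents > 0 & continents < 1),
              all(popsPerContinent >= 1),
              all(fstWithinContinent > 0 & fstWithinContinent < 1),
              all(nSamples >= 2),
              length(ancestralRange) == 2, ancestralRange[1] > 0,
              ancestralRange[2] < 1)
    if (!identical(sort(names(continents)), sort(names(popsPerContinent))))
        stop("continents and popsPerContinent must share names")
    structure(list(nLoci = as.integer(nLoci), continents = continents,
                   popsPerContinent = popsPerContinent[names(continents)],
                   fstWithinContinent = fstWithinContinent,
                   nSamples = nSamples, ancestralRange = ancestralRange),
              class = "dipSimConfig")
}

#' Generate a population-structured synthetic genotype dataset
#'
#' Hierarchical Balding-Nichols sampling: ancestral frequencies are drawn
#' uniformly, each continent's frequencies diverge from them at the
#' continental FST, each population's diverge from its continent at the
#' within-continent FST, and genotypes are drawn under Hardy-Weinberg
#' equilibrium within populations. Loci are unlinked by construction.
#'
#' @param cfg a configuration from \code{\link{syntheticConfig}}.
#' @param seed integer seed; the dataset is a pure function of
#'   \code{(cfg, seed)}.
#' @return A list with \code{genotypes} (a \linkS4class{DipGenotypes}) and
#'   \code{truth} (the generating \linkS4class{DipFrequencies}).
#' @examples
#' ds <- makeDataset(syntheticConfig(nLoci = 5, nSamples = 10), seed = 1)
#' ds$genotypes
#' @export
makeDataset <- function(cfg = syntheticConfig(), seed = 1L) {
    stopifnot(inherits(cfg, "dipSimConfig"))
    set.seed(as.integer(seed))
    L <- cfg$nLoci
    loci <- sprintf("L%02d", seq_len(L))
    pAnc <- stats::runif(L, cfg$ancestralRange[1], cfg$ancestralRange[2])
    popNames <- character(0)
    popCont <- character(0)
    pPop <- NULL
    for (k in seq_along(cfg$continents)) {
        cont <- names(cfg$continents)[k]
        pCont <- bnFrequencies(pAnc, cfg$continents[[k]])
        nPop <- cfg$popsPerContinent[[k]]
        fw <- rep_len(cfg$fstWithinContinent, nPop)
        for (j in seq_len(nPop)) {
            popNames <- c(popNames, sprintf("%s_%02d", cont, j))
            popCont <- c(popCont, cont)
            pPop <- cbind(pPop, bnFrequencies(pCont, fw[j]))
        }
    }
    dimnames(pPop) <- list(loci, popNames)
    nPer <- rep_len(cfg$nSamples, length(popNames))
    total <- sum(nPer)
    d <- matrix(NA_integer_, L, total)
    sampPop <- rep(popNames, nPer)
    sampCont <- rep(popCont, nPer)
    col <- 0L
    for (j in seq_along(popNames)) {
        for (s in seq_len(nPer[j])) {
            col <- col + 1L
            d[, col] <- stats::rbinom(L, 2, pPop[, j])
        }
    }
    colnames(d) <- sprintf("%s_s%04d", sampPop, seq_len(total))
    rownames(d) <- loci
    list(genotypes = DipGenotypes(d, population = sampPop,
                                  continent = sampCont),
         truth = DipFrequencies(pPop, n = nPer))
}

#' Deterministic 57-locus reference frequency profile (synthetic)
#'
#' A synthetic stand-in for a single population's insertion-frequency
#' table over a 57-locus forensic DIP identification panel. The profile
#' is fixed (no randomness): frequencies are power-law spaced between
#' 0.3283 and 0.7146 with the exponent solved so the mean is 0.5045 —
#' the minimum, maximum and mean insertion frequencies characteristic of
#' such panels in East Asian populations. It drives kinship power studies
#' and worked examples when real genotypes are unavailable.
#'
#' @param n nominal diploid sample size attached to the table
#'   (default 233).
#' @return A \linkS4class{DipFrequencies} with one population
#'   (\code{"SYN"}).
#' @examples
#' range(pIns(syntheticPanelFreqs()))
#' @export
syntheticPanelFreqs <- function(n = 233L) {
    lo <- 0.3283; hi <- 0.7146; mu <- 0.5045
    u <- (0:56) / 56
    gamma <- stats::uniroot(function(g) mean(u^g) - (mu - lo) / (hi - lo),
                            c(0.1, 10))$root
    p <- lo + (hi - lo) * u^gamma
    DipFrequencies(matrix(p, 57, 1,
                          dimnames = list(sprintf("L%02d", 1:57), "SYN")),
                   n = n)
}
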