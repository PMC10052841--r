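#' Exact Hardy-Weinberg test for a biallelic locus
#'
#' Exact conditional test: given the minor-allele count, the probability of
#' every admissible heterozygote count (same parity as the minor-allele
#' count) is enumerated, and the two-sided p-value is the sum of the
#' probabilities of all outcomes no more likely than the observed one
#' (probability-ordering tail convention).
#'
#' @param n0,n1,n2 genotype counts: deletion homozygotes, heterozygotes,
#'   insertion homozygotes.
#' @return A list with \code{p_value}, \code{n_het} (observed), and
#'   \code{direction} (\code{"excess"}, \code{"deficit"} or
#'   \code{"none"} relative to the Hardy-Weinberg expectation). A
#'   monomorphic locus returns \code{p_value = 1} by convention.
#' @examples
#' hweExact(21, 55, 24)
#' @export
hweExact <- function(n0, n1, n2) {
    stopifnot(n0 >= 0, n1 >= 0, n2 >= 0)
    n <- n0 + n1 + n2
    if (n < 1) stop("empty genotype counts")
    nIns <- 2 * n2 + n1
    nA <- min(nIns, 2 * n - nIns)           # minor-allele count
    if (nA == 0L)
        return(list(p_value = 1, n_het = n1, direction = "none"))
    hets <- seq(nA %% 2, nA, by = 2)
    logp <- .hweLogProb(hets, n, nA)
    logp <- logp - max(logp)
    pr <- exp(logp)
    pr <- pr / sum(pr)
    obs <- pr[match(n1, hets)]
    p <- min(1, sum(pr[pr <= obs * (1 + 1e-10)]))
    pq <- (nIns / (2 * n)) * (1 - nIns / (2 * n))
    expected <- 2 * pq * n
    dir <- if (n1 > expected) "excess" else if (n1 < expected) "deficit"
           else "none"
    list(p_value = p, n_het = n1, direction = dir)
}

## log P(n_het | n, minor-count) up to a constant, closed form via lgamma
.hweLogProb <- function(h, n, nA) {
    homMinor <- (nA - h) / 2
    homMajor <- n - h - homMinor
    h * log(2) - lfactorial(homMinor) - lfactorial(h) - lfactorial(homMajor)
}

#' Hardy-Weinberg screen of a genotyped panel
#'
#' Applies \code{\link{hweExact}} to every autosomal locus and attaches a
#' Bonferroni verdict at family-wise level \code{alpha}.
#'
#' @param g a \linkS4class{DipGenotypes} object.
#' @param population optional population label(s) to subset to.
#' @param alpha family-wise significance level (default 0.05).
#' @return A data.frame with columns \code{locus}, \code{n_het},
#'   \code{p_value}, \code{direction}, \code{significant} (raw p below the
#'   Bonferroni threshold \code{alpha / n_loci}).
#' @export
hweTest <- function(g, population = NULL, alpha = 0.05) {
    cc <- genotypeCounts(g, population = population)
    res <- lapply(seq_len(nrow(cc)), function(i)
        hweExact(cc$n0[i], cc$n1[i], cc$n2[i]))
    thr <- bonferroniThreshold(alpha, nrow(cc))
    data.frame(locus = cc$locus,
               n_het = vapply(res, `[[`, 0, "n_het"),
               p_value = vapply(res, `[[`, 0, "p_value"),
               direction = vapply(res, `[[`, "", "direction"),
               significant = vapply(res, `[[`, 0, "p_value") < thr,
               row.names = NULL)
}

#' Bonferroni significance threshold
#'
#' @param alpha family-wise level in (0, 1).
#' @param m number of tests.
#' @return \code{alpha / m}.
#' @examples
#' bonferroniThreshold(0.05, choose(57, 2))  # 3.1328e-05
#' @export
bonferroniThreshold <- function(alpha, m) {
    stopifnot(alpha > 0, alpha < 1, m >= 1)
    alpha / m
}

#' Two-locus linkage-disequilibrium test (EM + likelihood ratio)
#'
#' Estimates the four two-locus haplotype frequencies from unphased
#' genotypes by EM (the double-heterozygote phase is the only ambiguity),
#' then tests for LD with the likelihood-ratio statistic
#' \eqn{G = 2(\ln L_{hap} - \ln L_{indep})}. Significance comes from a
#' permutation test (one locus's genotypes permuted across individuals;
#' the observed statistic is included in the reference set) and, for
#' speed, the asymptotic chi-square(1) p-value is also reported.
#'
#' @param gA,gB insertion-dosage vectors (0/1/2, NA = missing) of the two
#'   loci over the same samples.
#' @param permutations number of permutations (0 = asymptotic only).
#' @param seed integer seed for the permutation; required when
#'   \code{permutations > 0}.
#' @param tol,maxIter EM convergence tolerance and iteration cap.
#' @return A list with haplotype frequencies \code{hap} (II, ID, DI, DD in
#'   insertion/deletion order for locus A then B), \code{D}, \code{r2},
#'   \code{G}, \code{p_perm}, \code{p_chisq}, \code{permutations},
#'   \code{monomorphic} flag.
#' @export
ldTest <- function(gA, gB, permutations = 10000L, seed = NULL,
                   tol = 1e-8, maxIter = 1000L) {
    ok <- !is.na(gA) & !is.na(gB)
    gA <- as.integer(gA[ok]); gB <- as.integer(gB[ok])
    if (length(gA) < 2) stop("need at least 2 complete genotype pairs")
    pA <- mean(gA) / 2; pB <- mean(gB) / 2
    if (pA %in% c(0, 1) || pB %in% c(0, 1))
        return(list(hap = c(II = pA * pB, ID = pA * (1 - pB),
                            DI = (1 - pA) * pB, DD = (1 - pA) * (1 - pB)),
                    D = 0, r2 = NA_real_, G = 0, p_perm = 1, p_chisq = 1,
                    permutations = 0L, monomorphic = TRUE))
    counts <- tabulate(gA * 3L + gB + 1L, 9L)  # 3x3 table, gA major index
    fit <- .ldEm(counts, tol, maxIter)
    obsG <- fit$G
    pPerm <- NA_real_
    if (permutations > 0) {
        if (is.null(seed)) stop("permutation test needs a seed")
        set.seed(as.integer(seed))
        hits <- 0L
        for (b in seq_len(permutations)) {
            cb <- tabulate(gA * 3L + sample(gB) + 1L, 9L)
            if (.ldEm(cb, tol, maxIter)$G >= obsG - 1e-12) hits <- hits + 1L
        }
        pPerm <- (hits + 1) / (permutations + 1)
    }
    c(fit[c("hap", "D", "r2", "G")],
      list(p_perm = pPerm,
           p_chisq = stats::pchisq(obsG, df = 1, lower.tail = FALSE),
           permutations = as.integer(permutations), monomorphic = FALSE))
}

## EM on the 3x3 genotype count table (rows gA = 0,1,2; cols gB = 0,1,2
## flattened as gA*3+gB). Returns haplotype freqs, D, r2, G.
.ldEm <- function(counts, tol = 1e-8, maxIter = 1000L) {
    n <- sum(counts)
    cn <- function(a, b) counts[a * 3 + b + 1]
    pA <- sum(counts * rep(0:2, each = 3)) / (2 * n)
    pB <- sum(counts * rep(0:2, times = 3)) / (2 * n)
    ## haplotype counts fixed by unambiguous genotypes; the double het
    ## (1,1) splits between (II+DD) and (ID+DI)
    x <- c(II = pA * pB, ID = pA * (1 - pB), DI = (1 - pA) * pB,
           DD = (1 - pA) * (1 - pB))
    nDH <- cn(1, 1)
    base <- c(II = 2 * cn(2, 2) + cn(2, 1) + cn(1, 2),
              ID = 2 * cn(2, 0) + cn(2, 1) + cn(1, 0),
              DI = 2 * cn(0, 2) + cn(0, 1) + cn(1, 2),
              DD = 2 * cn(0, 0) + cn(0, 1) + cn(1, 0))
    for (it in seq_len(maxIter)) {
        wCis <- x["II"] * x["DD"]
        wTrans <- x["ID"] * x["DI"]
        a <- if (wCis + wTrans > 0) wCis / (wCis + wTrans) else 0.5
        xNew <- (base + nDH * c(a, 1 - a, 1 - a, a)) / (2 * n)
        if (max(abs(xNew - x)) < tol) { x <- xNew; break }
        x <- xNew
    }
    D <- unname(x["II"] - pA * pB)
    geno <- function(f) {
        p <- c(f["DD"]^2, 2 * f["DD"] * f["DI"], f["DI"]^2,
               2 * f["ID"] * f["DD"], 2 * (f["II"] * f["DD"] + f["ID"] * f["DI"]),
               2 * f["II"] * f["DI"],
               f["ID"]^2, 2 * f["II"] * f["ID"], f["II"]^2)
        p  # indexed as gA*3+gB+1
    }
    indep <- c(II = pA * pB, ID = pA * (1 - pB), DI = (1 - pA) * pB,
               DD = (1 - pA) * (1 - pB))
    ll <- function(f) {
        p <- geno(f)
        sum(counts[counts > 0] * log(p[counts > 0]))
    }
    G <- 2 * (ll(x) - ll(indep))
    list(hap = x, D = D, r2 = D^2 / (pA * (1 - pA) * pB * (1 - pB)),
         G = max(G, 0))
}

#' Pairwise LD screen of a genotyped panel
#'
#' Runs \code{\link{ldTest}} on every pair of autosomal loci and attaches
#' the Bonferroni verdict at family-wise level \code{alpha} over
#' \code{choose(L, 2)} tests.
#'
#' @inheritParams hweTest
#' @param permutations permutations per pair (0 = asymptotic chi-square
#'   p-values only, the default for a full-panel screen).
#' @param seed integer seed (required when \code{permutations > 0}).
#' @return A data.frame with one row per locus pair: \code{locusA},
#'   \code{locusB}, \code{D}, \code{r2}, \code{G}, \code{p_value} (the
#'   permutation p if permutations were run, else asymptotic),
#'   \code{significant}.
#' @export
ldScreen <- function(g, population = NULL, permutations = 0L, seed = NULL,
                     alpha = 0.05) {
    g <- autosomal(g)
    if (!is.null(population)) g <- g[, populationLabels(g) %in% population]
    d <- dosage(g)
    L <- nrow(d)
    if (L < 2) stop("need at least two loci")
    pairs <- utils::combn(L, 2)
    thr <- bonferroniThreshold(alpha, ncol(pairs))
    rows <- lapply(seq_len(ncol(pairs)), function(k) {
        i <- pairs[1, k]; j <- pairs[2, k]
        r <- ldTest(d[i, ], d[j, ], permutations = permutations, seed = seed)
        p <- if (permutations > 0) r$p_perm else r$p_chisq
        data.frame(locusA = rownames(d)[i], locusB = rownames(d)[j],
                   D = r$D, r2 = r$r2, G = r$G, p_value = p,
                   significant = p < thr)
    })
    do.call(rbind, rows)
}
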