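#' Weir-Cockerham FST between populations
#'
#' Multi-locus Weir-Cockerham (1984) theta from genotype data. Per locus,
#' the among-population (a), among-individual-within-population (b) and
#' within-individual (c) variance components are computed from allele
#' frequencies, sample sizes and observed heterozygosities, and
#' \eqn{\theta = \sum_l a_l / \sum_l (a_l + b_l + c_l)}. Negative
#' estimates are retained (they are legitimate near zero differentiation);
#' see \code{\link{clampNonNegative}} before feeding geometry consumers.
#'
#' @param g a \linkS4class{DipGenotypes} object.
#' @param populations the two (or more) population labels to compare;
#'   default: all populations in \code{g}.
#' @return The multi-locus theta (single number).
#' @export
wcFst <- function(g, populations = NULL) {
    comp <- .wcComponents(g, populations)
    denom <- sum(comp$a + comp$b + comp$c)
    if (denom <= 0) stop("no shared informative loci between the populations")
    sum(comp$a) / denom
}

## Per-locus W&C variance components over r >= 2 population samples
.wcComponents <- function(g, populations = NULL) {
    g <- autosomal(g)
    if (is.null(populations)) populations <- unique(populationLabels(g))
    if (length(populations) < 2) stop("need at least two populations")
    d <- dosage(g)
    key <- populationLabels(g)
    r <- length(populations)
    nMat <- pMat <- hMat <- matrix(0, nrow(d), r)
    for (k in seq_len(r)) {
        dk <- d[, key == populations[k], drop = FALSE]
        if (ncol(dk) == 0) stop("population '", populations[k], "' not found")
        nMat[, k] <- rowSums(!is.na(dk))
        pMat[, k] <- rowSums(dk, na.rm = TRUE) / (2 * nMat[, k])
        hMat[, k] <- rowSums(dk == 1L, na.rm = TRUE) / nMat[, k]
    }
    ok <- rowSums(nMat >= 2) == r
    if (!any(ok)) stop("no locus with >= 2 samples in every population")
    a <- b <- cc <- numeric(sum(ok))
    idx <- which(ok)
    for (i in seq_along(idx)) {
        l <- idx[i]
        ni <- nMat[l, ]; pi <- pMat[l, ]; hi <- hMat[l, ]
        nbar <- mean(ni)
        nc <- (r * nbar - sum(ni^2) / (r * nbar)) / (r - 1)
        pbar <- sum(ni * pi) / (r * nbar)
        s2 <- sum(ni * (pi - pbar)^2) / ((r - 1) * nbar)
        hbar <- sum(ni * hi) / (r * nbar)
        a[i] <- nbar / nc *
            (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) /
                 (nbar - 1))
        b[i] <- nbar / (nbar - 1) *
            (pbar * (1 - pbar) - (r - 1) / r * s2 -
                 (2 * nbar - 1) / (4 * nbar) * hbar)
        cc[i] <- hbar / 2
    }
    list(a = a, b = b, c = cc, loci = rownames(d)[idx])
}

#' Pairwise FST matrix over all populations
#'
#' @inheritParams wcFst
#' @return A \linkS4class{DipDistance} with \code{metricName "fst"};
#'   negative estimates are retained (\code{isClamped(x)} is FALSE).
#' @export
fstMatrix <- function(g) {
    pops <- unique(populationLabels(g))
    K <- length(pops)
    if (K < 2) stop("need at least two populations")
    m <- matrix(0, K, K, dimnames = list(pops, pops))
    for (i in seq_len(K - 1)) for (j in (i + 1):K)
        m[i, j] <- m[j, i] <- wcFst(g, c(pops[i], pops[j]))
    DipDistance(m, metric = "fst", clamped = FALSE)
}

#' Floor negative distances at zero
#'
#' Geometry-consuming stages (classical MDS, NJ) need non-negative
#' dissimilarities; this floors negative entries at 0 and sets the
#' \code{clamped} flag.
#'
#' @param d a \linkS4class{DipDistance}.
#' @return A \linkS4class{DipDistance} with non-negative entries.
#' @export
clampNonNegative <- function(d) {
    stopifnot(is(d, "DipDistance"))
    v <- as.matrix(d)
    had <- any(v < 0)
    v[v < 0] <- 0
    DipDistance(v, metric = metricName(d), clamped = had || isClamped(d))
}

#' Nei's DA genetic distance
#'
#' For biallelic loci, \eqn{D_A = 1 - \frac{1}{L}\sum_l
#' (\sqrt{p_{lx} p_{ly}} + \sqrt{q_{lx} q_{ly}})} between two allele
#' frequency vectors.
#'
#' @param fA,fB insertion-frequency vectors over the same loci.
#' @return The DA distance (single number in [0, 1]).
#' @examples
#' daDistance(0.9, 0.6)   # 1 - (sqrt(0.54) + sqrt(0.04))
#' @export
daDistance <- function(fA, fB) {
    if (length(fA) != length(fB))
        stop("frequency vectors must cover the same locus set")
    stopifnot(all(fA >= 0 & fA <= 1), all(fB >= 0 & fB <= 1))
    1 - mean(sqrt(fA * fB) + sqrt((1 - fA) * (1 - fB)))
}

#' Pairwise DA matrix from a frequency table
#'
#' @param f a \linkS4class{DipFrequencies}.
#' @return A \linkS4class{DipDistance} with \code{metricName "da"}.
#' @export
daMatrix <- function(f) {
    p <- pIns(f)
    K <- ncol(p)
    if (K < 2) stop("need at least two populations")
    m <- matrix(0, K, K, dimnames = list(colnames(p), colnames(p)))
    for (i in seq_len(K - 1)) for (j in (i + 1):K)
        m[i, j] <- m[j, i] <- daDistance(p[, i], p[, j])
    DipDistance(m, metric = "da", clamped = FALSE)
}

#' Rosenberg's informativeness for assignment
#'
#' Per-locus \eqn{I_n} over K populations:
#' \deqn{I_n = \sum_{alleles} \Big(-\bar p \ln \bar p +
#'   \frac{1}{K}\sum_i p_i \ln p_i\Big)}
#' with natural logarithms, the unweighted across-population mean
#' \eqn{\bar p}, and \eqn{0 \ln 0 := 0}. \eqn{I_n} is 0 iff all
#' populations share identical frequencies and is bounded by \eqn{\ln K}.
#'
#' @param f a \linkS4class{DipFrequencies} (or a loci x populations
#'   matrix of insertion frequencies).
#' @param populations optional subset of population labels (K >= 2).
#' @return A data.frame with columns \code{locus} and \code{In} (nats).
#' @export
informativenessIn <- function(f, populations = NULL) {
    p <- if (is(f, "DipFrequencies")) pIns(f) else as.matrix(f)
    if (!is.null(populations)) p <- p[, populations, drop = FALSE]
    if (ncol(p) < 2) stop("need at least two populations")
    xlx <- function(x) ifelse(x > 0, x * log(x), 0)
    inOne <- function(pv) {
        K <- length(pv)
        sum(vapply(list(pv, 1 - pv), function(al) {
            m <- mean(al)
            -xlx(m) + mean(xlx(al))
        }, 0))
    }
    data.frame(locus = rownames(p), In = apply(p, 1, inOne),
               row.names = NULL)
}

#' Hierarchical analysis of molecular variance (AMOVA)
#'
#' Locus-by-locus AMOVA on allele copies (each diploid contributes two
#' insertion/deletion indicators). With a population-to-group map the
#' design is three-level (among groups / among populations within groups /
#' within populations); without one it is two-level. Sums of squares use
#' the standard unequal-size expected-mean-square coefficients; variance
#' components are summed over loci. The within-individual level is
#' collapsed into the within-population term.
#'
#' @param g a \linkS4class{DipGenotypes} object.
#' @param grouping named character vector mapping population labels to
#'   group labels (e.g. continents), or NULL for the two-level design.
#'   Defaults to the continent labels carried by \code{g} when those
#'   define more than one group.
#' @return A list with \code{design}, \code{components} (named variance
#'   components), \code{percentages} (summing to 100), \code{phi}
#'   (Phi-statistics) and \code{df}.
#' @export
amova <- function(g, grouping = NULL) {
    g <- autosomal(g)
    pops <- unique(populationLabels(g))
    if (is.null(grouping)) {
        map <- vapply(pops, function(p)
            unique(continentLabels(g)[populationLabels(g) == p]), "")
        if (length(unique(map)) > 1) grouping <- map
    }
    threeLevel <- !is.null(grouping) && length(unique(grouping)) > 1
    if (threeLevel && any(table(grouping[pops]) == 1))
        warning("a group contains a single population; ",
                "its among-population term is empty")
    d <- dosage(g)
    key <- populationLabels(g)
    P <- length(pops)
    if (P < 2) stop("need at least two populations")
    grp <- if (threeLevel) unname(grouping[pops]) else rep("all", P)
    groups <- unique(grp)
    G <- length(groups)
    sa <- sb <- sc <- 0
    for (l in seq_len(nrow(d))) {
        Np <- Tp <- numeric(P)
        for (k in seq_len(P)) {
            dk <- d[l, key == pops[k]]
            Np[k] <- 2 * sum(!is.na(dk))
            Tp[k] <- sum(dk, na.rm = TRUE)
        }
        if (any(Np == 0)) next
        N <- sum(Np); Tt <- sum(Tp)
        Ng <- tapply(Np, grp, sum)[groups]
        Tg <- tapply(Tp, grp, sum)[groups]
        ssWithin <- sum(Tp - Tp^2 / Np)
        ssPop <- sum(tapply(Tp^2 / Np, grp, sum)[groups] - Tg^2 / Ng)
        ssGrp <- sum(Tg^2 / Ng) - Tt^2 / N
        msC <- ssWithin / (N - P)
        if (threeLevel) {
            sumNp2g <- tapply(Np^2, grp, sum)[groups]
            nPP <- (sum(sumNp2g / Ng) - sum(Np^2) / N) / (G - 1)
            nPPP <- (N - sum(Ng^2) / N) / (G - 1)
            msA <- ssGrp / (G - 1)
            vc <- msC
            if (P == G) {        # every group a single population:
                vb <- 0          # the among-pops-in-groups level is empty
            } else {
                nP <- (N - sum(sumNp2g / Ng)) / (P - G)
                msB <- ssPop / (P - G)
                vb <- (msB - vc) / nP
            }
            va <- (msA - vc - nPP * vb) / nPPP
        } else {
            n1 <- (N - sum(Np^2) / N) / (P - 1)
            msB <- (ssPop + ssGrp) / (P - 1)   # ssGrp is 0 when G == 1
            vc <- msC
            vb <- (msB - vc) / n1
            va <- 0
        }
        sa <- sa + va; sb <- sb + vb; sc <- sc + vc
    }
    tot <- sa + sb + sc
    comp <- c(among_groups = sa, among_pops_within_groups = sb,
              within_pops = sc)
    if (!threeLevel)
        comp <- comp[c("among_pops_within_groups", "within_pops")] |>
            stats::setNames(c("among_pops", "within_pops"))
    phi <- c(phi_ST = (sa + sb) / tot)
    if (threeLevel)
        phi <- c(phi, phi_CT = sa / tot, phi_SC = sb / (sb + sc))
    list(design = if (threeLevel) "three-level" else "two-level",
         components = comp,
         percentages = 100 * comp / tot,
         phi = phi,
         df = if (threeLevel)
             c(among_groups = G - 1, among_pops_within_groups = P - G)
         else c(among_pops = P - 1))
}
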