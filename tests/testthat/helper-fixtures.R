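# fixture builders shared across test files; everything is generated in code

# two-population toy with written-out genotype counts
# pop A: 2/6/2 (p = 0.5, Ho = 0.6); pop B: 6/2/2 (p = 0.3, Ho = 0.2)
toyTwoPops <- function() {
    dosA <- rep(c(0L, 1L, 2L), c(2, 6, 2))
    dosB <- rep(c(0L, 1L, 2L), c(6, 2, 2))
    m <- rbind(L1 = c(dosA, dosB))
    colnames(m) <- sprintf("s%02d", 1:20)
    DipGenotypes(m, population = rep(c("A", "B"), each = 10),
                 continent = rep(c("C1", "C2"), each = 10))
}

# genotype matrix from explicit per-locus dosage rows, one population
toyGenotypes <- function(..., population = "P1", continent = "EA") {
    rows <- list(...)
    m <- do.call(rbind, rows)
    rownames(m) <- sprintf("rs%02d", seq_along(rows))
    colnames(m) <- sprintf("s%02d", seq_len(ncol(m)))
    DipGenotypes(m, population = rep(population, ncol(m)),
                 continent = rep(continent, ncol(m)))
}

# least-squares Procrustes residual after centring + orthogonal rotation
procrustesResidual <- function(X, Y) {
    X <- scale(X, scale = FALSE)
    Y <- scale(Y, scale = FALSE)
    s <- svd(crossprod(Y, X))
    R <- s$u %*% t(s$v)
    # allow a global scale (MDS reproduces configuration up to similarity)
    num <- sum(diag(crossprod(X, Y %*% R)))
    den <- sum(Y^2)
    sqrt(sum((X - (num / den) * Y %*% R)^2))
}

# exact HWE probabilities by direct factorial enumeration (oracle route,
# independent of the package's lgamma + renormalisation path)
hweOracle <- function(n0, n1, n2) {
    n <- n0 + n1 + n2
    nIns <- 2 * n2 + n1
    nA <- min(nIns, 2 * n - nIns)
    nB <- 2 * n - nA
    if (nA == 0) return(1)
    hets <- seq(nA %% 2, nA, by = 2)
    pr <- vapply(hets, function(h) {
        hm <- (nA - h) / 2
        hM <- n - h - hm
        exp(lfactorial(n) - lfactorial(hm) - lfactorial(h) - lfactorial(hM) +
            h * log(2) + lfactorial(nA) + lfactorial(nB) - lfactorial(2 * n))
    }, 0)
    obs <- pr[match(n1, hets)]
    min(1, sum(pr[pr <= obs * (1 + 1e-10)]))
}

# joint sib-pair genotype probability by enumeration over parental mating
# types and Mendelian gamete draws (oracle for the kappa-form LR)
sibPairOracle <- function(g1, g2, p) {
    q <- 1 - p
    pg <- function(g) c(q^2, 2 * p * q, p^2)[g + 1]
    childDist <- function(gm, gf) {
        out <- numeric(3)
        for (am in 0:1) for (af in 0:1) {
            pm <- if (am == 1) gm / 2 else 1 - gm / 2
            pf <- if (af == 1) gf / 2 else 1 - gf / 2
            out[am + af + 1] <- out[am + af + 1] + pm * pf
        }
        out
    }
    joint <- 0
    for (gm in 0:2) for (gf in 0:2) {
        cd <- childDist(gm, gf)
        joint <- joint + pg(gm) * pg(gf) * cd[g1 + 1] * cd[g2 + 1]
    }
    joint / (pg(g1) * pg(g2))
}
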