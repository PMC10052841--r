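test_that("single-locus sibling LR matches the Mendelian enumeration oracle", {
    for (p in c(0.1, 0.3283, 0.5, 0.7146, 0.9))
        for (g1 in 0:2) for (g2 in 0:2)
            expect_equal(sibLrLocus(g1, g2, p), sibPairOracle(g1, g2, p),
                         tolerance = 1e-12,
                         label = sprintf("p=%g g1=%d g2=%d", p, g1, g2))
    expect_equal(sibLrLocus(2, 2, 0.5), 2.25)
    expect_equal(sibLrLocus(2, 0, 0.5), 0.25)
})

test_that("sibling genotype distribution is a proper distribution", {
    for (p in c(0.2, 0.5, 0.8)) for (g1 in 0:2) {
        q <- 1 - p
        pg <- c(q^2, 2 * p * q, p^2)
        total <- sum(vapply(0:2, function(g2)
            sibLrLocus(g1, g2, p) * pg[g2 + 1], 0))
        expect_equal(total, 1, tolerance = 1e-12)  # sums over g2 to 1
    }
})

test_that("E[LR | unrelated] is exactly 1 per locus", {
    for (p in seq(0.05, 0.95, by = 0.05)) {
        q <- 1 - p
        pg <- c(q^2, 2 * p * q, p^2)
        e <- sum(outer(0:2, 0:2, Vectorize(function(a, b)
            sibLrLocus(a, b, p) * pg[a + 1] * pg[b + 1])))
        expect_equal(e, 1, tolerance = 1e-12)
    }
})

test_that("degenerate frequencies are rejected as uninformative", {
    expect_error(sibLrLocus(1, 1, 0), "strictly inside")
    expect_error(sibLrLocus(1, 1, 1), "strictly inside")
    expect_warning(out <- panelLogLr(c(1, NA), c(1, 1), c(NA, NA)),
                   "no informative locus")
    expect_equal(out, 0)
})

test_that("panel log LR is the sum of per-locus log10 contributions", {
    expect_equal(panelLogLr(c(2, 2), c(2, 0), c(0.5, 0.5)),
                 log10(2.25) + log10(0.25))
    # per-locus LRs (2, 0.5) -> combined 1 (log10 = 0)
    p <- c(0.5, 0.5)
    lr <- sibLrLocus(c(2, 2), c(2, 0), p)
    expect_equal(log10(prod(c(2, 0.5))), 0)
    # against extended-precision brute product on a random pair
    set.seed(8)
    pf <- runif(57, 0.3, 0.7)
    pr <- simulatePair(pf, "full_sibling")
    expect_equal(panelLogLr(pr$g1, pr$g2, pf),
                 sum(log10(sibLrLocus(pr$g1, pr$g2, pf))), tolerance = 1e-12)
})

test_that("mechanistic sibling simulation reproduces the kappa IBD pattern", {
    set.seed(12)
    p <- rep(0.5, 1)
    # track IBD by simulating parents with labelled alleles
    nrep <- 20000
    ibd <- replicate(nrep, {
        mum <- sample(c("m1", "m2")); dad <- sample(c("d1", "d2"))
        c1 <- c(sample(mum, 1), sample(dad, 1))
        c2 <- c(sample(mum, 1), sample(dad, 1))
        sum(c1 == c2)
    })
    emp <- tabulate(ibd + 1, 3) / nrep
    se <- sqrt(c(0.25, 0.5, 0.25) * c(0.75, 0.5, 0.75) / nrep)
    expect_true(all(abs(emp - c(0.25, 0.5, 0.25)) < 3 * se))

    # unrelated pairs: empirical allele frequency converges to the input
    pf <- seq(0.32, 0.72, length.out = 57)
    tot <- 0
    for (i in 1:200) {
        pr <- simulatePair(pf, "unrelated")
        tot <- tot + pr$g1 + pr$g2
    }
    emp <- tot / (4 * 200)
    expect_lt(max(abs(emp - pf)), 4 * sqrt(0.25 / 800) + 0.02)

    # near fixation the sibling pair is almost always insertion homozygous
    set.seed(13)
    pr <- simulatePair(rep(0.999, 500), "full_sibling")
    expect_gt(mean(pr$g1 == 2 & pr$g2 == 2), 0.98)
})

test_that("explicit-parent simulation agrees with the kappa-mixture law", {
    # joint genotype-pair frequencies from the mechanistic simulator match
    # the kappa decomposition kappa0 P(g1)P(g2) + kappa1 ... used by the LR
    set.seed(21)
    p <- 0.37
    nrep <- 30000
    g1 <- integer(nrep); g2 <- integer(nrep)
    for (i in seq_len(nrep)) {
        pr <- simulatePair(p, "full_sibling")
        g1[i] <- pr$g1; g2[i] <- pr$g2
    }
    q <- 1 - p
    pg <- c(q^2, 2 * p * q, p^2)
    for (a in 0:2) for (b in 0:2) {
        expected <- sibPairOracle(a, b, p) * pg[a + 1] * pg[b + 1]
        emp <- mean(g1 == a & g2 == b)
        expect_lt(abs(emp - expected),
                  3 * sqrt(expected * (1 - expected) / nrep) + 1e-4)
    }
})

test_that("power study rates are monotone and separate the hypotheses", {
    ks <- powerStudy(syntheticPanelFreqs(), nPairs = 400, seed = 5)
    s <- kinshipSummary(ks)
    expect_true(all(diff(s$accuracy) <= 0))
    expect_true(all(diff(s$false_positive) <= 0))
    expect_true(all(s$accuracy >= 0 & s$accuracy <= 1))
    expect_gt(mean(log10LrSamples(ks, "full_sibling")), 0)
    expect_lt(mean(log10LrSamples(ks, "unrelated")), 0)
    expect_error(powerStudy(syntheticPanelFreqs(), nPairs = 0), "at least 1")
})

test_that("a panel with no informative locus classifies everything at LR 1", {
    f <- DipFrequencies(matrix(c(0, 1), 2, 1,
                               dimnames = list(c("a", "b"), "P")), n = 10)
    expect_warning(ks <- powerStudy(f, nPairs = 50, seed = 1), "fixed loci")
    s <- kinshipSummary(ks)
    expect_equal(s$accuracy[s$limit == 1], 1)        # inclusive rule
    expect_equal(s$false_positive[s$limit == 1], 1)
    expect_equal(s$accuracy[s$limit == 10], 0)
})

test_that("the 57-locus balanced panel matches a high-replicate reference", {
    # frozen reference accuracies from an independent 10^5-pair
    # Monte-Carlo oracle at p = 0.5 for all 57 loci:
    # acc = 0.98115, 0.93533, 0.82942, 0.65421, 0.41782 at the 5 limits
    ks <- powerStudy(rep(0.5, 57), nPairs = 1000, seed = 99)
    s <- kinshipSummary(ks)
    ref <- c(0.98115, 0.93533, 0.82942, 0.65421, 0.41782)
    se <- sqrt(ref * (1 - ref) / 1000)
    expect_true(all(abs(s$accuracy - ref) < 3 * se + 0.003))
})
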