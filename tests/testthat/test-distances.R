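test_that("Weir-Cockerham components match the hand-evaluated toy", {
    # pop A counts 2/6/2 (p=0.5, Ho=0.6), pop B 6/2/2 (p=0.3, Ho=0.2):
    # a = 1/180, b = 2/45, c = 0.2, theta = 1/45
    g <- toyTwoPops()
    comp <- dipkit:::.wcComponents(g)
    expect_equal(comp$a, 1 / 180, tolerance = 1e-12)
    expect_equal(comp$b, 2 / 45, tolerance = 1e-12)
    expect_equal(comp$c, 0.2, tolerance = 1e-12)
    expect_equal(wcFst(g), 1 / 45, tolerance = 1e-12)
})

test_that("FST hits 1 for fixed opposite alleles and ~0 under the null", {
    m <- rbind(L1 = rep(c(0L, 2L), each = 10),
               L2 = rep(c(2L, 0L), each = 10))
    colnames(m) <- sprintf("s%02d", 1:20)
    g <- DipGenotypes(m, population = rep(c("A", "B"), each = 10),
                      continent = rep(c("x", "y"), each = 10))
    expect_equal(wcFst(g), 1, tolerance = 1e-12)

    set.seed(19)
    d <- t(replicate(40, rbinom(200, 2, runif(1, 0.3, 0.7))))
    rownames(d) <- sprintf("L%02d", 1:40)
    colnames(d) <- sprintf("s%03d", 1:200)
    gg <- DipGenotypes(d, population = rep(c("A", "B"), each = 100),
                       continent = rep("EA", 200))
    expect_lt(abs(wcFst(gg)), 0.02)   # one population split at random
})

test_that("FST matrix is symmetric and clamping flags negatives", {
    ds <- makeDataset(syntheticConfig(
        nLoci = 30, continents = c(A = 0.1, B = 0.1),
        popsPerContinent = c(A = 2L, B = 1L), nSamples = 40), seed = 3)
    fst <- fstMatrix(ds$genotypes)
    m <- as.matrix(fst)
    expect_lt(max(abs(m - t(m))), 1e-12)
    expect_true(all(diag(m) == 0))
    cl <- clampNonNegative(fst)
    expect_true(all(as.matrix(cl) >= 0))
})

test_that("DA distance matches hand evaluation and its bounds", {
    expect_equal(daDistance(c(0.5, 0.5), c(0.5, 0.5)), 0)
    expect_equal(daDistance(c(1, 0), c(0, 1)), 1)
    expect_equal(daDistance(0.9, 0.6), 1 - (sqrt(0.54) + sqrt(0.04)),
                 tolerance = 1e-12)
    expect_error(daDistance(c(0.1, 0.2), 0.3), "same locus set")
    # invariance under consistent I <-> D relabelling
    set.seed(2)
    x <- runif(20, 0.1, 0.9); y <- runif(20, 0.1, 0.9)
    expect_equal(daDistance(x, y), daDistance(1 - x, 1 - y),
                 tolerance = 1e-12)
})

test_that("informativeness for assignment matches the closed form", {
    f2 <- matrix(c(1, 0), 1, 2, dimnames = list("L1", c("A", "B")))
    expect_equal(informativenessIn(f2)$In, log(2), tolerance = 1e-12)
    same <- matrix(0.4, 3, 4, dimnames = list(paste0("L", 1:3),
                                              paste0("P", 1:4)))
    expect_equal(informativenessIn(same)$In, rep(0, 3), tolerance = 1e-12)
    # K = 2, p = (0.9, 0.1): direct evaluation of the formula
    p <- c(0.9, 0.1); pb <- 0.5
    direct <- sum(vapply(list(p, 1 - p), function(al)
        -mean(al) * log(mean(al)) + mean(al * log(al)), 0))
    got <- informativenessIn(matrix(p, 1, 2,
                dimnames = list("L1", c("A", "B"))))$In
    expect_equal(got, direct, tolerance = 1e-12)
    expect_lte(got, log(2))
    # invariant to I <-> D relabelling applied across populations
    set.seed(14)
    m <- matrix(runif(12, 0.05, 0.95), 3, 4,
                dimnames = list(paste0("L", 1:3), paste0("P", 1:4)))
    expect_equal(informativenessIn(m)$In, informativenessIn(1 - m)$In,
                 tolerance = 1e-12)
})

test_that("the W&C estimator recovers the Balding-Nichols parameter", {
    set.seed(41)
    Ftrue <- 0.10
    L <- 100; npop <- 5; n <- 100
    pAnc <- runif(L, 0.3, 0.7)
    d <- NULL
    for (k in seq_len(npop)) {
        pk <- bnFrequencies(pAnc, Ftrue)
        d <- cbind(d, vapply(seq_len(n), function(i) rbinom(L, 2, pk),
                             integer(L)))
    }
    rownames(d) <- sprintf("L%03d", seq_len(L))
    colnames(d) <- sprintf("s%04d", seq_len(ncol(d)))
    g <- DipGenotypes(d, population = rep(paste0("P", 1:npop), each = n),
                      continent = rep("C", npop * n))
    comp <- dipkit:::.wcComponents(g)
    theta <- sum(comp$a) / sum(comp$a + comp$b + comp$c)
    # jackknife-over-loci standard error
    thJack <- vapply(seq_len(L), function(l)
        sum(comp$a[-l]) / sum(comp$a[-l] + comp$b[-l] + comp$c[-l]), 0)
    se <- sqrt((L - 1) / L * sum((thJack - mean(thJack))^2))
    expect_lt(abs(theta - Ftrue), 3 * se)
})

test_that("AMOVA partitions variance sensibly in degenerate designs", {
    # two populations fixed for opposite alleles: ~100% among populations
    m <- rbind(L1 = rep(c(0L, 2L), each = 10))
    colnames(m) <- sprintf("s%02d", 1:20)
    g <- DipGenotypes(m, population = rep(c("A", "B"), each = 10),
                      continent = rep("C", 20))
    a <- amova(g)
    expect_identical(a$design, "two-level")
    expect_gt(a$percentages[["among_pops"]], 95)
    expect_equal(sum(a$percentages), 100, tolerance = 1e-6)
    expect_error(amova(DipGenotypes(m, population = rep("A", 20),
                                    continent = rep("C", 20))),
                 "at least two populations")
    # three-level design where every group holds one population: the
    # among-pops-in-groups level is empty, components stay finite
    g2 <- DipGenotypes(m, population = rep(c("A", "B"), each = 10),
                       continent = rep(c("x", "y"), each = 10))
    expect_warning(a2 <- amova(g2), "single population")
    expect_true(all(is.finite(a2$components)))
    expect_equal(a2$components[["among_pops_within_groups"]], 0)
    expect_gt(a2$percentages[["among_groups"]], 95)
})

test_that("two-level AMOVA Phi_ST is consistent with pairwise theta", {
    ds <- makeDataset(syntheticConfig(
        nLoci = 60, continents = c(C = 0.05),
        popsPerContinent = c(C = 2L), nSamples = 100), seed = 8)
    g <- ds$genotypes
    a <- amova(g)
    expect_equal(unname(a$phi[["phi_ST"]]), wcFst(g), tolerance = 0.01)
})

test_that("AMOVA recovers the generative continental differentiation", {
    ds <- makeDataset(syntheticConfig(
        nLoci = 57, continents = c(A = 0.12, B = 0.12, C = 0.12,
                                   D = 0.12, E = 0.12),
        popsPerContinent = c(A = 2L, B = 2L, C = 2L, D = 2L, E = 2L),
        fstWithinContinent = 0.002, nSamples = 50), seed = 10)
    a <- amova(ds$genotypes)
    expect_identical(a$design, "three-level")
    expect_equal(sum(a$percentages), 100, tolerance = 1e-6)
    expect_gte(a$components[["within_pops"]], 0)
    # among-group percentage tracks the generative FST of 12%
    expect_lt(abs(a$percentages[["among_groups"]] - 12), 4)
})
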