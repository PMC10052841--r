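test_that("PCA coordinates reproduce the covariance eigendecomposition", {
    set.seed(6)
    m <- matrix(rnorm(15), 5, 3)
    pc <- dipPca(m, nComponents = 3)
    ev <- eigen(stats::cov(m), symmetric = TRUE)
    expect_equal(pc$explained, 100 * ev$values / sum(ev$values),
                 tolerance = 1e-9)
    ctr <- scale(m, scale = FALSE)
    for (j in 1:2) {   # coordinates match projections up to the fixed sign
        proj <- ctr %*% ev$vectors[, j]
        expect_equal(abs(pc$coordinates[, j]), abs(drop(proj)),
                     tolerance = 1e-9)
    }
    expect_true(all(diff(pc$explained) <= 1e-12))
    expect_lte(sum(pc$explained), 100 + 1e-9)
})

test_that("rank-1 data load entirely on PC1 and constant data warn", {
    m <- outer(1:6, c(1, 2, 3))
    pc <- dipPca(m, nComponents = 3)
    expect_equal(pc$explained[1], 100, tolerance = 1e-9)
    expect_warning(z <- dipPca(matrix(1, 4, 3)), "constant")
    expect_true(all(z$coordinates == 0))
})

test_that("PCA sign convention makes output deterministic", {
    set.seed(30)
    m <- matrix(rnorm(40), 8, 5)
    p1 <- dipPca(m)
    p2 <- dipPca(m[sample(8), ])   # row permutation
    expect_equal(sort(p1$coordinates[, 1]), sort(p2$coordinates[, 1]),
                 tolerance = 1e-9)
    expect_equal(p1$explained, p2$explained, tolerance = 1e-9)
    # first nonzero loading entry is non-negative
    expect_gte(p1$loadings[which(p1$loadings[, 1] != 0)[1], 1], 0)
})

test_that("individual-level PCA mean-imputes missing dosages", {
    g <- toyGenotypes(c(0L, 1L, 2L, NA), c(2L, NA, 0L, 1L),
                      c(1L, 1L, 0L, 2L))
    pc <- dipPca(g, nComponents = 2)
    expect_false(any(is.na(pc$coordinates)))
    expect_identical(pc$level, "individual")
})

test_that("classical MDS recovers a planted planar configuration", {
    set.seed(15)
    X <- cbind(runif(6, -2, 2), runif(6, -2, 2))
    D <- as.matrix(dist(X))
    dimnames(D) <- list(letters[1:6], letters[1:6])
    out <- classicalMds(D, dims = 2)
    expect_lt(procrustesResidual(X, out$points), 1e-9)
})

test_that("MDS degenerate inputs: zero matrix and duplicated points", {
    z <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
    expect_warning(out <- classicalMds(z, dims = 2), "zero-padded")
    expect_true(all(out$points == 0))
    X <- rbind(c(0, 0), c(1, 0), c(0, 1), c(0, 1))   # point 4 duplicates 3
    D <- as.matrix(dist(X))
    dimnames(D) <- list(paste0("p", 1:4), paste0("p", 1:4))
    out <- classicalMds(D, dims = 2)
    expect_equal(out$points[3, ], out$points[4, ], tolerance = 1e-9)
})

test_that("MDS on PCA-score distances reproduces the scores", {
    set.seed(26)
    m <- matrix(rnorm(50), 10, 5)
    pc <- dipPca(m, nComponents = 5)
    D <- as.matrix(dist(pc$coordinates))
    out <- classicalMds(D, dims = 5)
    expect_lt(procrustesResidual(pc$coordinates, out$points), 1e-8)
})

test_that("NJ exactly recovers planted additive trees", {
    set.seed(44)
    for (i in 1:3) {
        tr <- ape::rtree(7, rooted = FALSE,
                         br = function(n) runif(n, 0.05, 1))
        D <- ape::cophenetic.phylo(tr)
        got <- njTree(D)
        expect_equal(as.numeric(ape::dist.topo(got, tr)), 0)
        cd <- ape::cophenetic.phylo(got)
        expect_equal(cd[rownames(D), colnames(D)], D, tolerance = 1e-8)
    }
})

test_that("3-taxon NJ uses the three-point closed form", {
    D <- matrix(c(0, 5, 9, 5, 0, 8, 9, 8, 0), 3, 3,
                dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
    tr <- njTree(D)
    len <- tr$edge.length[match(1:3, tr$edge[, 2])]
    expect_equal(sort(len), c(2, 3, 6), tolerance = 1e-12)
})

test_that("NJ on an ultrametric matrix matches the UPGMA topology", {
    set.seed(52)
    m <- matrix(rnorm(7 * 4), 7)
    rownames(m) <- paste0("t", 1:7)
    hc <- hclust(dist(m), method = "average")
    D <- cophenetic(hc)
    upg <- ape::as.phylo(hc)
    got <- njTree(as.matrix(D))
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(upg), got)), 0)
})

test_that("NJ edge cases: 2 taxa and negative branch flooring", {
    D <- matrix(c(0, 3, 3, 0), 2, 2, dimnames = list(c("a", "b"),
                                                     c("a", "b")))
    expect_warning(tr <- njTree(D), "single-edge")
    expect_identical(sort(tr$tip.label), c("a", "b"))
    expect_equal(sum(tr$edge.length), 3)
    # a distance matrix violating additivity can force negative branches
    D4 <- matrix(c(0, 1, 1, 1,
                   1, 0, 1, 1,
                   1, 1, 0, 0.1,
                   1, 1, 0.1, 0), 4, 4,
                 dimnames = list(letters[1:4], letters[1:4]))
    tr4 <- njTree(D4)
    expect_true(all(tr4$edge.length >= 0))
})
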