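#' Principal component analysis of genotypes or frequencies
#'
#' Individual-level PCA uses centred, unscaled insertion dosages (missing
#' calls mean-imputed per locus before centring); population-level PCA
#' uses centred insertion frequencies. The sign of each component is fixed
#' so that the first nonzero loading entry is non-negative, making output
#' deterministic.
#'
#' @param x a \linkS4class{DipGenotypes} (individual level) or
#'   \linkS4class{DipFrequencies} (population level), or a plain
#'   items x features matrix.
#' @param nComponents number of components to return (default 10, capped
#'   at the matrix rank bound).
#' @return A list with \code{coordinates} (items x components),
#'   \code{explained} (percentage of total variance per component,
#'   non-increasing), \code{loadings} and \code{level}.
#' @export
dipPca <- function(x, nComponents = 10L) {
    if (is(x, "DipGenotypes")) {
        m <- t(dosage(autosomal(x)))
        m <- .meanImpute(m)
        level <- "individual"
    } else if (is(x, "DipFrequencies")) {
        m <- t(pIns(x))
        level <- "population"
    } else {
        m <- as.matrix(x)
        level <- "matrix"
    }
    if (nrow(m) < 2) stop("need at least two items")
    totVar <- sum(apply(m, 2, stats::var))
    if (totVar == 0) {
        warning("constant matrix: no variance to decompose")
        k <- min(nComponents, ncol(m))
        return(list(coordinates = matrix(0, nrow(m), k,
                        dimnames = list(rownames(m), paste0("PC", seq_len(k)))),
                    explained = rep(0, k), loadings = NULL, level = level))
    }
    pr <- stats::prcomp(m, center = TRUE, scale. = FALSE)
    k <- min(nComponents, ncol(pr$x))
    flip <- vapply(seq_len(k), function(j) {
        v <- pr$rotation[, j]
        nz <- v[v != 0]
        if (length(nz) && nz[1] < 0) -1 else 1
    }, 0)
    coords <- sweep(pr$x[, seq_len(k), drop = FALSE], 2, flip, `*`)
    load <- sweep(pr$rotation[, seq_len(k), drop = FALSE], 2, flip, `*`)
    expl <- 100 * pr$sdev^2 / sum(pr$sdev^2)
    list(coordinates = coords, explained = expl[seq_len(k)],
         loadings = load, level = level)
}

## column-mean imputation of missing dosages
.meanImpute <- function(m) {
    for (j in seq_len(ncol(m))) {
        miss <- is.na(m[, j])
        if (any(miss)) m[miss, j] <- mean(m[, j], na.rm = TRUE)
    }
    m[is.na(m)] <- 0   # all-missing column
    m
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Double-centres the squared distance matrix
#' (\eqn{B = -\tfrac{1}{2} J D^2 J}), eigen-decomposes it, and returns the
#' leading coordinates scaled by the square roots of the positive
#' eigenvalues. If fewer than \code{dims} eigenvalues are positive, the
#' remaining coordinate columns are zero-padded with a warning.
#'
#' @param d a \linkS4class{DipDistance} or symmetric zero-diagonal matrix
#'   (negative entries must be clamped first, see
#'   \code{\link{clampNonNegative}}).
#' @param dims number of output dimensions (default 2).
#' @return A list with \code{points} (items x dims) and \code{eig}
#'   (all eigenvalues of the centred matrix).
#' @export
classicalMds <- function(d, dims = 2L) {
    m <- if (is(d, "DipDistance")) as.matrix(d) else as.matrix(d)
    if (any(m < 0)) stop("negative distances; clamp them first")
    n <- nrow(m)
    J <- diag(n) - matrix(1 / n, n, n)
    B <- -0.5 * J %*% (m^2) %*% J
    e <- eigen((B + t(B)) / 2, symmetric = TRUE)
    pos <- which(e$values > max(e$values, 0) * 1e-12)
    k <- min(dims, length(pos))
    pts <- matrix(0, n, dims,
                  dimnames = list(rownames(m), paste0("Dim", seq_len(dims))))
    if (k > 0)
        pts[, seq_len(k)] <- e$vectors[, pos[seq_len(k)], drop = FALSE] %*%
            diag(sqrt(e$values[pos[seq_len(k)]]), k)
    if (k < dims)
        warning("only ", k, " positive eigenvalues; remaining dimensions ",
                "zero-padded")
    list(points = pts, eig = e$values)
}

#' Neighbour-joining tree from a distance matrix
#'
#' Saitou-Nei neighbour joining (via \code{\link[ape]{nj}}) with negative
#' branch lengths floored at zero (the convention of mainstream tree
#' software); whether any flooring happened is recorded in the
#' \code{"clamped"} attribute of the returned tree.
#'
#' @param d a \linkS4class{DipDistance} or symmetric matrix with at least
#'   3 taxa (2 taxa yield a single-edge tree with a warning).
#' @return An unrooted \code{phylo} object.
#' @export
njTree <- function(d) {
    m <- if (is(d, "DipDistance")) as.matrix(d) else as.matrix(d)
    if (nrow(m) < 2) stop("need at least two taxa")
    if (nrow(m) == 2) {
        warning("2 taxa: returning a single-edge tree")
        tr <- ape::read.tree(text = sprintf("(%s:%.17g,%s:%.17g);",
                                            rownames(m)[1], m[1, 2] / 2,
                                            rownames(m)[2], m[1, 2] / 2))
        attr(tr, "clamped") <- FALSE
        return(tr)
    }
    tr <- ape::nj(stats::as.dist(m))
    neg <- tr$edge.length < 0
    tr$edge.length[neg] <- 0
    attr(tr, "clamped") <- any(neg)
    tr
}
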