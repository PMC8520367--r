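# Tensor representation and SPD dissimilarities.
#
# A single diffusion tensor is a symmetric positive-definite 3x3 matrix,
# passed around either as the matrix itself or as its 6 lower-triangular
# components in the order (Dxx, Dxy, Dyy, Dxz, Dyz, Dzz).

#' Convert between 6-component vectors and 3x3 tensors
#'
#' Components are ordered lower-triangular: Dxx, Dxy, Dyy, Dxz, Dyz, Dzz
#' (the common 6-component NIfTI convention). The reconstructed matrix is
#' symmetric by construction.
#'
#' @param v numeric vector of 6 components.
#' @return \code{tensorFromComponents}: a symmetric 3x3 matrix.
#' @examples
#' tensorFromComponents(c(1, 0, 1, 0, 0, 1))  # identity
#' @export
tensorFromComponents <- function(v) {
    stopifnot(length(v) == 6L)
    matrix(c(v[1], v[2], v[4],
             v[2], v[3], v[5],
             v[4], v[5], v[6]), 3L, 3L)
}

#' @rdname tensorFromComponents
#' @param m symmetric 3x3 matrix.
#' @return \code{tensorComponents}: the 6 lower-triangular components.
#' @export
tensorComponents <- function(m) {
    stopifnot(is.matrix(m), all(dim(m) == 3L))
    c(m[1, 1], m[2, 1], m[2, 2], m[3, 1], m[3, 2], m[3, 3])
}

asTensorMatrix <- function(t) {
    if (is.matrix(t)) t else tensorFromComponents(t)
}

#' Check that a tensor is symmetric positive-definite
#'
#' @param t a 3x3 matrix or 6-component vector.
#' @param tol positive tolerance; the tensor is valid iff its smallest
#'   eigenvalue exceeds \code{tol}. Default 1e-10 (tensors near the SPD
#'   boundary are rejected, not repaired).
#' @return \code{TRUE} or \code{FALSE}.
#' @examples
#' validateSPD(diag(3))                              # TRUE
#' validateSPD(c(1, 0, 1, 0, 0, -1))                 # FALSE
#' @export
validateSPD <- function(t, tol = 1e-10) {
    m <- asTensorMatrix(t)
    if (!all(is.finite(m)))
        stop("invalid input: tensor has non-finite components")
    if (max(abs(m - t(m))) > 1e-8 * max(1, max(abs(m))))
        stop("invalid input: tensor matrix is not symmetric")
    m <- (m + t(m)) / 2   # absorb floating-point asymmetry
    min(eigen(m, symmetric = TRUE, only.values = TRUE)$values) > tol
}

# Spectral matrix log / exp for symmetric matrices.
spdLogm <- function(m) {
    e <- eigen(m, symmetric = TRUE)
    e$vectors %*% (log(e$values) * t(e$vectors))
}

symExpm <- function(m) {
    e <- eigen(m, symmetric = TRUE)
    e$vectors %*% (exp(e$values) * t(e$vectors))
}

# Isometric embedding of a symmetric 3x3 matrix into R^6: Euclidean distance
# between embeddings equals the Frobenius distance between matrices
# (off-diagonals weighted by sqrt(2)).
SQRT2 <- sqrt(2)
symEmbed <- function(m) {
    c(m[1, 1], m[2, 2], m[3, 3],
      SQRT2 * m[2, 1], SQRT2 * m[3, 1], SQRT2 * m[3, 2])
}

#' Dissimilarity between two diffusion tensors
#'
#' Quantifies how different the diffusion characteristics of two voxels are:
#' 0 if and only if the tensors are equal, symmetric, and growing without
#' bound as either tensor approaches singularity (for the log-based metrics).
#' The default is the log-Euclidean distance
#' \deqn{d(A, B) = \lVert \log A - \log B \rVert_F,}
#' the Frobenius norm of the difference of matrix logarithms. The metric is
#' a pluggable strategy: \code{"frobenius"} gives the flat distance
#' \eqn{\lVert A - B\rVert_F} and \code{"affineInvariant"} the Riemannian
#' distance \eqn{\lVert \log(A^{-1/2} B A^{-1/2}) \rVert_F}. The chosen name
#' is recorded in every segmentation output.
#'
#' @param a,b SPD tensors (3x3 matrices or 6-component vectors).
#' @param metric one of \code{"logEuclidean"}, \code{"frobenius"},
#'   \code{"affineInvariant"}.
#' @param tol SPD tolerance forwarded to \code{\link{validateSPD}}.
#' @return A nonnegative dissimilarity.
#' @examples
#' tensorDissimilarity(diag(3), exp(1) * diag(3))  # sqrt(3)
#' tensorDissimilarity(diag(3), diag(c(4, 1, 1)))  # log(4)
#' @export
tensorDissimilarity <- function(a, b, metric = "logEuclidean", tol = 1e-10) {
    metric <- match.arg(metric, TENSOR_METRICS)
    a <- asTensorMatrix(a)
    b <- asTensorMatrix(b)
    if (!validateSPD(a, tol) || !validateSPD(b, tol))
        stop("invalid input: tensorDissimilarity requires SPD tensors ",
             "(smallest eigenvalue must exceed ", tol, ")")
    switch(metric,
        logEuclidean = {
            d <- spdLogm(a) - spdLogm(b)
            sqrt(sum(d * d))
        },
        frobenius = {
            d <- a - b
            sqrt(sum(d * d))
        },
        affineInvariant = {
            ev <- eigen(solve(a, b), only.values = TRUE)$values
            sqrt(sum(log(Re(ev))^2))
        })
}

# Feature embedding for a whole field: a matrix with one row per voxel
# (linear index order) in which Euclidean row distance equals the configured
# feature dissimilarity. NULL when no such embedding exists
# (affine-invariant metric), in which case callers fall back to pairwise
# evaluation via the returned pairDist closure.
#
# For tensor fields every in-mask voxel is SPD-validated here; the first
# failing voxel is named in the error, per the segmentation contract.
fieldFeatures <- function(field, metric, tol = 1e-10) {
    if (is(field, "ScalarImage")) {
        v <- as.vector(field@values)
        if (!all(is.finite(v[field@mask])))
            stop("invalid input: non-finite intensity inside the mask")
        emb <- matrix(v, ncol = 1L)
        return(list(emb = emb,
                    pairDist = function(i, j) abs(v[i] - v[j])))
    }
    stopifnot(is(field, "TensorField"))
    metric <- match.arg(metric, TENSOR_METRICS)
    gd <- dim(field@mask)
    n <- prod(gd)
    comp <- matrix(field@tensors, nrow = n)   # n x 6, lower-tri order
    inmask <- which(field@mask)
    mats <- vector("list", n)
    for (i in inmask) {
        m <- tensorFromComponents(comp[i, ])
        if (!all(is.finite(m)) ||
            min(eigen(m, symmetric = TRUE, only.values = TRUE)$values) <= tol) {
            pos <- paste(arrayInd(i, gd), collapse = ",")
            stop("invalid input: tensor at voxel (", pos,
                 ") is not SPD (index ", i, ")")
        }
        mats[[i]] <- m
    }
    if (metric == "affineInvariant") {
        one <- function(i, j) {
            ev <- eigen(solve(mats[[i]], mats[[j]]), only.values = TRUE)$values
            sqrt(sum(log(Re(ev))^2))
        }
        return(list(emb = NULL,
                    pairDist = function(i, j) mapply(one, i, j)))
    }
    emb <- matrix(NA_real_, n, 6L)
    for (i in inmask) {
        m <- if (metric == "logEuclidean") spdLogm(mats[[i]]) else mats[[i]]
        emb[i, ] <- symEmbed(m)
    }
    list(emb = emb, pairDist = function(i, j)
        sqrt(rowSums((emb[i, , drop = FALSE] - emb[j, , drop = FALSE])^2)))
}
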