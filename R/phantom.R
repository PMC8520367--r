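# Synthetic phantoms with known ground truth, plus Dice scoring.
#
# The geometry emulates the imaging picture that motivates the package --
# bilateral, symmetric, ovoid periventricular lesions -- as two elliptical
# inclusions mirrored about the midline column. No radiological realism is
# claimed; the phantoms exist to exercise and score the segmentation.

# Run expr under a private, fully specified RNG state so phantoms are
# bit-identical across runs and platforms for a fixed seed.
withPhantomRNG <- function(seed, expr) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
             sample.kind = "Rejection")
    expr
}

# Logical lesion mask of both mirrored ellipses; errors if they overlap.
lesionMask <- function(spec) {
    d <- spec@dim
    R <- matrix(seq_len(d[1]), d[1], d[2])
    C <- matrix(seq_len(d[2]), d[1], d[2], byrow = TRUE)
    inEllipse <- function(r0, c0)
        ((R - r0) / spec@lesionAxes[1])^2 +
        ((C - c0) / spec@lesionAxes[2])^2 <= 1
    m1 <- inEllipse(spec@lesionCenter[1], spec@lesionCenter[2])
    m2 <- inEllipse(spec@lesionCenter[1], d[2] + 1 - spec@lesionCenter[2])
    if (any(m1 & m2))
        stop("specification error: mirrored lesion ellipses overlap")
    m1 | m2
}

#' Generate a scalar phantom with ground truth
#'
#' A piecewise-constant image (background level outside, lesion level inside
#' the two mirrored ellipses) with optional additive Gaussian noise.
#' Reproducible: a fixed spec seed yields a bit-identical phantom.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @return A list with \code{image} (a \linkS4class{ScalarImage}) and
#'   \code{truth} (logical lesion mask).
#' @examples
#' p <- makeScalarPhantom(phantomSpec(noiseSD = 0))
#' length(unique(as.vector(imageValues(p$image))))  # 2
#' @export
makeScalarPhantom <- function(spec) {
    truth <- lesionMask(spec)
    vals <- array(spec@backgroundLevel, spec@dim)
    vals[truth] <- spec@lesionLevel
    if (spec@noiseSD > 0)
        vals <- vals + withPhantomRNG(spec@seed,
            array(rnorm(prod(spec@dim), 0, spec@noiseSD), spec@dim))
    list(image = scalarImage(vals), truth = truth)
}

#' Generate a diffusion-tensor phantom with ground truth
#'
#' Background voxels carry the isotropic tensor
#' \code{diag(backgroundEigenvalues)}; lesion voxels the anisotropic tensor
#' \code{diag(lesionEigenvalues)} with principal axis along x. Noise is
#' applied in log-tensor space: the six lower-triangular components of the
#' matrix logarithm receive iid Gaussian perturbations and the result is
#' mapped back by the matrix exponential, so every generated tensor is SPD
#' by construction at any noise level (no clipping or repair needed).
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @return A list with \code{field} (a \linkS4class{TensorField}) and
#'   \code{truth} (logical lesion mask).
#' @export
makeTensorPhantom <- function(spec) {
    truth <- lesionMask(spec)
    n <- prod(spec@dim)
    logBg <- log(spec@backgroundEigenvalues)
    logLes <- log(spec@lesionEigenvalues)
    # 6 log-components per voxel, lower-tri order (diagonal entries at 1,3,6)
    L <- matrix(0, n, 6L)
    L[, c(1L, 3L, 6L)] <- matrix(logBg, n, 3L, byrow = TRUE)
    les <- which(truth)
    L[les, c(1L, 3L, 6L)] <- matrix(logLes, length(les), 3L, byrow = TRUE)
    if (spec@noiseSD > 0) {
        L <- L + withPhantomRNG(spec@seed,
            matrix(rnorm(6L * n, 0, spec@noiseSD), n, 6L))
        comp <- t(vapply(seq_len(n), function(i)
            tensorComponents(symExpm(tensorFromComponents(L[i, ]))),
            numeric(6)))
    } else {
        comp <- exp(L)   # diagonal log-tensors: exp acts componentwise
        comp[, c(2L, 4L, 5L)] <- 0
    }
    list(field = tensorField(array(comp, c(spec@dim, 6L))), truth = truth)
}

#' Default seed mask for a phantom
#'
#' Deterministic sparse seeds for the reference task: one target seed at the
#' centre of each mirrored lesion, background seeds at the four grid corners
#' and the midline centre voxel.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @return A \linkS4class{SeedSets}.
#' @export
phantomSeeds <- function(spec) {
    d <- spec@dim
    ctr <- round(spec@lesionCenter)
    at <- function(r, c) (c - 1L) * d[1] + r
    target <- c(at(ctr[1], ctr[2]), at(ctr[1], d[2] + 1L - ctr[2]))
    bg <- c(at(1L, 1L), at(d[1], 1L), at(1L, d[2]), at(d[1], d[2]),
            at(round(d[1] / 2), round(d[2] / 2)))
    seedSets(target, bg, d)
}

#' Dice overlap coefficient between two masks
#'
#' \eqn{2 |A \cap B| / (|A| + |B|)}; defined as 1 when both masks are empty.
#'
#' @param a,b logical (or 0/1) arrays of identical dimensions.
#' @return A value in [0, 1].
#' @examples
#' diceCoefficient(matrix(c(TRUE, TRUE, FALSE, FALSE), 2),
#'                 matrix(c(TRUE, FALSE, TRUE, FALSE), 2))  # 0.5
#' @export
diceCoefficient <- function(a, b) {
    if (!identical(dim(a), dim(b)))
        stop("invalid input: mask shapes differ")
    a <- as.vector(a) > 0 & !is.na(a)
    b <- as.vector(b) > 0 & !is.na(b)
    denom <- sum(a) + sum(b)
    if (denom == 0) return(1)
    2 * sum(a & b) / denom
}
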