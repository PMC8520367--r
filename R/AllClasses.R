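#' @import methods
NULL

TENSOR_METRICS <- c("logEuclidean", "frobenius", "affineInvariant")

#' Scalar image container
#'
#' A 2D or 3D grid of real intensities with an in-mask indicator. Voxels
#' outside the mask take no part in segmentation: they contribute no graph
#' node, no seed and no neighbour link.
#'
#' @slot values numeric array (2D or 3D) of intensities; must be finite on
#'   every in-mask voxel.
#' @slot mask logical array of the same dimensions; \code{TRUE} marks voxels
#'   that participate.
#' @export
setClass("ScalarImage", representation(values = "array", mask = "array"))

setValidity("ScalarImage", function(object) {
    if (!identical(dim(object@values), dim(object@mask)))
        return("values and mask must have identical dimensions")
    nd <- length(dim(object@values))
    if (nd < 2L || nd > 3L) return("images must be 2D or 3D")
    if (!is.logical(object@mask)) return("mask must be logical")
    if (anyNA(object@mask)) return("mask must not contain NA")
    v <- object@values[object@mask]
    if (length(v) && !all(is.finite(v)))
        return("in-mask intensities must be finite")
    TRUE
})

#' Diffusion-tensor field container
#'
#' One symmetric 3x3 diffusion tensor per voxel, stored as six components in
#' lower-triangular order (Dxx, Dxy, Dyy, Dxz, Dyz, Dzz) along the trailing
#' array dimension -- the common 6-component NIfTI convention. Validity of
#' the container checks shape only; SPD validation of individual tensors
#' happens at use sites (see \code{\link{validateSPD}}), where failures are
#' reported per voxel.
#'
#' @slot tensors numeric array of dimension \code{c(gridDim, 6)} where
#'   \code{gridDim} is 2D or 3D.
#' @slot mask logical array of dimension \code{gridDim}.
#' @export
setClass("TensorField", representation(tensors = "array", mask = "array"))

setValidity("TensorField", function(object) {
    d <- dim(object@tensors)
    if (d[length(d)] != 6L)
        return("trailing dimension of tensors must hold 6 components")
    gd <- d[-length(d)]
    if (length(gd) < 2L || length(gd) > 3L)
        return("tensor grid must be 2D or 3D")
    if (!identical(as.integer(gd), as.integer(dim(object@mask))))
        return("mask dimensions must match the tensor grid")
    if (!is.logical(object@mask) || anyNA(object@mask))
        return("mask must be logical without NA")
    TRUE
})

#' Seed sets for interactive segmentation
#'
#' The user-marked partition of voxels into target seeds (the set O),
#' background seeds (B) and the unknown remainder (U). Indices are 1-based
#' linear indices into the image array (R column-major order).
#'
#' @slot target integer vector of target-seed voxel indices.
#' @slot background integer vector of background-seed voxel indices.
#' @slot dim integer vector, the grid dimensions the indices refer to.
#' @export
setClass("SeedSets",
    representation(target = "integer", background = "integer", dim = "integer"))

setValidity("SeedSets", function(object) {
    n <- prod(object@dim)
    idx <- c(object@target, object@background)
    if (length(idx) && (min(idx) < 1L || max(idx) > n))
        return("seed indices out of range for the stated dimensions")
    if (anyDuplicated(object@target) || anyDuplicated(object@background))
        return("duplicate indices within a seed set")
    if (length(intersect(object@target, object@background)))
        return("target and background seed sets must be disjoint")
    TRUE
})

#' Energy parameters for the seeded-cut objective
#'
#' @slot alpha expansion factor in (0,1) weighting the regional term against
#'   the boundary term: E = alpha * regional + (1-alpha) * boundary.
#' @slot sigma boundary-term scale of the Gaussian kernel
#'   \code{exp(-d^2/(2 sigma^2))}; \code{NA} requests the data-adaptive
#'   default (mean neighbour-pair dissimilarity).
#' @slot hardConstraintWeight the large regional penalty K charged for
#'   flipping a seed; \code{NA} requests the per-instance default that
#'   guarantees seeds are never flipped by a minimum cut.
#' @slot metric tensor dissimilarity name: \code{"logEuclidean"} (default),
#'   \code{"frobenius"} or \code{"affineInvariant"}. Ignored for scalar
#'   images, where the feature distance is absolute intensity difference.
#' @export
setClass("EnergyParams",
    representation(alpha = "numeric", sigma = "numeric",
                   hardConstraintWeight = "numeric", metric = "character"))

setValidity("EnergyParams", function(object) {
    a <- object@alpha
    if (length(a) != 1L || !is.finite(a) || a <= 0 || a >= 1)
        return("alpha must lie strictly inside (0, 1)")
    s <- object@sigma
    if (length(s) != 1L || (!is.na(s) && (!is.finite(s) || s <= 0)))
        return("sigma must be a positive number or NA (data-adaptive)")
    k <- object@hardConstraintWeight
    if (length(k) != 1L || (!is.na(k) && (!is.finite(k) || k <= 0)))
        return("hardConstraintWeight must be positive or NA (per-instance)")
    if (length(object@metric) != 1L || !object@metric %in% TENSOR_METRICS)
        return(sprintf("metric must be one of: %s",
                       paste(TENSOR_METRICS, collapse = ", ")))
    TRUE
})

#' Per-voxel effective distances to the seed sets
#'
#' Average dissimilarity from each voxel to the target seed set and to the
#' background seed set, both computed with the same metric. Entries are NA
#' on masked-out voxels.
#'
#' @slot toTarget numeric vector over linear voxel indices (D_i to O).
#' @slot toBackground numeric vector over linear voxel indices (D_i to B).
#' @slot metric the dissimilarity used.
#' @export
setClass("EffectiveDistances",
    representation(toTarget = "numeric", toBackground = "numeric",
                   metric = "character"))

#' Capacitated s/t flow graph
#'
#' Non-terminal nodes are numbered 1..nNodes; the source terminal (target
#' region side) is nNodes+1 and the sink terminal (background side) is
#' nNodes+2. Arcs are directed; neighbour links appear once per direction
#' with equal capacity.
#'
#' @slot nNodes number of non-terminal nodes.
#' @slot from,to integer arc endpoints.
#' @slot capacity nonnegative finite arc capacities.
#' @slot nodeVoxel linear voxel index backing each node (empty when the
#'   graph was not built from an image).
#' @export
setClass("FlowGraph",
    representation(nNodes = "integer", from = "integer", to = "integer",
                   capacity = "numeric", nodeVoxel = "integer"))

setValidity("FlowGraph", function(object) {
    m <- length(object@from)
    if (length(object@to) != m || length(object@capacity) != m)
        return("from, to and capacity must have equal length")
    hi <- object@nNodes + 2L
    if (m && (min(object@from, object@to) < 1L || max(object@from, object@to) > hi))
        return("arc endpoints out of range")
    if (any(object@from == object@to)) return("self-loops are not allowed")
    if (m && (!all(is.finite(object@capacity)) || any(object@capacity < 0)))
        return("capacities must be finite and nonnegative")
    if (length(object@nodeVoxel) &&
        length(object@nodeVoxel) != object@nNodes)
        return("nodeVoxel must map every non-terminal node")
    TRUE
})

#' Result of a seeded segmentation
#'
#' @slot labeling integer array over the grid: 1 = target, 0 = background,
#'   NA = masked out.
#' @slot energy total objective E of the returned labeling, recomputed from
#'   the labeling itself.
#' @slot flowValue the max-flow / min-cut value; equals \code{energy} (up to
#'   rounding) whenever the seeds are respected.
#' @slot params the fully resolved \code{EnergyParams} actually used (sigma
#'   and K filled in).
#' @slot seedCounts named integer vector (target, background).
#' @export
setClass("SegmentationResult",
    representation(labeling = "array", energy = "numeric",
                   flowValue = "numeric", params = "EnergyParams",
                   seedCounts = "integer"))

#' Synthetic phantom specification
#'
#' Describes a 2D slice carrying two lesions mirrored about the midline
#' column -- emulating the bilateral, symmetric, periventricular lesion
#' geometry seen in delayed post-hypoxic leukoencephalopathy -- on a uniform
#' background. One ellipse is given; the second is its exact mirror.
#'
#' @slot dim grid dimensions (rows, cols).
#' @slot lesionCenter (row, col) centre of the first ellipse; the mirror sits
#'   at column \code{dim[2] + 1 - col}.
#' @slot lesionAxes (row semi-axis, col semi-axis) in voxels.
#' @slot backgroundLevel,lesionLevel scalar-phantom intensities.
#' @slot backgroundEigenvalues,lesionEigenvalues tensor-phantom eigenvalues
#'   (mm^2/s), principal axis along x; all strictly positive.
#' @slot noiseSD noise standard deviation: additive on intensities for the
#'   scalar phantom, applied to matrix-log components for the tensor phantom
#'   (so generated tensors stay SPD by construction).
#' @slot seed RNG seed for reproducible phantoms.
#' @export
setClass("PhantomSpec",
    representation(dim = "integer", lesionCenter = "numeric",
                   lesionAxes = "numeric", backgroundLevel = "numeric",
                   lesionLevel = "numeric", backgroundEigenvalues = "numeric",
                   lesionEigenvalues = "numeric", noiseSD = "numeric",
                   seed = "integer"))

setValidity("PhantomSpec", function(object) {
    if (length(object@dim) != 2L || any(object@dim < 4L))
        return("phantom grid must be 2D and at least 4x4")
    if (length(object@lesionCenter) != 2L || length(object@lesionAxes) != 2L)
        return("lesionCenter and lesionAxes must each have length 2")
    if (any(object@lesionAxes <= 0))
        return("lesion semi-axes must be positive")
    lo <- object@lesionCenter - object@lesionAxes
    hi <- object@lesionCenter + object@lesionAxes
    if (any(lo < 1) || any(hi > object@dim))
        return("lesion ellipse must fit inside the grid")
    mc <- object@dim[2L] + 1 - object@lesionCenter[2L]
    if (mc - object@lesionAxes[2L] < 1 || mc + object@lesionAxes[2L] > object@dim[2L])
        return("mirrored lesion ellipse must fit inside the grid")
    if (length(object@backgroundEigenvalues) != 3L ||
        length(object@lesionEigenvalues) != 3L)
        return("tensor eigenvalue sets must have length 3")
    if (any(object@backgroundEigenvalues <= 0) ||
        any(object@lesionEigenvalues <= 0))
        return("tensor eigenvalues must be strictly positive")
    if (!is.finite(object@noiseSD) || object@noiseSD < 0)
        return("noiseSD must be a nonnegative number")
    TRUE
})

#' Group summary (mean, SD, n)
#'
#' The printed per-arm cell of a clinical comparison table: sample mean,
#' sample standard deviation and group size.
#'
#' @slot mean sample mean (variable units).
#' @slot sd sample standard deviation, positive.
#' @slot n group size, at least 2.
#' @export
setClass("GroupSummary",
    representation(mean = "numeric", sd = "numeric", n = "integer"))

setValidity("GroupSummary", function(object) {
    if (length(object@mean) != 1L || !is.finite(object@mean))
        return("mean must be a single finite number")
    if (length(object@sd) != 1L || !is.finite(object@sd) || object@sd <= 0)
        return("sd must be a single positive number")
    if (length(object@n) != 1L || is.na(object@n) || object@n < 2L)
        return("n must be an integer >= 2")
    TRUE
})

## ---- constructors ----------------------------------------------------------

#' Create a ScalarImage
#'
#' @param values numeric array or matrix of intensities.
#' @param mask optional logical array; default marks every finite voxel
#'   in-mask.
#' @return A \linkS4class{ScalarImage}.
#' @examples
#' img <- scalarImage(matrix(0, 4, 4))
#' @export
scalarImage <- function(values, mask = NULL) {
    values <- as.array(values)
    storage.mode(values) <- "double"
    if (is.null(mask)) mask <- array(is.finite(values), dim(values))
    new("ScalarImage", values = values, mask = as.array(mask))
}

#' Create a TensorField
#'
#' @param tensors numeric array with trailing dimension 6 (lower-triangular
#'   components Dxx, Dxy, Dyy, Dxz, Dyz, Dzz).
#' @param mask optional logical array over the grid; default all in-mask.
#' @return A \linkS4class{TensorField}.
#' @export
tensorField <- function(tensors, mask = NULL) {
    tensors <- as.array(tensors)
    storage.mode(tensors) <- "double"
    gd <- dim(tensors)[-length(dim(tensors))]
    if (is.null(mask)) mask <- array(TRUE, gd)
    new("TensorField", tensors = tensors, mask = as.array(mask))
}

#' Create SeedSets from index vectors
#'
#' @param target,background linear voxel indices (1-based, column-major).
#' @param dim grid dimensions.
#' @return A \linkS4class{SeedSets}.
#' @seealso \code{\link{readSeedMask}}, \code{\link{seedsFromMask}}
#' @export
seedSets <- function(target, background, dim) {
    new("SeedSets", target = as.integer(sort(unique(target))),
        background = as.integer(sort(unique(background))),
        dim = as.integer(dim))
}

#' Create SeedSets from a label array
#'
#' Labels follow the single-artifact dialect: 0 = unknown, 1 = target seed,
#' 2 = background seed.
#'
#' @param labels integer array with values in \{0, 1, 2\}.
#' @return A \linkS4class{SeedSets}.
#' @export
seedsFromMask <- function(labels) {
    labels <- as.array(labels)
    if (!all(labels %in% c(0, 1, 2)))
        stop("seed label image may only contain 0 (unknown), 1 (target), ",
             "2 (background)")
    seedSets(which(labels == 1), which(labels == 2), dim(labels))
}

#' Create EnergyParams
#'
#' @param alpha expansion factor in (0,1); default 0.5.
#' @param sigma boundary scale; \code{NA} (default) = mean neighbour-pair
#'   dissimilarity of the image being segmented.
#' @param hardConstraintWeight seed penalty K; \code{NA} (default) = computed
#'   per instance so that no minimum cut can flip a seed.
#' @param metric tensor dissimilarity name; see
#'   \code{\link{tensorDissimilarity}}.
#' @return An \linkS4class{EnergyParams}.
#' @examples
#' energyParams(alpha = 0.5, metric = "logEuclidean")
#' @export
energyParams <- function(alpha = 0.5, sigma = NA_real_,
                         hardConstraintWeight = NA_real_,
                         metric = "logEuclidean") {
    new("EnergyParams", alpha = as.numeric(alpha), sigma = as.numeric(sigma),
        hardConstraintWeight = as.numeric(hardConstraintWeight),
        metric = metric)
}

#' Create a GroupSummary
#'
#' @param mean,sd,n sample mean, standard deviation (> 0) and size (>= 2).
#' @return A \linkS4class{GroupSummary}.
#' @examples
#' groupSummary(9.43, 2.25, 36)
#' @export
groupSummary <- function(mean, sd, n) {
    new("GroupSummary", mean = as.numeric(mean), sd = as.numeric(sd),
        n = as.integer(n))
}

#' Create a PhantomSpec
#'
#' Defaults describe the package's reference task: a 64x64 slice with two
#' mirrored elliptical lesions (semi-axes 5 rows x 8 columns, centres at
#' columns 20 and 45), isotropic background tensors diag(1,1,1)e-3 mm^2/s,
#' anisotropic lesion tensors diag(1.8,0.6,0.6)e-3 with principal axis along
#' x, and noise SD 0.05 (log-tensor units for the tensor phantom, intensity
#' units for the scalar one) -- nontrivial but solvable with sparse seeds.
#'
#' @param dim,lesionCenter,lesionAxes geometry; see \linkS4class{PhantomSpec}.
#' @param backgroundLevel,lesionLevel scalar intensities.
#' @param backgroundEigenvalues,lesionEigenvalues tensor eigenvalues.
#' @param noiseSD noise standard deviation.
#' @param seed RNG seed.
#' @return A \linkS4class{PhantomSpec}.
#' @examples
#' spec <- phantomSpec(noiseSD = 0)
#' @export
phantomSpec <- function(dim = c(64L, 64L), lesionCenter = c(32, 20),
                        lesionAxes = c(5, 8), backgroundLevel = 1,
                        lesionLevel = 2,
                        backgroundEigenvalues = c(1, 1, 1) * 1e-3,
                        lesionEigenvalues = c(1.8, 0.6, 0.6) * 1e-3,
                        noiseSD = 0.05, seed = 42L) {
    new("PhantomSpec", dim = as.integer(dim),
        lesionCenter = as.numeric(lesionCenter),
        lesionAxes = as.numeric(lesionAxes),
        backgroundLevel = as.numeric(backgroundLevel),
        lesionLevel = as.numeric(lesionLevel),
        backgroundEigenvalues = as.numeric(backgroundEigenvalues),
        lesionEigenvalues = as.numeric(lesionEigenvalues),
        noiseSD = as.numeric(noiseSD), seed = as.integer(seed))
}
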