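# Seed sets, effective distances and the four-penalty energy.
#
# The objective over binary labelings x (1 = target, 0 = background) is
#   E(x) = alpha * sum_i R(i, x_i) + (1 - alpha) * sum_{(i,j) in N, x_i != x_j} B(i, j)
# where R is the regional penalty (hard K/0 on seeds, normalised effective
# distances on unknowns) and B the Gaussian boundary penalty.

#' Neighbour pairs of a voxel grid
#'
#' Returns each unordered neighbour pair once as a two-column matrix of
#' linear indices. 2D grids use the 8-neighbourhood; 3D volumes are
#' processed slice-wise by default (\code{"slice8"}) with an opt-in
#' face-adjacent full-3D mode (\code{"full6"}).
#'
#' @param dim grid dimensions (length 2 or 3).
#' @param mask optional logical array; pairs with either voxel masked out are
#'   dropped.
#' @param connectivity \code{"slice8"} or \code{"full6"}.
#' @return Integer matrix with columns \code{i}, \code{j} (always i < j).
#' @examples
#' nrow(neighborPairs(c(2, 2)))  # 6: four edges + two diagonals
#' nrow(neighborPairs(c(1, 3)))  # 2: chain adjacency
#' @export
neighborPairs <- function(dim, mask = NULL,
                          connectivity = c("slice8", "full6")) {
    connectivity <- match.arg(connectivity)
    d <- as.integer(dim)
    if (length(d) == 2L) d <- c(d, 1L)
    stopifnot(length(d) == 3L)
    offsets <- if (connectivity == "slice8")
        list(c(1L, 0L, 0L), c(0L, 1L, 0L), c(1L, 1L, 0L), c(-1L, 1L, 0L))
    else
        list(c(1L, 0L, 0L), c(0L, 1L, 0L), c(0L, 0L, 1L))
    idx <- array(seq_len(prod(d)), d)
    from <- integer(0); to <- integer(0)
    axisRange <- function(extent, shift) {
        lo <- max(1L, 1L - shift); hi <- min(extent, extent - shift)
        if (lo > hi) integer(0) else lo:hi
    }
    for (off in offsets) {
        r <- axisRange(d[1], off[1])
        c_ <- axisRange(d[2], off[2])
        s <- axisRange(d[3], off[3])
        if (!length(r) || !length(c_) || !length(s)) next
        from <- c(from, as.vector(idx[r, c_, s, drop = FALSE]))
        to <- c(to, as.vector(idx[r + off[1], c_ + off[2], s + off[3],
                                  drop = FALSE]))
    }
    if (!is.null(mask)) {
        keep <- mask[from] & mask[to]
        from <- from[keep]; to <- to[keep]
    }
    swap <- from > to
    pairs <- cbind(i = ifelse(swap, to, from), j = ifelse(swap, from, to))
    storage.mode(pairs) <- "integer"
    pairs
}

#' Effective distance from a voxel to a seed set
#'
#' The set-average dissimilarity
#' \deqn{D_i^S = \frac{1}{|S|} \sum_{s \in S} d(f_i, f_s)}
#' between the feature at voxel i and the features at the seed voxels:
#' tensor dissimilarity for tensor fields, absolute intensity difference for
#' scalar images. These are the per-voxel distances to the target set O and
#' background set B that drive the regional term for unknown voxels.
#'
#' @param i linear voxel index.
#' @param seeds non-empty integer vector of seed voxel indices.
#' @param field a \linkS4class{ScalarImage} or \linkS4class{TensorField}.
#' @param metric tensor dissimilarity name (ignored for scalar images).
#' @return Nonnegative mean dissimilarity.
#' @examples
#' img <- scalarImage(matrix(c(5, 3, 9), 1, 3))
#' effectiveDistance(1, c(2, 3), img)  # (2 + 4) / 2 = 3
#' @export
effectiveDistance <- function(i, seeds, field, metric = "logEuclidean") {
    if (!length(seeds))
        stop("configuration error: effective distance needs a non-empty seed set")
    feats <- fieldFeatures(field, metric)
    mean(feats$pairDist(rep.int(as.integer(i), length(seeds)),
                        as.integer(seeds)))
}

# Vectorised effective distances for every in-mask voxel, reusing one field
# embedding. Returns an EffectiveDistances object (NA off-mask).
effectiveDistancesAll <- function(field, seeds, metric = "logEuclidean",
                                  feats = NULL) {
    if (!length(seeds@target) || !length(seeds@background))
        stop("configuration error: both seed sets must be non-empty")
    if (is.null(feats)) feats <- fieldFeatures(field, metric)
    n <- prod(gridDim(field))
    inmask <- which(imageMask(field))
    distTo <- function(set) {
        acc <- numeric(length(inmask))
        if (!is.null(feats$emb)) {
            E <- feats$emb
            for (s in set) {
                diff <- E[inmask, , drop = FALSE] -
                    rep(E[s, ], each = length(inmask))
                acc <- acc + sqrt(rowSums(diff^2))
            }
        } else {
            for (s in set)
                acc <- acc + vapply(inmask, function(i) feats$pairDist(i, s),
                                    numeric(1))
        }
        out <- rep(NA_real_, n)
        out[inmask] <- acc / length(set)
        out
    }
    new("EffectiveDistances", toTarget = distTo(seeds@target),
        toBackground = distTo(seeds@background), metric = metric)
}

#' Regional penalty of assigning a label to a voxel
#'
#' Encodes the first three penalties of the seeded-cut energy. Seeds are hard
#' constraints: a target seed costs 0 when labelled target and the large
#' weight K when labelled background (mirrored for background seeds).
#' Unknown voxels pay their normalised effective distance, so each is pulled
#' toward the closer seed set:
#' \eqn{R(i, \mathrm{target}) = D_i^O / (D_i^O + D_i^B)} and
#' \eqn{R(i, \mathrm{background}) = D_i^B / (D_i^O + D_i^B)}; when both
#' distances are 0 there is no information and both penalties are 0.5.
#'
#' @param i linear voxel index.
#' @param label \code{"target"} or \code{"background"}.
#' @param seeds a \linkS4class{SeedSets}.
#' @param dists an \linkS4class{EffectiveDistances} covering unknown voxels.
#' @param params an \linkS4class{EnergyParams} with a resolved (non-NA)
#'   \code{hardConstraintWeight}.
#' @return Nonnegative penalty; the two labels' penalties sum to 1 on
#'   unknown voxels.
#' @export
regionalPenalty <- function(i, label = c("target", "background"), seeds,
                            dists, params) {
    label <- match.arg(label)
    K <- params@hardConstraintWeight
    if (is.na(K))
        stop("hardConstraintWeight is unresolved; call resolveParams() first")
    if (i %in% seeds@target)
        return(if (label == "target") 0 else K)
    if (i %in% seeds@background)
        return(if (label == "background") 0 else K)
    dO <- dists@toTarget[i]
    dB <- dists@toBackground[i]
    tot <- dO + dB
    if (!is.finite(tot))
        stop("effective distances missing for unknown voxel ", i)
    if (tot == 0) return(0.5)
    if (label == "target") dO / tot else dB / tot
}

#' Boundary penalty between two neighbouring voxels
#'
#' The fourth penalty: the cost of cutting the link between adjacent voxels
#' i and j, \eqn{B(i,j) = \exp(-d(f_i, f_j)^2 / (2\sigma^2))}. It is charged
#' only across label discontinuities and is maximal (1) for identical
#' neighbours, so cuts through homogeneous regions are most expensive.
#'
#' @param i,j linear indices of two neighbouring voxels (checked against
#'   \code{connectivity}).
#' @param field the image.
#' @param params \linkS4class{EnergyParams}; an \code{NA} sigma is resolved
#'   data-adaptively from the field first.
#' @param connectivity neighbourhood system, as in
#'   \code{\link{neighborPairs}}.
#' @return Penalty in (0, 1].
#' @export
boundaryPenalty <- function(i, j, field, params = energyParams(),
                            connectivity = "slice8") {
    d <- gridDim(field)
    ci <- arrayInd(as.integer(i), d)
    cj <- arrayInd(as.integer(j), d)
    delta <- abs(ci - cj)
    ok <- if (connectivity == "full6") sum(delta) == 1L
          else all(delta[, -seq_len(2L), drop = FALSE] == 0L) &&
               all(delta[, 1:2] <= 1L) && any(delta[, 1:2] > 0L)
    if (!ok)
        stop("contract violation: voxels ", i, " and ", j,
             " are not neighbours under ", connectivity)
    params <- resolveParams(params, field, connectivity)
    feats <- fieldFeatures(field, params@metric)
    dist <- feats$pairDist(as.integer(i), as.integer(j))
    exp(-dist^2 / (2 * params@sigma^2))
}

#' Resolve data-adaptive energy parameters
#'
#' Fills the two instance-dependent defaults of \linkS4class{EnergyParams}:
#' \code{sigma} becomes the mean feature dissimilarity over all in-mask
#' neighbour pairs (1 if that mean is 0, i.e. a perfectly uniform image,
#' where the kernel value is 1 regardless), and \code{hardConstraintWeight}
#' becomes \eqn{K = (1 + M)/\alpha} with M the largest per-node sum of
#' incident n-link capacities \eqn{(1-\alpha) B(i,j)} -- so the seed t-link
#' capacity \eqn{\alpha K = 1 + M} strictly exceeds every incident n-link
#' sum and no minimum cut can flip a seed, for any alpha in (0,1).
#'
#' @param params an \linkS4class{EnergyParams}.
#' @param field the image the parameters will be used on.
#' @param connectivity neighbourhood system.
#' @return An \linkS4class{EnergyParams} with sigma and K filled in.
#' @export
resolveParams <- function(params, field, connectivity = "slice8") {
    if (!is.na(params@sigma) && !is.na(params@hardConstraintWeight))
        return(params)
    feats <- fieldFeatures(field, params@metric)
    pairs <- neighborPairs(gridDim(field), imageMask(field), connectivity)
    d <- if (nrow(pairs)) feats$pairDist(pairs[, 1], pairs[, 2]) else numeric(0)
    sigma <- params@sigma
    if (is.na(sigma)) {
        sigma <- if (length(d)) mean(d) else 1
        if (sigma == 0) sigma <- 1
    }
    K <- params@hardConstraintWeight
    if (is.na(K)) {
        w <- (1 - params@alpha) * exp(-d^2 / (2 * sigma^2))
        inc <- c(rowsum(c(w, w), c(pairs[, 1], pairs[, 2])))
        M <- if (length(inc)) max(inc) else 0
        K <- (1 + M) / params@alpha
    }
    energyParams(params@alpha, sigma, K, params@metric)
}

#' Total seeded-cut energy of a labeling
#'
#' Evaluates
#' \deqn{E = \alpha \sum_i R(i, x_i) + (1-\alpha)
#'   \sum_{(i,j) \in N,\, x_i \neq x_j} B(i, j)}
#' for an arbitrary labeling. Labelings that violate a hard seed constraint
#' are permitted -- each violation simply scores K -- so optimality can be
#' probed by exhaustive enumeration.
#'
#' @param labeling integer/logical array over the grid: 1 = target,
#'   0 = background; masked voxels may be NA.
#' @param field the image.
#' @param seeds a \linkS4class{SeedSets}.
#' @param params an \linkS4class{EnergyParams}; unresolved sigma/K are
#'   resolved from the field first (pass the output of
#'   \code{\link{resolveParams}} to pin them).
#' @param connectivity neighbourhood system.
#' @return The nonnegative energy.
#' @export
totalEnergy <- function(labeling, field, seeds, params = energyParams(),
                        connectivity = "slice8") {
    params <- resolveParams(params, field, connectivity)
    mask <- imageMask(field)
    lab <- as.integer(labeling)
    if (anyNA(lab[mask]))
        stop("labeling must be defined on every in-mask voxel")
    feats <- fieldFeatures(field, params@metric)
    inmask <- which(mask)
    K <- params@hardConstraintWeight

    unknown <- setdiff(inmask, c(seeds@target, seeds@background))
    regional <- 0
    regional <- regional +
        K * (sum(lab[seeds@target] == 0L) + sum(lab[seeds@background] == 1L))
    if (length(unknown)) {
        dists <- effectiveDistancesAll(field, seeds, params@metric, feats)
        dO <- dists@toTarget[unknown]
        dB <- dists@toBackground[unknown]
        tot <- dO + dB
        pT <- ifelse(tot == 0, 0.5, dO / tot)
        pB <- ifelse(tot == 0, 0.5, dB / tot)
        regional <- regional + sum(ifelse(lab[unknown] == 1L, pT, pB))
    }

    pairs <- neighborPairs(gridDim(field), mask, connectivity)
    boundary <- 0
    if (nrow(pairs)) {
        cut <- lab[pairs[, 1]] != lab[pairs[, 2]]
        if (any(cut)) {
            d <- feats$pairDist(pairs[cut, 1], pairs[cut, 2])
            boundary <- sum(exp(-d^2 / (2 * params@sigma^2)))
        }
    }
    params@alpha * regional + (1 - params@alpha) * boundary
}
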