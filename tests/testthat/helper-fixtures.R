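# Shared generators for randomized property tests. All callers set a seed
# before use.

# Random SPD 3x3 matrix, bounded away from the SPD boundary.
randomSPD <- function(scale = 1) {
    A <- matrix(rnorm(9), 3L)
    (crossprod(A) + 0.5 * diag(3)) * scale
}

# Random proper rotation matrix.
randomRotation <- function() {
    Q <- qr.Q(qr(matrix(rnorm(9), 3L)))
    if (det(Q) < 0) Q[, 1] <- -Q[, 1]
    Q
}

# Random flow graph with n non-terminal nodes: t-links for every node plus
# random internal arcs; capacities integer or uniform floats.
randomFlowGraph <- function(n, integerCaps = TRUE, extraArcs = 2L * n) {
    s <- n + 1L; t <- n + 2L
    from <- c(rep(s, n), seq_len(n))
    to <- c(seq_len(n), rep(t, n))
    if (extraArcs > 0 && n >= 2L) {
        a <- sample.int(n, extraArcs, replace = TRUE)
        b <- sample.int(n, extraArcs, replace = TRUE)
        keep <- a != b
        from <- c(from, a[keep])
        to <- c(to, b[keep])
    }
    caps <- if (integerCaps) as.numeric(sample(0:10, length(from), TRUE))
            else round(runif(length(from), 0, 10), 6)
    new("FlowGraph", nNodes = as.integer(n), from = as.integer(from),
        to = as.integer(to), capacity = caps, nodeVoxel = integer(0))
}

# Random small scalar segmentation instance with two seeds.
randomScalarInstance <- function(nr = 3L, nc = 4L) {
    img <- scalarImage(matrix(rnorm(nr * nc, 50, 20), nr, nc))
    idx <- sample.int(nr * nc, 2L)
    list(field = img, seeds = seedSets(idx[1], idx[2], c(nr, nc)))
}

# Random small tensor segmentation instance with two seeds.
randomTensorInstance <- function(nr = 3L, nc = 3L) {
    n <- nr * nc
    comp <- t(vapply(seq_len(n),
                     function(i) tensorComponents(randomSPD(1e-3)),
                     numeric(6)))
    field <- tensorField(array(comp, c(nr, nc, 6L)))
    idx <- sample.int(n, 2L)
    list(field = field, seeds = seedSets(idx[1], idx[2], c(nr, nc)))
}

# Exhaustive-enumeration minimum of the seeded-cut energy, built from the
# exported penalty primitives (independent of the graph solver). Returns the
# minimal energy over all seed-consistent labelings.
enumMinEnergy <- function(field, seeds, params = energyParams(),
                          connectivity = "slice8") {
    rp <- resolveParams(params, field, connectivity)
    mask <- imageMask(field)
    inmask <- which(mask)
    unknown <- setdiff(inmask, c(targetSeeds(seeds), backgroundSeeds(seeds)))
    u <- length(unknown)
    stopifnot(u <= 12L)

    dO <- vapply(unknown, effectiveDistance, numeric(1),
                 seeds = targetSeeds(seeds), field = field,
                 metric = metricName(rp))
    dB <- vapply(unknown, effectiveDistance, numeric(1),
                 seeds = backgroundSeeds(seeds), field = field,
                 metric = metricName(rp))
    tot <- dO + dB
    pT <- ifelse(tot == 0, 0.5, dO / tot)
    pB <- ifelse(tot == 0, 0.5, dB / tot)

    pairs <- neighborPairs(dim(mask), mask, connectivity)
    bw <- vapply(seq_len(nrow(pairs)), function(k)
        boundaryPenalty(pairs[k, 1], pairs[k, 2], field, rp, connectivity),
        numeric(1))

    lab <- rep(NA_integer_, prod(dim(mask)))
    lab[targetSeeds(seeds)] <- 1L
    lab[backgroundSeeds(seeds)] <- 0L
    alpha <- alphaFactor(rp)
    best <- Inf
    for (bits in 0:(2^u - 1)) {
        if (u) lab[unknown] <-
            as.integer(bitwAnd(bits, bitwShiftL(1L, seq_len(u) - 1L)) != 0L)
        regional <- if (u) sum(ifelse(lab[unknown] == 1L, pT, pB)) else 0
        cut <- lab[pairs[, 1]] != lab[pairs[, 2]]
        e <- alpha * regional + (1 - alpha) * sum(bw[cut])
        if (e < best) best <- e
    }
    best
}
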