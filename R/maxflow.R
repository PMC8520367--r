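# s/t graph construction and exact minimum-cut computation.
#
# Max flow is computed by igraph's C implementation; the min-cut partition is
# then derived here by the documented deterministic tie-break: nodes
# reachable from s in the residual graph are labelled target, all others
# background.

#' Build the s/t graph of a seeded segmentation instance
#'
#' Non-terminal nodes are the in-mask voxels (in increasing linear-index
#' order). Terminal links carry the alpha-scaled regional penalties, with the
#' orientation chosen so that the side of the cut a node falls on pays the
#' penalty of its assigned label: \code{s -> i} has capacity
#' \eqn{\alpha R(i, \mathrm{background})} and \code{i -> t} capacity
#' \eqn{\alpha R(i, \mathrm{target})}. Neighbour links carry
#' \eqn{(1-\alpha) B(i,j)} in both directions.
#'
#' @param field a \linkS4class{ScalarImage} or \linkS4class{TensorField}.
#' @param seeds a \linkS4class{SeedSets} with both sets non-empty.
#' @param params an \linkS4class{EnergyParams}; unresolved sigma/K are
#'   resolved from the field.
#' @param connectivity neighbourhood system (\code{"slice8"} or
#'   \code{"full6"}).
#' @return A \linkS4class{FlowGraph}.
#' @export
buildSTGraph <- function(field, seeds, params = energyParams(),
                         connectivity = "slice8") {
    if (!length(seeds@target) || !length(seeds@background))
        stop("configuration error: both target (O) and background (B) seed ",
             "sets must be non-empty")
    if (!identical(as.integer(gridDim(seeds)), as.integer(gridDim(field))))
        stop("seed mask dimensions do not match the image")
    mask <- imageMask(field)
    if (any(!mask[c(seeds@target, seeds@background)]))
        stop("configuration error: seeds placed on masked-out voxels")
    params <- resolveParams(params, field, connectivity)
    feats <- fieldFeatures(field, params@metric)
    alpha <- params@alpha
    K <- params@hardConstraintWeight

    inmask <- which(mask)
    m <- length(inmask)
    node <- integer(prod(gridDim(field)))
    node[inmask] <- seq_len(m)
    s <- m + 1L; t <- m + 2L

    # regional penalties per node for each label
    rT <- numeric(m); rB <- numeric(m)           # R(i, target), R(i, background)
    isT <- node[seeds@target]; isB <- node[seeds@background]
    rB[isT] <- K; rT[isB] <- K
    unknown <- setdiff(inmask, c(seeds@target, seeds@background))
    if (length(unknown)) {
        dists <- effectiveDistancesAll(field, seeds, params@metric, feats)
        dO <- dists@toTarget[unknown]; dB <- dists@toBackground[unknown]
        tot <- dO + dB
        rT[node[unknown]] <- ifelse(tot == 0, 0.5, dO / tot)
        rB[node[unknown]] <- ifelse(tot == 0, 0.5, dB / tot)
    }

    pairs <- neighborPairs(gridDim(field), mask, connectivity)
    nFrom <- node[pairs[, 1]]; nTo <- node[pairs[, 2]]
    w <- if (nrow(pairs)) {
        d <- feats$pairDist(pairs[, 1], pairs[, 2])
        (1 - alpha) * exp(-d^2 / (2 * params@sigma^2))
    } else numeric(0)

    new("FlowGraph", nNodes = m,
        from = c(rep(s, m), seq_len(m), nFrom, nTo),
        to = c(seq_len(m), rep(t, m), nTo, nFrom),
        capacity = c(alpha * rB, alpha * rT, w, w),
        nodeVoxel = as.integer(inmask))
}

#' Maximum flow and minimum s/t cut
#'
#' Computes an exact maximum s-to-t flow (via \code{igraph::max_flow}) and
#' the induced minimum cut. The source-side set is determined
#' deterministically: nodes reachable from s in the residual graph. By
#' max-flow/min-cut duality the returned cut capacity equals the flow value.
#'
#' @param g a \linkS4class{FlowGraph}.
#' @param tol absolute tolerance used to decide residual-arc saturation for
#'   floating-point capacities.
#' @return A list with \code{flowValue}, \code{sourceSide} (non-terminal
#'   node ids on the source side, labelled target downstream), and
#'   \code{cutCapacity}.
#' @examples
#' g <- new("FlowGraph", nNodes = 2L,
#'          from = c(3L, 3L, 1L, 2L, 1L), to = c(1L, 2L, 4L, 4L, 2L),
#'          capacity = c(3, 2, 2, 3, 1), nodeVoxel = integer(0))
#' maxFlowMinCut(g)$flowValue  # 5
#' @export
maxFlowMinCut <- function(g, tol = 1e-11) {
    s <- g@nNodes + 1L; t <- g@nNodes + 2L
    nv <- g@nNodes + 2L
    if (!length(g@from)) {
        return(list(flowValue = 0, sourceSide = integer(0), cutCapacity = 0))
    }
    ig <- igraph::make_graph(rbind(g@from, g@to), n = nv, directed = TRUE)
    mf <- igraph::max_flow(ig, source = s, target = t, capacity = g@capacity)
    flow <- as.numeric(mf$flow)

    # residual arcs: unsaturated forward arcs and traversed reverse arcs
    rFrom <- c(g@from[g@capacity - flow > tol], g@to[flow > tol])
    rTo <- c(g@to[g@capacity - flow > tol], g@from[flow > tol])
    reach <- logical(nv)
    reach[s] <- TRUE
    frontier <- s
    adj <- split(rTo, factor(rFrom, levels = seq_len(nv)))
    while (length(frontier)) {
        nxt <- unique(unlist(adj[frontier], use.names = FALSE))
        nxt <- nxt[!reach[nxt]]
        reach[nxt] <- TRUE
        frontier <- nxt
    }
    crossing <- reach[g@from] & !reach[g@to]
    list(flowValue = as.numeric(mf$value),
         sourceSide = which(reach[seq_len(g@nNodes)]),
         cutCapacity = sum(g@capacity[crossing]))
}

#' Brute-force minimum cut by exhaustive enumeration
#'
#' Test oracle: enumerates all 2^n source-side subsets of the non-terminal
#' nodes and returns the minimum cut capacity together with every attaining
#' subset. Refuses graphs with more than 20 non-terminal nodes.
#'
#' @param g a \linkS4class{FlowGraph} with at most 20 non-terminal nodes.
#' @param tol absolute tolerance for collecting co-optimal cuts.
#' @return A list with \code{value} and \code{cuts} (a list of integer
#'   vectors, the source-side non-terminal nodes of each optimal cut).
#' @export
bruteForceMinCut <- function(g, tol = 1e-12) {
    n <- g@nNodes
    if (n > 20L)
        stop("bruteForceMinCut refuses graphs with more than 20 nodes")
    s <- n + 1L; t <- n + 2L
    best <- Inf; cuts <- list()
    for (bits in 0:(2^n - 1)) {
        side <- logical(n + 2L)
        side[s] <- TRUE
        if (n) side[seq_len(n)] <- bitwAnd(bits, bitwShiftL(1L, seq_len(n) - 1L)) != 0L
        val <- sum(g@capacity[side[g@from] & !side[g@to]])
        if (val < best - tol) {
            best <- val
            cuts <- list(which(side[seq_len(n)]))
        } else if (val <= best + tol) {
            cuts <- c(cuts, list(which(side[seq_len(n)])))
        }
    }
    list(value = best, cuts = cuts)
}

#' Write / read a flow graph as a plain-text edge list
#'
#' Documented debug format: a header line \code{nodes <n>} (terminals are
#' implicitly \code{s = n+1}, \code{t = n+2}), then one line per arc
#' \code{<from> <to> <capacity>} with full double precision.
#'
#' @param g a \linkS4class{FlowGraph}.
#' @param path file path.
#' @return \code{readFlowGraph} returns the \linkS4class{FlowGraph};
#'   \code{writeFlowGraph} returns \code{path} invisibly.
#' @export
writeFlowGraph <- function(g, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("nodes %d", g@nNodes), con)
    writeLines(sprintf("%d %d %.17g", g@from, g@to, g@capacity), con)
    invisible(path)
}

#' @rdname writeFlowGraph
#' @export
readFlowGraph <- function(path) {
    lines <- readLines(path)
    hdr <- strsplit(lines[1], " ", fixed = TRUE)[[1]]
    if (length(hdr) != 2L || hdr[1] != "nodes")
        stop("format error: expected header 'nodes <n>'")
    n <- as.integer(hdr[2])
    if (length(lines) > 1L) {
        parts <- do.call(rbind, strsplit(lines[-1], " ", fixed = TRUE))
        new("FlowGraph", nNodes = n, from = as.integer(parts[, 1]),
            to = as.integer(parts[, 2]), capacity = as.numeric(parts[, 3]),
            nodeVoxel = integer(0))
    } else {
        new("FlowGraph", nNodes = n, from = integer(0), to = integer(0),
            capacity = numeric(0), nodeVoxel = integer(0))
    }
}
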