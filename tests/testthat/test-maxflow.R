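test_that("graph construction counts nodes and neighbour links correctly", {
    img <- scalarImage(matrix(c(1, 2, 3, 4), 2, 2))
    seeds <- seedSets(1, 4, c(2, 2))
    g <- buildSTGraph(img, seeds)
    expect_equal(nNodes(g), 4L)              # 4 voxels + implicit terminals
    e <- graphEdges(g)
    s <- nNodes(g) + 1L; t <- nNodes(g) + 2L
    expect_equal(sum(e$from == s), 4L)       # one s t-link per node
    expect_equal(sum(e$to == t), 4L)         # one t t-link per node
    # 6 n-link pairs (4 edges + 2 diagonals), one arc per direction
    nl <- e[e$from != s & e$to != t, ]
    expect_equal(nrow(nl), 12L)
    # n-links are symmetric in capacity
    key <- paste(pmin(nl$from, nl$to), pmax(nl$from, nl$to))
    expect_true(all(tapply(nl$capacity, key, function(x)
        length(x) == 2 && diff(x) == 0)))
})

test_that("fully seeded instances need no effective distances", {
    img <- scalarImage(matrix(c(1, 2, 3, 4), 2, 2))
    seeds <- seedSets(c(1, 2), c(3, 4), c(2, 2))
    g <- buildSTGraph(img, seeds)
    e <- graphEdges(g)
    s <- nNodes(g) + 1L; t <- nNodes(g) + 2L
    tl <- e[e$from == s | e$to == t, ]
    # every t-link is either 0 or alpha*K: only hard constraints remain
    p <- resolveParams(energyParams(), img)
    expect_true(all(abs(tl$capacity) < 1e-12 |
                    abs(tl$capacity - 0.5 * hardWeight(p)) < 1e-9))
})

test_that("empty seed sets are a configuration error", {
    img <- scalarImage(matrix(1, 2, 2))
    expect_error(buildSTGraph(img, seedSets(integer(0), 4, c(2, 2))),
                 "configuration error")
    expect_error(buildSTGraph(img, seedSets(1, integer(0), c(2, 2))),
                 "configuration error")
})

test_that("max flow solves textbook instances", {
    # single arc s -> t
    g1 <- new("FlowGraph", nNodes = 0L, from = 1L, to = 2L, capacity = 7,
              nodeVoxel = integer(0))
    expect_equal(maxFlowMinCut(g1)$flowValue, 7)
    # s->a(3), s->b(2), a->t(2), b->t(3), a->b(1): min cut {s} = 5
    g2 <- new("FlowGraph", nNodes = 2L, from = c(3L, 3L, 1L, 2L, 1L),
              to = c(1L, 2L, 4L, 4L, 2L), capacity = c(3, 2, 2, 3, 1),
              nodeVoxel = integer(0))
    r2 <- maxFlowMinCut(g2)
    expect_equal(r2$flowValue, 5)
    expect_equal(r2$cutCapacity, 5)
    expect_equal(bruteForceMinCut(g2)$value, 5)
    # no s -> t path: flow 0
    g3 <- new("FlowGraph", nNodes = 2L, from = c(3L, 2L),
              to = c(1L, 4L), capacity = c(3, 3), nodeVoxel = integer(0))
    r3 <- maxFlowMinCut(g3)
    expect_equal(r3$flowValue, 0)
    expect_equal(r3$cutCapacity, 0)
    # reachability tie-break: node 1 is reachable from s, node 2 is not
    expect_equal(r3$sourceSide, 1L)
})

test_that("brute force enumerates all optimal cuts and guards its size", {
    g <- new("FlowGraph", nNodes = 2L, from = c(3L, 3L, 1L, 2L, 1L),
             to = c(1L, 2L, 4L, 4L, 2L), capacity = c(3, 2, 2, 3, 1),
             nodeVoxel = integer(0))
    bf <- bruteForceMinCut(g)
    expect_equal(bf$value, 5)
    # three co-optimal cuts: {}, {a}, {a,b} on the source side
    expect_setequal(vapply(bf$cuts, paste, character(1), collapse = ","),
                    c("", "1", "1,2"))
    gZero <- new("FlowGraph", nNodes = 3L, from = c(4L, 1L), to = c(1L, 5L),
                 capacity = c(0, 0), nodeVoxel = integer(0))
    expect_equal(bruteForceMinCut(gZero)$value, 0)
    gBig <- new("FlowGraph", nNodes = 21L, from = 22L, to = 23L,
                capacity = 1, nodeVoxel = integer(0))
    expect_error(bruteForceMinCut(gBig), "refuses")
})

test_that("max flow equals brute force on random graphs and duality holds exactly", {
    set.seed(1234)
    for (rep in 1:60) {
        n <- sample(2:12, 1)
        integerCaps <- rep <= 30
        g <- randomFlowGraph(n, integerCaps)
        mf <- maxFlowMinCut(g)
        bf <- bruteForceMinCut(g)
        if (integerCaps) {
            expect_identical(mf$flowValue, bf$value)
            expect_identical(mf$cutCapacity, bf$value)
        } else {
            expect_equal(mf$flowValue, bf$value, tolerance = 1e-9)
            expect_equal(mf$cutCapacity, bf$value, tolerance = 1e-9)
        }
        # the returned source side is itself an optimal cut
        side <- logical(n + 2L); side[n + 1L] <- TRUE
        side[mf$sourceSide] <- TRUE
        e <- graphEdges(g)
        expect_equal(sum(e$capacity[side[e$from] & !side[e$to]]),
                     bf$value, tolerance = 1e-9)
    }
})

test_that("max flow is deterministic for a fixed graph", {
    set.seed(55)
    g <- randomFlowGraph(10, FALSE)
    r1 <- maxFlowMinCut(g)
    r2 <- maxFlowMinCut(g)
    expect_identical(r1$flowValue, r2$flowValue)
    expect_identical(r1$sourceSide, r2$sourceSide)
})

test_that("flow graphs round-trip through the text edge-list format", {
    set.seed(66)
    g <- randomFlowGraph(6, FALSE)
    f <- tempfile(fileext = ".txt")
    writeFlowGraph(g, f)
    h <- readFlowGraph(f)
    expect_identical(nNodes(h), nNodes(g))
    expect_identical(graphEdges(h), graphEdges(g))
    expect_error(readFlowGraph(writeLines2 <- {
        f2 <- tempfile(); writeLines("bogus header", f2); f2
    }), "format error")
})
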