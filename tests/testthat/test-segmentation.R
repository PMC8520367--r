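test_that("a noiseless two-intensity image is recovered exactly from one seed per region", {
    img <- scalarImage(matrix(rep(c(0, 100), each = 8 * 4), 8, 8))
    seeds <- seedSets(target = 1, background = 64, dim = c(8, 8))
    res <- segmentImage(img, seeds)
    truth <- matrix(rep(c(TRUE, FALSE), each = 8 * 4), 8, 8)
    expect_equal(diceCoefficient(labeling(res) == 1L, truth), 1)
    expect_equal(energyValue(res), flowValue(res), tolerance = 1e-9)
})

test_that("a fully seeded image returns the seed labels", {
    img <- scalarImage(matrix(rnorm(6), 2, 3))
    seeds <- seedSets(c(1, 3, 5), c(2, 4, 6), c(2, 3))
    res <- segmentImage(img, seeds)
    expect_equal(which(labeling(res) == 1L), c(1L, 3L, 5L))
    expect_equal(which(labeling(res) == 0L), c(2L, 4L, 6L))
})

test_that("the noiseless tensor phantom is recovered exactly from sparse seeds", {
    spec <- phantomSpec(noiseSD = 0)
    p <- makeTensorPhantom(spec)
    res <- segmentImage(p$field, phantomSeeds(spec))
    expect_equal(diceCoefficient(labeling(res) == 1L, p$truth), 1)
    expect_equal(metricName(paramsUsed(res)), "logEuclidean")
})

test_that("a uniform tensor field keeps its seeds and stays seed-consistent", {
    comp <- matrix(rep(tensorComponents(diag(3) * 1e-3), each = 9), 9)
    fld <- tensorField(array(comp, c(3, 3, 6)))
    seeds <- seedSets(5, c(1, 9), c(3, 3))
    res <- segmentImage(fld, seeds)
    lab <- labeling(res)
    expect_equal(lab[5], 1L)
    expect_equal(lab[c(1, 9)], c(0L, 0L))
    expect_false(anyNA(lab))
})

test_that("non-SPD in-mask voxels abort tensor segmentation naming the voxel", {
    comp <- matrix(rep(tensorComponents(diag(3)), each = 4), 4)
    comp[3, ] <- c(1, 0, 1, 0, 0, -1)
    fld <- tensorField(array(comp, c(2, 2, 6)))
    expect_error(segmentImage(fld, seedSets(1, 4, c(2, 2))), "\\(1,2\\)")
    # the same voxel masked out is no longer an error
    m <- matrix(TRUE, 2, 2); m[1, 2] <- FALSE
    fld2 <- tensorField(array(comp, c(2, 2, 6)), m)
    res <- segmentImage(fld2, seedSets(1, 4, c(2, 2)))
    expect_true(is.na(labeling(res)[1, 2]))
})

test_that("segmentation is deterministic bit-for-bit", {
    spec <- phantomSpec(noiseSD = 0.05, seed = 99L)
    p <- makeTensorPhantom(spec)
    r1 <- segmentImage(p$field, phantomSeeds(spec))
    r2 <- segmentImage(p$field, phantomSeeds(spec))
    expect_identical(labeling(r1), labeling(r2))
    expect_identical(energyValue(r1), energyValue(r2))
})

test_that("seeds are preserved on randomized instances and energies match flows", {
    set.seed(777)
    for (rep in 1:10) {
        inst <- if (rep %% 2) randomScalarInstance(4, 5)
                else randomTensorInstance(3, 4)
        res <- segmentImage(inst$field, inst$seeds)
        lab <- labeling(res)
        expect_true(all(lab[targetSeeds(inst$seeds)] == 1L))
        expect_true(all(lab[backgroundSeeds(inst$seeds)] == 0L))
        expect_equal(energyValue(res), flowValue(res),
                     tolerance = 1e-6 * (1 + energyValue(res)))
    }
})

test_that("the solver attains the exhaustive-enumeration energy minimum", {
    set.seed(888)
    for (rep in 1:8) {
        inst <- if (rep %% 2) randomScalarInstance(3, 4)
                else randomTensorInstance(3, 3)
        res <- segmentImage(inst$field, inst$seeds)
        emin <- enumMinEnergy(inst$field, inst$seeds)
        expect_equal(energyValue(res), emin,
                     tolerance = 1e-9 * (1 + emin))
        expect_lte(energyValue(res), emin + 1e-9)
    }
})

test_that("swapping seed sets complements the labeling on a symmetric phantom", {
    spec <- phantomSpec(noiseSD = 0)
    p <- makeTensorPhantom(spec)
    seeds <- phantomSeeds(spec)
    fwd <- segmentImage(p$field, seeds)
    swp <- segmentImage(p$field,
                        seedSets(backgroundSeeds(seeds), targetSeeds(seeds),
                                 gridDim(seeds)))
    expect_equal(labeling(swp), 1L - labeling(fwd))
})

test_that("volumes are segmented slice-wise by default and fully 3D on request", {
    vals <- array(rep(c(0, 10), each = 4), c(2, 2, 2))
    img <- scalarImage(vals)
    seeds <- seedSets(1, 8, c(2, 2, 2))
    resSlice <- segmentImage(img, seeds)
    res3d <- segmentImage(img, seeds, connectivity = "full6")
    truth <- vals == 0
    expect_equal(diceCoefficient(labeling(res3d) == 1L, truth), 1)
    expect_true(all(labeling(resSlice)[c(1, 8)] == c(1L, 0L)))
})
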