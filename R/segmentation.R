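# End-to-end seeded segmentation: build the s/t graph, solve the min cut,
# map the source side back to a label array, and audit the energy.

segmentCore <- function(field, seeds, params, connectivity) {
    params <- resolveParams(params, field, connectivity)
    g <- buildSTGraph(field, seeds, params, connectivity)
    cut <- maxFlowMinCut(g)

    lab <- array(NA_integer_, gridDim(field))
    lab[g@nodeVoxel] <- 0L
    lab[g@nodeVoxel[cut$sourceSide]] <- 1L

    if (any(lab[seeds@target] != 1L) || any(lab[seeds@background] != 0L))
        stop("internal error: a seed was flipped by the minimum cut")

    energy <- totalEnergy(lab, field, seeds, params, connectivity)
    if (abs(energy - cut$flowValue) > 1e-6 * (1 + abs(energy)))
        warning(sprintf(
            "energy audit mismatch: E = %.10g but flow = %.10g",
            energy, cut$flowValue))
    new("SegmentationResult", labeling = lab, energy = energy,
        flowValue = cut$flowValue, params = params,
        seedCounts = c(target = length(seeds@target),
                       background = length(seeds@background)))
}

#' @describeIn segmentImage scalar images; the voxel feature is the
#'   intensity and the feature distance its absolute difference.
#' @export
setMethod("segmentImage", "ScalarImage",
    function(x, seeds, params = energyParams(), connectivity = "slice8") {
        segmentCore(x, seeds, params, connectivity)
    })

#' @describeIn segmentImage tensor fields; every in-mask voxel must be SPD
#'   (the first offending voxel is named otherwise) and the feature distance
#'   is the tensor dissimilarity named in \code{params}.
#' @export
setMethod("segmentImage", "TensorField",
    function(x, seeds, params = energyParams(), connectivity = "slice8") {
        segmentCore(x, seeds, params, connectivity)
    })
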