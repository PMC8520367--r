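#' @name accessors
#' @title Accessors for tensorCut classes
#' @description Slot accessors; user code should prefer these over direct
#'   slot access.
#' @param x a tensorCut object.
#' @return The corresponding slot value.
NULL

#' @rdname accessors
#' @export
setGeneric("imageValues", function(x) standardGeneric("imageValues"))
#' @rdname accessors
#' @export
setGeneric("imageMask", function(x) standardGeneric("imageMask"))
#' @rdname accessors
#' @export
setGeneric("tensorArray", function(x) standardGeneric("tensorArray"))
#' @rdname accessors
#' @export
setGeneric("gridDim", function(x) standardGeneric("gridDim"))
#' @rdname accessors
#' @export
setGeneric("targetSeeds", function(x) standardGeneric("targetSeeds"))
#' @rdname accessors
#' @export
setGeneric("backgroundSeeds", function(x) standardGeneric("backgroundSeeds"))
#' @rdname accessors
#' @export
setGeneric("alphaFactor", function(x) standardGeneric("alphaFactor"))
#' @rdname accessors
#' @export
setGeneric("sigmaScale", function(x) standardGeneric("sigmaScale"))
#' @rdname accessors
#' @export
setGeneric("hardWeight", function(x) standardGeneric("hardWeight"))
#' @rdname accessors
#' @export
setGeneric("metricName", function(x) standardGeneric("metricName"))
#' @rdname accessors
#' @export
setGeneric("labeling", function(x) standardGeneric("labeling"))
#' @rdname accessors
#' @export
setGeneric("energyValue", function(x) standardGeneric("energyValue"))
#' @rdname accessors
#' @export
setGeneric("flowValue", function(x) standardGeneric("flowValue"))
#' @rdname accessors
#' @export
setGeneric("paramsUsed", function(x) standardGeneric("paramsUsed"))
#' @rdname accessors
#' @export
setGeneric("nNodes", function(x) standardGeneric("nNodes"))
#' @rdname accessors
#' @export
setGeneric("graphEdges", function(x) standardGeneric("graphEdges"))

#' Seeded graph-cut segmentation
#'
#' Segments an image into target and background by an exact minimum s/t cut
#' of the seeded-cut energy. Methods exist for \linkS4class{ScalarImage}
#' (feature distance = absolute intensity difference) and
#' \linkS4class{TensorField} (feature distance = the configured tensor
#' dissimilarity).
#'
#' @param x the image to segment.
#' @param seeds a \linkS4class{SeedSets}; both sets must be non-empty.
#' @param params an \linkS4class{EnergyParams}.
#' @param connectivity \code{"slice8"} (8-neighbourhood per slice, the
#'   default) or \code{"full6"} (6-neighbourhood through a 3D volume).
#' @param ... passed to methods.
#' @return A \linkS4class{SegmentationResult}.
#' @seealso \code{\link{totalEnergy}}, \code{\link{buildSTGraph}}
#' @export
setGeneric("segmentImage",
           function(x, seeds, params = energyParams(), ...)
               standardGeneric("segmentImage"))

## ---- accessor methods ------------------------------------------------------

#' @rdname accessors
setMethod("imageValues", "ScalarImage", function(x) x@values)
#' @rdname accessors
setMethod("imageMask", "ScalarImage", function(x) x@mask)
#' @rdname accessors
setMethod("imageMask", "TensorField", function(x) x@mask)
#' @rdname accessors
setMethod("tensorArray", "TensorField", function(x) x@tensors)
#' @rdname accessors
setMethod("gridDim", "ScalarImage", function(x) dim(x@values))
#' @rdname accessors
setMethod("gridDim", "TensorField", function(x) dim(x@mask))
#' @rdname accessors
setMethod("gridDim", "SeedSets", function(x) x@dim)
#' @rdname accessors
setMethod("targetSeeds", "SeedSets", function(x) x@target)
#' @rdname accessors
setMethod("backgroundSeeds", "SeedSets", function(x) x@background)
#' @rdname accessors
setMethod("alphaFactor", "EnergyParams", function(x) x@alpha)
#' @rdname accessors
setMethod("sigmaScale", "EnergyParams", function(x) x@sigma)
#' @rdname accessors
setMethod("hardWeight", "EnergyParams", function(x) x@hardConstraintWeight)
#' @rdname accessors
setMethod("metricName", "EnergyParams", function(x) x@metric)
#' @rdname accessors
setMethod("metricName", "EffectiveDistances", function(x) x@metric)
#' @rdname accessors
setMethod("labeling", "SegmentationResult", function(x) x@labeling)
#' @rdname accessors
setMethod("energyValue", "SegmentationResult", function(x) x@energy)
#' @rdname accessors
setMethod("flowValue", "SegmentationResult", function(x) x@flowValue)
#' @rdname accessors
setMethod("paramsUsed", "SegmentationResult", function(x) x@params)
#' @rdname accessors
setMethod("nNodes", "FlowGraph", function(x) x@nNodes)
#' @rdname accessors
setMethod("graphEdges", "FlowGraph", function(x)
    data.frame(from = x@from, to = x@to, capacity = x@capacity))

## ---- show methods ----------------------------------------------------------

setMethod("show", "ScalarImage", function(object) {
    d <- dim(object@values)
    cat(sprintf("ScalarImage: %s grid, %d/%d voxels in-mask\n",
                paste(d, collapse = "x"), sum(object@mask), prod(d)))
})

setMethod("show", "TensorField", function(object) {
    d <- dim(object@mask)
    cat(sprintf("TensorField: %s grid, 6 components/voxel, %d/%d in-mask\n",
                paste(d, collapse = "x"), sum(object@mask), prod(d)))
})

setMethod("show", "SeedSets", function(object) {
    cat(sprintf("SeedSets on %s grid: %d target (O), %d background (B), %d unknown (U)\n",
                paste(object@dim, collapse = "x"), length(object@target),
                length(object@background),
                prod(object@dim) - length(object@target) - length(object@background)))
})

setMethod("show", "EnergyParams", function(object) {
    cat(sprintf("EnergyParams: alpha=%g, sigma=%s, K=%s, metric=%s\n",
                object@alpha,
                if (is.na(object@sigma)) "adaptive" else format(object@sigma),
                if (is.na(object@hardConstraintWeight)) "per-instance"
                else format(object@hardConstraintWeight),
                object@metric))
})

setMethod("show", "FlowGraph", function(object) {
    cat(sprintf("FlowGraph: %d nodes + terminals s=%d, t=%d; %d arcs\n",
                object@nNodes, object@nNodes + 1L, object@nNodes + 2L,
                length(object@from)))
})

setMethod("show", "SegmentationResult", function(object) {
    lab <- object@labeling
    cat(sprintf("SegmentationResult: %d target / %d background voxels; E=%.6g, flow=%.6g (metric %s, alpha %g)\n",
                sum(lab == 1L, na.rm = TRUE), sum(lab == 0L, na.rm = TRUE),
                object@energy, object@flowValue, object@params@metric,
                object@params@alpha))
})

setMethod("show", "PhantomSpec", function(object) {
    cat(sprintf("PhantomSpec: %s grid, lesion centre (%g,%g) axes (%g,%g), noise SD %g, seed %d\n",
                paste(object@dim, collapse = "x"), object@lesionCenter[1],
                object@lesionCenter[2], object@lesionAxes[1],
                object@lesionAxes[2], object@noiseSD, object@seed))
})

setMethod("show", "GroupSummary", function(object) {
    cat(sprintf("GroupSummary: %g +/- %g (n = %d)\n", object@mean,
                object@sd, object@n))
})
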