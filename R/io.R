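# Readers and writers: NIfTI volumes and tensor fields, PNG 2D masks and
# images, JSON configs and audits.
#
# Coordinate convention: arrays are indexed 1-based in R's column-major
# order; all linear voxel indices in this package refer to that order. The
# NIfTI affine of inputs is not interpreted; arrays round-trip as stored.

isPNG <- function(path) grepl("\\.png$", path, ignore.case = TRUE)

# Drop the niftiImage class and attributes, keeping values bit-exact.
asPlainArray <- function(x) array(as.vector(x), dim(x))

#' Write / read a diffusion-tensor NIfTI volume
#'
#' Tensors are stored with a trailing dimension of 6 components in
#' lower-triangular order (Dxx, Dxy, Dyy, Dxz, Dyz, Dzz). 2D fields are
#' written as \code{rows x cols x 1 x 6}; 3D fields as
#' \code{x x y x z x 6}. Doubles are written at full precision, so a write /
#' read cycle is bit-exact. Masked-out voxels are stored as all-zero
#' records.
#'
#' On read, every voxel is SPD-validated; voxels failing validation are
#' flagged masked-out and their count is reported via \code{message}.
#'
#' @param field a \linkS4class{TensorField}.
#' @param path a \code{.nii} or \code{.nii.gz} path.
#' @param tol SPD tolerance used for per-voxel validation on read.
#' @return \code{readTensorNifti} returns a \linkS4class{TensorField};
#'   \code{writeTensorNifti} returns \code{path} invisibly.
#' @export
writeTensorNifti <- function(field, path) {
    stopifnot(is(field, "TensorField"))
    gd <- gridDim(field)
    arr <- field@tensors
    if (length(gd) == 2L) dim(arr) <- c(gd, 1L, 6L)
    n <- prod(gd)
    comp <- matrix(arr, nrow = n)
    comp[!as.vector(field@mask), ] <- 0
    arr <- array(comp, dim(arr))
    RNifti::writeNifti(RNifti::asNifti(arr, datatype = "double"), path)
    invisible(path)
}

#' @rdname writeTensorNifti
#' @export
readTensorNifti <- function(path, tol = 1e-10) {
    arr <- asPlainArray(RNifti::readNifti(path))
    d <- dim(arr)
    if (d[length(d)] != 6L)
        stop("format error: expected a trailing dimension of 6 tensor ",
             "components in lower-triangular order (Dxx, Dxy, Dyy, Dxz, ",
             "Dyz, Dzz); got trailing dimension ", d[length(d)])
    if (length(d) == 4L && d[3] == 1L) {
        dim(arr) <- c(d[1:2], 6L)
        d <- dim(arr)
    }
    gd <- d[-length(d)]
    n <- prod(gd)
    comp <- matrix(arr, nrow = n)
    mask <- vapply(seq_len(n), function(i) {
        m <- tensorFromComponents(comp[i, ])
        all(is.finite(m)) &&
            min(eigen(m, symmetric = TRUE, only.values = TRUE)$values) > tol
    }, logical(1))
    nbad <- sum(!mask)
    if (nbad > 0)
        message(nbad, " voxel(s) failed SPD validation and were masked out")
    tensorField(arr, array(mask, gd))
}

#' Write / read label masks and seed masks
#'
#' Label images use a single-artifact dialect: 0 = unknown, 1 = target,
#' 2 = background for seed masks; segmentation outputs use 0/1. PNG (2D
#' only, 8-bit grayscale with labels stored as value/255) and NIfTI dialects
#' are interchangeable: identical label arrays yield identical
#' \linkS4class{SeedSets} from either format.
#'
#' @param mask integer array of labels.
#' @param path \code{.png} (2D only) or \code{.nii}/\code{.nii.gz}.
#' @return \code{readLabelMask} returns the integer label array;
#'   \code{readSeedMask} a \linkS4class{SeedSets}; writers return \code{path}
#'   invisibly.
#' @export
writeMask <- function(mask, path) {
    mask <- as.array(mask)
    storage.mode(mask) <- "integer"
    if (anyNA(mask)) mask[is.na(mask)] <- 0L
    if (isPNG(path)) {
        if (length(dim(mask)) != 2L)
            stop("format error: PNG masks must be 2D")
        png::writePNG(mask / 255, path)
    } else {
        RNifti::writeNifti(RNifti::asNifti(mask, datatype = "int16"), path)
    }
    invisible(path)
}

#' @rdname writeMask
#' @export
readLabelMask <- function(path) {
    if (isPNG(path)) {
        arr <- png::readPNG(path)
        if (length(dim(arr)) == 3L) arr <- arr[, , 1L]
        lab <- array(as.integer(round(arr * 255)), dim(arr))
    } else {
        arr <- asPlainArray(RNifti::readNifti(path))
        d <- dim(arr)
        while (length(d) > 2L && d[length(d)] == 1L) {
            d <- d[-length(d)]
            dim(arr) <- d
        }
        lab <- array(as.integer(round(arr)), dim(arr))
    }
    lab
}

#' @rdname writeMask
#' @export
readSeedMask <- function(path) {
    lab <- readLabelMask(path)
    if (!all(lab %in% 0:2))
        stop("format error: seed label image may only contain 0 (unknown), ",
             "1 (target), 2 (background)")
    seedsFromMask(lab)
}

#' Write / read a 2D/3D scalar image
#'
#' PNG images (2D) are stored as 8-bit grayscale scaled to the unit
#' interval; NIfTI stores doubles at full precision.
#'
#' @param image a \linkS4class{ScalarImage}.
#' @param path \code{.png} or \code{.nii}/\code{.nii.gz}.
#' @return \code{readScalarImage} returns a \linkS4class{ScalarImage};
#'   the writer returns \code{path} invisibly.
#' @export
writeScalarImage <- function(image, path) {
    stopifnot(is(image, "ScalarImage"))
    v <- image@values
    if (isPNG(path)) {
        if (length(dim(v)) != 2L)
            stop("format error: PNG images must be 2D")
        rng <- range(v)
        scaled <- if (diff(rng) > 0) (v - rng[1]) / diff(rng) else v * 0
        png::writePNG(scaled, path)
    } else {
        RNifti::writeNifti(RNifti::asNifti(v, datatype = "double"), path)
    }
    invisible(path)
}

#' @rdname writeScalarImage
#' @export
readScalarImage <- function(path) {
    if (isPNG(path)) {
        arr <- png::readPNG(path)
        if (length(dim(arr)) == 3L) arr <- arr[, , 1L]
        scalarImage(array(as.numeric(arr), dim(arr)))
    } else {
        arr <- asPlainArray(RNifti::readNifti(path))
        d <- dim(arr)
        while (length(d) > 3L && d[length(d)] == 1L) {
            d <- d[-length(d)]
            dim(arr) <- d
        }
        scalarImage(arr)
    }
}

#' Serialize energy parameters to / from flat JSON
#'
#' Keys: \code{alpha}, \code{sigma}, \code{hard_constraint_weight},
#' \code{metric}. \code{null} encodes the data-adaptive defaults.
#'
#' @param params an \linkS4class{EnergyParams}.
#' @param path JSON file path.
#' @return \code{readEnergyParams} returns an \linkS4class{EnergyParams};
#'   the writer returns \code{path} invisibly.
#' @export
writeEnergyParams <- function(params, path) {
    x <- list(alpha = params@alpha,
              sigma = if (is.na(params@sigma)) NULL else params@sigma,
              hard_constraint_weight =
                  if (is.na(params@hardConstraintWeight)) NULL
                  else params@hardConstraintWeight,
              metric = params@metric)
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
    invisible(path)
}

#' @rdname writeEnergyParams
#' @export
readEnergyParams <- function(path) {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    energyParams(alpha = x$alpha %||% 0.5,
                 sigma = x$sigma %||% NA_real_,
                 hardConstraintWeight = x$hard_constraint_weight %||% NA_real_,
                 metric = x$metric %||% "logEuclidean")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write the audit record of a segmentation run
#'
#' JSON with the metric name, alpha, sigma, K, seed counts, energy and flow
#' value. Re-running the segmentation with the recorded parameters and the
#' original inputs reproduces the labeling exactly (the pipeline is
#' deterministic).
#'
#' @param result a \linkS4class{SegmentationResult}.
#' @param path JSON file path.
#' @return \code{path}, invisibly.
#' @export
writeAudit <- function(result, path) {
    p <- result@params
    x <- list(metric = p@metric, alpha = p@alpha, sigma = p@sigma,
              hard_constraint_weight = p@hardConstraintWeight,
              n_target_seeds = unname(result@seedCounts["target"]),
              n_background_seeds = unname(result@seedCounts["background"]),
              energy = result@energy, flow_value = result@flowValue,
              n_target_voxels = sum(result@labeling == 1L, na.rm = TRUE),
              n_background_voxels = sum(result@labeling == 0L, na.rm = TRUE))
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}
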