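#' @include AllClasses.R
NULL

## NIfTI I/O is delegated to RNifti; the conventions here are: world
## coordinates are RAS+ mm, voxel indices are 0-based, and any input image
## not already in RAS+ orientation is reoriented to canonical RAS+ on load.

#' Read a 3-D NIfTI volume
#'
#' Reads a NIfTI-1 file into a \linkS4class{ScalarVolume}, or a
#' \linkS4class{BrainMask} when every value is 0 or 1 and \code{asMask} is
#' not \code{FALSE}. Images not in RAS+ orientation are reoriented to
#' canonical RAS+ (with a message), so downstream geometry is unambiguous.
#'
#' @param path path to a \code{.nii} or \code{.nii.gz} file.
#' @param asMask \code{NA} (default): return a \code{BrainMask} iff the data
#'   are binary; \code{TRUE}: require binary data and return a mask;
#'   \code{FALSE}: always return a \code{ScalarVolume}.
#' @param kind kind tag for the returned \code{ScalarVolume}.
#' @return a \linkS4class{ScalarVolume} or \linkS4class{BrainMask}.
#' @seealso \code{\link{writeVolume}}
#' @export
readVolume <- function(path, asMask = NA, kind = "other") {
    if (!file.exists(path))
        stop("file not found: ", path)
    img <- RNifti::readNifti(path)
    nd <- length(dim(img))
    if (nd != 3L)
        stop(sprintf("expected a 3D volume, got %dD: %s", nd, path))
    if (RNifti::orientation(img) != "RAS") {
        message("reorienting ", basename(path), " from ",
                RNifti::orientation(img), " to RAS")
        RNifti::orientation(img) <- "RAS"
    }
    aff <- unclass(RNifti::xform(img))
    attributes(aff) <- list(dim = c(4L, 4L))
    dat <- as.array(img)
    grid <- VolumeGrid(dim(dat), aff)
    binary <- all(dat %in% c(0, 1))
    if (isTRUE(asMask) && !binary)
        stop("mask requested but values are not all 0/1: ", path)
    if (binary && !isFALSE(asMask))
        BrainMask(grid, dat != 0)
    else
        ScalarVolume(grid, dat, kind = kind)
}

#' Write a volume or mask as NIfTI-1
#'
#' Non-finite values are replaced by 0 before writing (out-of-mask NaN policy:
#' the mask is carried separately, volumes store 0 outside it).
#'
#' @param vol a \linkS4class{ScalarVolume} or \linkS4class{BrainMask}.
#' @param path output path (\code{.nii} or \code{.nii.gz}); the parent
#'   directory must exist.
#' @return \code{path}, invisibly.
#' @export
writeVolume <- function(vol, path) {
    if (!dir.exists(dirname(path)))
        stop("parent directory does not exist: ", dirname(path))
    if (is(vol, "BrainMask")) {
        dat <- array(as.numeric(vol@data), dim = vol@grid@shape)
        grid <- vol@grid
    } else if (is(vol, "ScalarVolume")) {
        dat <- vol@data
        dat[!is.finite(dat)] <- 0
        grid <- vol@grid
    } else stop("vol must be a ScalarVolume or BrainMask")
    img <- RNifti::asNifti(dat)
    RNifti::pixdim(img) <- voxelEdges(grid)
    RNifti::sform(img) <- structure(grid@affine, code = 2L)
    RNifti::qform(img) <- structure(grid@affine, code = 2L)
    RNifti::writeNifti(img, path)
    invisible(path)
}

#' World-to-voxel and voxel-to-world coordinate maps
#'
#' \code{worldToVoxel} applies the inverse grid affine to world mm
#' coordinates, yielding continuous 0-based voxel indices; \code{voxelToWorld}
#' is its exact inverse. \code{worldToVoxelNearest} additionally rounds each
#' index half away from zero (deterministically, unlike banker's rounding).
#' Out-of-grid indices are returned as-is; callers decide how to flag them.
#'
#' @param grid a \linkS4class{VolumeGrid}.
#' @param xyz numeric length-3 coordinate, or an n x 3 matrix of coordinates.
#' @return same shape as \code{xyz}: voxel indices (continuous, or integer
#'   for the nearest variant) or world mm coordinates.
#' @export
#' @examples
#' g <- VolumeGrid(c(10L, 10L, 10L), affineScaled(c(2, 2, 2), c(-10, -10, -10)))
#' worldToVoxel(g, c(0, 0, 0))   # voxel (5, 5, 5)
#' voxelToWorld(g, c(5, 5, 5))   # back to the origin
worldToVoxel <- function(grid, xyz) {
    .applyAffine(solve(grid@affine), xyz)
}

#' @rdname worldToVoxel
#' @export
voxelToWorld <- function(grid, xyz) {
    .applyAffine(grid@affine, xyz)
}

#' @rdname worldToVoxel
#' @export
worldToVoxelNearest <- function(grid, xyz) {
    v <- worldToVoxel(grid, xyz)
    r <- sign(v) * floor(abs(v) + 0.5)   # round half away from zero
    if (is.matrix(v)) matrix(as.integer(r), ncol = 3L) else as.integer(r)
}

.applyAffine <- function(a, xyz) {
    if (is.matrix(xyz)) {
        stopifnot(ncol(xyz) == 3L)
        out <- t(a %*% rbind(t(xyz), 1))[, 1:3, drop = FALSE]
        dimnames(out) <- NULL
        out
    } else {
        stopifnot(length(xyz) == 3L)
        as.vector(a %*% c(xyz, 1))[1:3]
    }
}

#' World coordinates of all voxel centers
#'
#' @param grid a \linkS4class{VolumeGrid}.
#' @param which optional integer vector of linear (column-major) voxel
#'   indices; default all voxels.
#' @return n x 3 matrix of mm coordinates, rows in column-major voxel order.
#' @export
voxelCenters <- function(grid, which = NULL) {
    if (is.null(which)) which <- seq_len(prod(grid@shape))
    ijk <- arrayInd(which, .dim = grid@shape) - 1L
    voxelToWorld(grid, ijk)
}

## ---------------------------------------------------------------------------
## Packed-vector helpers: the pipeline stores per-voxel statistics as plain
## vectors over the mask's in-mask voxels, in fixed column-major order.
## ---------------------------------------------------------------------------

#' Pack and unpack in-mask voxel vectors
#'
#' \code{maskVector} extracts a volume's in-mask values as a vector in the
#' mask's fixed column-major voxel ordering; \code{vectorToVolume} writes such
#' a vector back into a full \linkS4class{ScalarVolume} (0 outside the mask).
#' This ordering is the voxel axis of every packed matrix in the pipeline.
#'
#' @param vol a \linkS4class{ScalarVolume}.
#' @param mask a \linkS4class{BrainMask} on the same grid.
#' @param values numeric vector of length \code{nVoxels(mask)}.
#' @param kind kind tag for the rebuilt volume.
#' @return \code{maskVector}: numeric vector; \code{vectorToVolume}: a
#'   \linkS4class{ScalarVolume}.
#' @export
maskVector <- function(vol, mask) {
    stopifnot(sameGrid(vol@grid, mask@grid))
    vol@data[mask@data]
}

#' @rdname maskVector
#' @export
vectorToVolume <- function(values, mask, kind = "other") {
    stopifnot(length(values) == nVoxels(mask))
    d <- array(0, dim = mask@grid@shape)
    d[mask@data] <- values
    ScalarVolume(mask@grid, d, kind = kind)
}
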