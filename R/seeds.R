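#' @include AllClasses.R
NULL

#' Voxelise a sphere on the pipeline grid
#'
#' Builds the binary volume of all in-mask voxels whose world-coordinate
#' centers lie within \code{radius} mm (closed ball, Euclidean distance in mm)
#' of \code{center}. Distances are computed in world coordinates, never in
#' voxel units, so anisotropic or rotated grids are handled correctly; the
#' center need not coincide with a voxel center.
#'
#' @param center numeric length-3 MNI mm coordinate.
#' @param radius sphere radius in mm, > 0.
#' @param grid a \linkS4class{VolumeGrid}.
#' @param mask a \linkS4class{BrainMask} on \code{grid}; voxels outside it
#'   are excluded. A sphere entirely outside the mask yields an all-zero
#'   volume with a warning.
#' @return binary \linkS4class{ScalarVolume}.
#' @export
#' @examples
#' g <- VolumeGrid(c(11L, 11L, 11L), affineScaled(c(2, 2, 2), c(-10, -10, -10)))
#' m <- BrainMask(g, array(TRUE, c(11, 11, 11)))
#' sum(volData(makeSphere(c(0, 0, 0), 6, g, m)))  # 123 voxels
makeSphere <- function(center, radius, grid, mask) {
    stopifnot(radius > 0, length(center) == 3L, all(is.finite(center)))
    stopifnot(sameGrid(grid, mask@grid))
    inv <- solve(grid@affine)[1:3, 1:3, drop = FALSE]
    ## conservative voxel-space bounding box: |v_i| <= r * ||row_i(A^-1)||
    halfw <- radius * sqrt(rowSums(inv^2))
    cv <- worldToVoxel(grid, center)
    lo <- pmax(ceiling(cv - halfw), 0)
    hi <- pmin(floor(cv + halfw), grid@shape - 1L)
    out <- array(0, dim = grid@shape)
    if (all(lo <= hi)) {
        ijk <- as.matrix(expand.grid(i = seq.int(lo[1], hi[1]),
                                     j = seq.int(lo[2], hi[2]),
                                     k = seq.int(lo[3], hi[3])))
        w <- voxelToWorld(grid, ijk)
        d2 <- (w[, 1] - center[1])^2 + (w[, 2] - center[2])^2 +
              (w[, 3] - center[3])^2
        keep <- d2 <= radius^2
        if (any(keep)) {
            lin <- 1L + ijk[keep, 1L] + grid@shape[1] *
                   (ijk[keep, 2L] + grid@shape[2] * ijk[keep, 3L])
            out[lin] <- 1
        }
    }
    out[!mask@data] <- 0
    if (sum(out) == 0)
        warning(sprintf("sphere at (%g, %g, %g) r=%g mm contains no in-mask voxel",
                        center[1], center[2], center[3], radius))
    ScalarVolume(grid, out, kind = "binary")
}

#' Build a study's coactivation seed
#'
#' The coactivation seed is the voxelwise union of fixed-radius spheres
#' centred on every peak the study reported, restricted to the brain mask.
#' Combining all of a study's peaks into one seed yields experiment-level
#' inference: one seed, and later one connectivity map per participant, per
#' study.
#'
#' @param foci data.frame of the study's peaks with columns \code{x, y, z}
#'   (MNI mm; at least one row) and optionally \code{study_id}, \code{group}.
#' @param radius sphere radius in mm (default 6).
#' @param grid a \linkS4class{VolumeGrid}.
#' @param mask a \linkS4class{BrainMask} on \code{grid}.
#' @param studyId,group identifiers stored on the seed; defaults taken from
#'   \code{foci} when present.
#' @return a \linkS4class{CoactivationSeed}.
#' @export
makeCoactivationSeed <- function(foci, radius = 6, grid, mask,
                                 studyId = NULL, group = NULL) {
    stopifnot(nrow(foci) >= 1L)
    if (is.null(studyId))
        studyId <- if ("study_id" %in% names(foci))
            foci$study_id[1] else "study"
    if (is.null(group))
        group <- if ("group" %in% names(foci)) foci$group[1] else "NT"
    acc <- array(0, dim = grid@shape)
    for (i in seq_len(nrow(foci))) {
        sph <- suppressWarnings(
            makeSphere(as.numeric(foci[i, c("x", "y", "z")]),
                       radius, grid, mask))
        acc <- pmax(acc, sph@data)
    }
    if (sum(acc) == 0)
        stop("all spheres of study '", studyId,
             "' fall outside the brain mask")
    CoactivationSeed(studyId, group,
                     ScalarVolume(grid, acc, kind = "binary"))
}

#' Mean time series over a seed
#'
#' Unweighted mean, at each timepoint, of the time series of the seed's
#' voxels.
#'
#' @param p a \linkS4class{ParticipantTimeSeries}.
#' @param seed a \linkS4class{CoactivationSeed} on the same grid.
#' @return numeric vector of length T (timepoints).
#' @export
seedMeanTimeseries <- function(p, seed) {
    stopifnot(sameGrid(voxelGrid(p), voxelGrid(seed)))
    idx <- .seedColumns(seed, p@mask)
    if (length(idx) == 0L)
        stop("seed of study '", seed@studyId, "' has no in-mask voxel")
    rowMeans(p@data[, idx, drop = FALSE])
}

## Packed-column indices (in the mask's voxel ordering) of a seed's voxels
.seedColumns <- function(seed, mask) {
    which(seed@mask@data[mask@data] != 0)
}

#' Seed-to-voxel Fisher z connectivity of one participant
#'
#' Correlates the seed's mean time series with every in-mask voxel's time
#' series (Pearson r) and applies the Fisher z transform
#' \code{z = atanh(r)}. Correlations are clipped to +/- \code{clipR} first so
#' perfect correlations (e.g. a single-voxel seed with itself) stay finite.
#' Voxels with zero temporal variance get z = 0; their count is reported via
#' \code{message}. If the seed's mean series itself has zero variance the map
#' is all zero, with a warning.
#'
#' @param p a \linkS4class{ParticipantTimeSeries}.
#' @param seed a \linkS4class{CoactivationSeed} on the same grid.
#' @param excludeSeedVoxels zero the seed's own voxels in the output
#'   (default \code{FALSE}).
#' @param clipR clipping bound on |r| before atanh (default 1 - 1e-7).
#' @return \code{fisherZValues}: numeric vector over in-mask voxels (mask
#'   ordering); \code{fisherZMap}: the same values as a
#'   \linkS4class{ScalarVolume} of kind \code{z}.
#' @export
fisherZValues <- function(p, seed, excludeSeedVoxels = FALSE,
                          clipR = 1 - 1e-7) {
    s <- seedMeanTimeseries(p, seed)
    r <- .corVector(s, p@data)
    nzv <- attr(r, "nZeroVar")
    if (nzv > 0L)
        message(nzv, " zero-variance voxel(s) set to z = 0")
    if (attr(r, "seedZeroVar")) {
        warning("seed mean series has zero variance; all-zero z map")
        z <- numeric(length(r))
    } else {
        z <- atanh(pmin(pmax(as.numeric(r), -clipR), clipR))
    }
    if (excludeSeedVoxels)
        z[.seedColumns(seed, p@mask)] <- 0
    z
}

#' @rdname fisherZValues
#' @export
fisherZMap <- function(p, seed, excludeSeedVoxels = FALSE,
                       clipR = 1 - 1e-7) {
    z <- fisherZValues(p, seed, excludeSeedVoxels, clipR)
    vectorToVolume(z, p@mask, kind = "z")
}

## Pearson correlation of a vector with every column of a T x V matrix,
## vectorised; zero-variance columns yield r = 0 (count in attribute).
.corVector <- function(s, mat) {
    Tn <- length(s)
    sc <- s - mean(s)
    ssd <- sqrt(sum(sc^2))
    mc <- sweep(mat, 2L, colMeans(mat), check.margin = FALSE)
    csd <- sqrt(colSums(mc^2))
    zeroVar <- csd == 0
    seedZero <- ssd == 0
    if (seedZero) {
        r <- numeric(ncol(mat))
    } else {
        num <- as.numeric(crossprod(mc, sc))
        den <- csd * ssd
        den[zeroVar] <- 1
        r <- num / den
        r[zeroVar] <- 0
    }
    structure(r, nZeroVar = sum(zeroVar), seedZeroVar = seedZero)
}

#' Fisher z stacks for every study of a group
#'
#' Computes, for each study of the chosen group, the participants x voxels
#' matrix of seed-to-voxel Fisher z values across the whole connectome: the
#' experiment-level unit that both group-map branches consume.
#'
#' @param foci a \linkS4class{StudyFociTable} (all entries MNI).
#' @param participants list of \linkS4class{ParticipantTimeSeries}.
#' @param mask the shared \linkS4class{BrainMask}.
#' @param group \code{"NT"} or \code{"ASD"}.
#' @param config an \linkS4class{AnmConfig}.
#' @return named list (study id) of \linkS4class{ExperimentZStack}s.
#' @export
buildZStacks <- function(foci, participants, mask, group,
                         config = anmConfig()) {
    byStudy <- studyFoci(foci, group)
    if (length(byStudy) == 0L)
        stop("no studies in group ", group)
    grid <- mask@grid
    seeds <- lapply(byStudy, function(f)
        makeCoactivationSeed(f, radius = config@radius, grid = grid,
                             mask = mask))
    V <- nVoxels(mask)
    stacks <- lapply(names(seeds), function(sid) {
        z <- matrix(0, nrow = length(participants), ncol = V)
        for (pi in seq_along(participants)) {
            z[pi, ] <- suppressMessages(fisherZValues(
                participants[[pi]], seeds[[sid]],
                excludeSeedVoxels = config@excludeSeedVoxels,
                clipR = config@clipR))
        }
        ExperimentZStack(sid, group, mask, z)
    })
    names(stacks) <- names(seeds)
    stacks
}
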