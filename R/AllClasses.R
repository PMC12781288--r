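#' @include AllGenerics.R
NULL

## ---------------------------------------------------------------------------
## VolumeGrid
## ---------------------------------------------------------------------------

#' VolumeGrid: a voxel lattice with a world-coordinate affine
#'
#' A \code{VolumeGrid} couples a 3-D voxel lattice (its \code{shape}, voxels
#' per axis) with a 4x4 affine matrix mapping homogeneous 0-based voxel
#' indices to world coordinates in mm, RAS+ convention (x increases to the
#' right, y to anterior, z to superior). Every volume, mask, seed and map in
#' the pipeline lives on one shared grid; grid mismatch is an error, never a
#' silent resample.
#'
#' @slot shape integer vector of length 3, voxels per axis, all positive.
#' @slot affine numeric 4x4 matrix, invertible, last row (0,0,0,1).
#'
#' @param shape integer vector of length 3.
#' @param affine numeric 4x4 matrix.
#' @return a \code{VolumeGrid} object.
#' @export VolumeGrid
#' @exportClass VolumeGrid
#' @examples
#' # 2 mm isotropic grid centred on the origin
#' g <- VolumeGrid(c(10L, 10L, 10L), affineScaled(c(2, 2, 2), c(-9, -9, -9)))
#' voxelEdges(g)
setClass("VolumeGrid",
    representation(shape = "integer", affine = "matrix"),
    validity = function(object) {
        msg <- character()
        if (length(object@shape) != 3L || any(object@shape < 1L))
            msg <- c(msg, "shape must be 3 positive integers")
        if (!identical(dim(object@affine), c(4L, 4L)))
            msg <- c(msg, "affine must be a 4x4 matrix")
        else {
            if (!all(is.finite(object@affine)))
                msg <- c(msg, "affine must be finite")
            else if (abs(det(object@affine)) < 1e-12)
                msg <- c(msg, "affine must be invertible")
            if (max(abs(object@affine[4, ] - c(0, 0, 0, 1))) > 1e-9)
                msg <- c(msg, "affine last row must be (0,0,0,1)")
        }
        if (length(msg) == 0L && any(voxelEdges(object) <= 0))
            msg <- c(msg, "voxel edge lengths must be > 0")
        if (length(msg)) msg else TRUE
    })

VolumeGrid <- function(shape, affine) {
    new("VolumeGrid", shape = as.integer(shape),
        affine = matrix(as.numeric(affine), 4L, 4L))
}

#' Voxel edge lengths of a grid
#'
#' Edge lengths in mm along each voxel axis, computed as the Euclidean norms
#' of the affine's first three columns (correct for rotated or anisotropic
#' grids).
#'
#' @param grid a \linkS4class{VolumeGrid}.
#' @return numeric vector of length 3 (mm).
#' @export
voxelEdges <- function(grid) {
    a <- grid@affine[1:3, 1:3, drop = FALSE]
    sqrt(colSums(a^2))
}

#' Build a scale-and-translate affine
#'
#' Convenience constructor for the common axis-aligned case: voxel index i
#' maps to \code{origin + i * scales}.
#'
#' @param scales numeric length-3 voxel sizes in mm.
#' @param origin numeric length-3 world coordinate of voxel (0,0,0).
#' @return a 4x4 affine matrix.
#' @export
affineScaled <- function(scales, origin = c(0, 0, 0)) {
    a <- diag(c(scales, 1))
    a[1:3, 4] <- origin
    a
}

#' Compare two grids for equality
#'
#' Grids are equal iff shapes match and affines agree entrywise within
#' \code{tol}.
#'
#' @param a,b \linkS4class{VolumeGrid} objects.
#' @param tol numeric tolerance on affine entries (default 1e-6).
#' @return logical scalar.
#' @export
sameGrid <- function(a, b, tol = 1e-6) {
    identical(a@shape, b@shape) && max(abs(a@affine - b@affine)) <= tol
}

setMethod("show", "VolumeGrid", function(object) {
    e <- voxelEdges(object)
    cat(sprintf("VolumeGrid: %d x %d x %d voxels, edges %.3g x %.3g x %.3g mm\n",
        object@shape[1], object@shape[2], object@shape[3], e[1], e[2], e[3]))
})

## ---------------------------------------------------------------------------
## BrainMask
## ---------------------------------------------------------------------------

#' BrainMask: binary in-brain indicator on a grid
#'
#' The analysis mask. Its in-mask voxel count is the Bonferroni denominator
#' for the alpha-derived threshold mode, and its fixed column-major ordering
#' of in-mask voxels defines the voxel axis of every packed time-series or z
#' matrix in the pipeline.
#'
#' @slot grid a \linkS4class{VolumeGrid}.
#' @slot data logical array of dimension \code{grid@shape}.
#'
#' @param grid a \linkS4class{VolumeGrid}.
#' @param data logical (or 0/1 numeric) array.
#' @return a \code{BrainMask}.
#' @export BrainMask
#' @exportClass BrainMask
setClass("BrainMask",
    representation(grid = "VolumeGrid", data = "array"),
    validity = function(object) {
        msg <- character()
        if (!is.logical(object@data))
            msg <- c(msg, "mask data must be logical")
        if (!identical(dim(object@data), as.integer(object@grid@shape)))
            msg <- c(msg, "mask dimensions must match grid shape")
        if (any(is.na(object@data)))
            msg <- c(msg, "mask must not contain NA")
        if (length(msg) == 0L && sum(object@data) < 1L)
            msg <- c(msg, "mask must contain at least one voxel")
        if (length(msg)) msg else TRUE
    })

BrainMask <- function(grid, data) {
    d <- array(as.logical(data), dim = grid@shape)
    new("BrainMask", grid = grid, data = d)
}

setMethod("voxelGrid", "BrainMask", function(x) x@grid)
setMethod("volData", "BrainMask", function(x) x@data)
setMethod("nVoxels", "BrainMask", function(x) sum(x@data))

setMethod("show", "BrainMask", function(object) {
    cat(sprintf("BrainMask: %d in-mask voxels on ", nVoxels(object)))
    show(object@grid)
})

## ---------------------------------------------------------------------------
## ScalarVolume
## ---------------------------------------------------------------------------

.VOLUME_KINDS <- c("z", "mean_z", "t", "count", "fraction", "binary",
                   "contrast", "other")

#' ScalarVolume: a real-valued volume with a semantic kind
#'
#' Carries one scalar per voxel plus a \code{kind} tag recording what the
#' values mean (Fisher z, t statistic, overlap count/fraction, binary mask,
#' contrast). Out-of-mask voxels are stored as 0; statistics only ever read
#' in-mask voxels, so no NaN propagates into overlap counts.
#'
#' @slot grid a \linkS4class{VolumeGrid}.
#' @slot data numeric array of dimension \code{grid@shape}.
#' @slot kind one of \code{"z"}, \code{"mean_z"}, \code{"t"}, \code{"count"},
#'   \code{"fraction"}, \code{"binary"}, \code{"contrast"}, \code{"other"}.
#'
#' @param grid a \linkS4class{VolumeGrid}.
#' @param data numeric array.
#' @param kind character scalar kind tag.
#' @return a \code{ScalarVolume}.
#' @export ScalarVolume
#' @exportClass ScalarVolume
setClass("ScalarVolume",
    representation(grid = "VolumeGrid", data = "array", kind = "character"),
    validity = function(object) {
        msg <- character()
        if (!identical(dim(object@data), as.integer(object@grid@shape)))
            msg <- c(msg, "data dimensions must match grid shape")
        if (length(object@kind) != 1L || !(object@kind %in% .VOLUME_KINDS))
            msg <- c(msg, sprintf("kind must be one of: %s",
                                  paste(.VOLUME_KINDS, collapse = ", ")))
        else {
            fin <- object@data[is.finite(object@data)]
            if (object@kind == "binary" && length(fin) &&
                !all(fin %in% c(0, 1)))
                msg <- c(msg, "binary volume values must be 0/1")
            if (object@kind == "fraction" && length(fin) &&
                (min(fin) < 0 || max(fin) > 1))
                msg <- c(msg, "fraction volume values must lie in [0,1]")
        }
        if (length(msg)) msg else TRUE
    })

ScalarVolume <- function(grid, data, kind = "other") {
    d <- array(as.numeric(data), dim = grid@shape)
    new("ScalarVolume", grid = grid, data = d, kind = kind)
}

setMethod("voxelGrid", "ScalarVolume", function(x) x@grid)
setMethod("volData", "ScalarVolume", function(x) x@data)
setMethod("volKind", "ScalarVolume", function(x) x@kind)
setMethod("nVoxels", "ScalarVolume", function(x) sum(x@data != 0))

setMethod("show", "ScalarVolume", function(object) {
    rng <- range(object@data[is.finite(object@data)])
    cat(sprintf("ScalarVolume (kind=%s): range [%.4g, %.4g] on ",
        object@kind, rng[1], rng[2]))
    show(object@grid)
})

## ---------------------------------------------------------------------------
## StudyFociTable
## ---------------------------------------------------------------------------

#' StudyFociTable: per-study activation peak coordinates
#'
#' Holds the activation peaks reported by each study of the meta-analytic
#' corpus: study identifier, diagnostic group (\code{ASD} autistic,
#' \code{NT} neurotypical), world coordinates in mm, and coordinate space tag
#' (\code{MNI} or \code{TAL}). After \code{\link{normalizeToMni}} all entries
#' are MNI.
#'
#' @slot entries data.frame with columns \code{study_id}, \code{group},
#'   \code{x}, \code{y}, \code{z}, \code{space}.
#'
#' @param entries a data.frame as above.
#' @return a \code{StudyFociTable}.
#' @export StudyFociTable
#' @exportClass StudyFociTable
setClass("StudyFociTable",
    representation(entries = "data.frame"),
    validity = function(object) {
        req <- c("study_id", "group", "x", "y", "z", "space")
        msg <- character()
        miss <- setdiff(req, names(object@entries))
        if (length(miss))
            msg <- c(msg, sprintf("missing column(s): %s",
                                  paste(miss, collapse = ", ")))
        else {
            e <- object@entries
            if (nrow(e) == 0L)
                msg <- c(msg, "table must contain at least one focus")
            if (!all(e$group %in% c("ASD", "NT")))
                msg <- c(msg, "group must be ASD or NT")
            if (!all(e$space %in% c("MNI", "TAL")))
                msg <- c(msg, "space must be MNI or TAL")
            xyz <- as.matrix(e[, c("x", "y", "z")])
            if (!all(is.finite(xyz)))
                msg <- c(msg, "coordinates must be finite")
            else if (any(abs(xyz) >= 200))
                msg <- c(msg, "coordinates must satisfy |x|,|y|,|z| < 200 mm")
        }
        if (length(msg)) msg else TRUE
    })

StudyFociTable <- function(entries) {
    entries$study_id <- as.character(entries$study_id)
    entries$group <- as.character(entries$group)
    entries$space <- as.character(entries$space)
    for (cc in c("x", "y", "z")) entries[[cc]] <- as.numeric(entries[[cc]])
    new("StudyFociTable", entries = as.data.frame(entries,
                                                  stringsAsFactors = FALSE))
}

#' Foci of one group, split by study
#'
#' @param table a \linkS4class{StudyFociTable}.
#' @param group \code{"NT"} or \code{"ASD"}.
#' @return named list (study id) of data.frames of that study's foci.
#' @export
studyFoci <- function(table, group) {
    stopifnot(is(table, "StudyFociTable"), group %in% c("ASD", "NT"))
    e <- table@entries[table@entries$group == group, , drop = FALSE]
    split(e, e$study_id)
}

#' @rdname StudyFociTable-class
#' @param x a \linkS4class{StudyFociTable}.
#' @export
fociEntries <- function(x) x@entries

setMethod("show", "StudyFociTable", function(object) {
    e <- object@entries
    cat(sprintf("StudyFociTable: %d foci, %d studies (NT: %d, ASD: %d); spaces: %s\n",
        nrow(e), length(unique(e$study_id)),
        length(unique(e$study_id[e$group == "NT"])),
        length(unique(e$study_id[e$group == "ASD"])),
        paste(sort(unique(e$space)), collapse = ", ")))
})

## ---------------------------------------------------------------------------
## CoactivationSeed
## ---------------------------------------------------------------------------

#' CoactivationSeed: union of spheres around one study's peaks
#'
#' The per-study unit of the analysis: a binary volume formed by the voxelwise
#' union of fixed-radius spheres centred on every peak the study reported,
#' intersected with the brain mask.
#'
#' @slot studyId character study identifier.
#' @slot group \code{"ASD"} or \code{"NT"}.
#' @slot mask binary \linkS4class{ScalarVolume} on the pipeline grid.
#'
#' @export CoactivationSeed
#' @exportClass CoactivationSeed
setClass("CoactivationSeed",
    representation(studyId = "character", group = "character",
                   mask = "ScalarVolume"),
    validity = function(object) {
        msg <- character()
        if (object@mask@kind != "binary")
            msg <- c(msg, "seed mask must be a binary volume")
        if (sum(object@mask@data) < 1)
            msg <- c(msg, "seed must contain at least one voxel")
        if (!object@group %in% c("ASD", "NT"))
            msg <- c(msg, "group must be ASD or NT")
        if (length(msg)) msg else TRUE
    })

CoactivationSeed <- function(studyId, group, mask) {
    new("CoactivationSeed", studyId = as.character(studyId),
        group = as.character(group), mask = mask)
}

setMethod("voxelGrid", "CoactivationSeed", function(x) x@mask@grid)
setMethod("nVoxels", "CoactivationSeed", function(x) sum(x@mask@data))

setMethod("show", "CoactivationSeed", function(object) {
    cat(sprintf("CoactivationSeed: study %s (%s), %d voxels\n",
        object@studyId, object@group, nVoxels(object)))
})

## ---------------------------------------------------------------------------
## ParticipantTimeSeries
## ---------------------------------------------------------------------------

#' ParticipantTimeSeries: packed resting-state data of one participant
#'
#' A T x V matrix of one participant's voxel time series over the brain mask
#' (T timepoints, V in-mask voxels in the mask's fixed column-major voxel
#' ordering). This is the per-participant unit of the normative connectome.
#'
#' @slot participantId character identifier.
#' @slot mask the shared \linkS4class{BrainMask} defining the voxel ordering.
#' @slot data numeric T x V matrix, T >= 8.
#'
#' @export ParticipantTimeSeries
#' @exportClass ParticipantTimeSeries
setClass("ParticipantTimeSeries",
    representation(participantId = "character", mask = "BrainMask",
                   data = "matrix"),
    validity = function(object) {
        msg <- character()
        if (nrow(object@data) < 8L)
            msg <- c(msg, "need at least 8 timepoints")
        if (ncol(object@data) != nVoxels(object@mask))
            msg <- c(msg, "columns must equal the in-mask voxel count")
        if (!all(is.finite(object@data)))
            msg <- c(msg, "time series must be finite")
        if (length(msg)) msg else TRUE
    })

ParticipantTimeSeries <- function(participantId, mask, data) {
    new("ParticipantTimeSeries", participantId = as.character(participantId),
        mask = mask, data = data)
}

setMethod("voxelGrid", "ParticipantTimeSeries", function(x) x@mask@grid)

setMethod("show", "ParticipantTimeSeries", function(object) {
    cat(sprintf("ParticipantTimeSeries: %s, %d timepoints x %d voxels\n",
        object@participantId, nrow(object@data), ncol(object@data)))
})

## ---------------------------------------------------------------------------
## ExperimentZStack
## ---------------------------------------------------------------------------

#' ExperimentZStack: one study's Fisher z maps across connectome participants
#'
#' Rows are participants, columns are in-mask voxels (mask ordering); entry
#' (p, v) is participant p's Fisher z connectivity between the study's
#' coactivation seed and voxel v.
#'
#' @slot studyId character study identifier.
#' @slot group \code{"ASD"} or \code{"NT"}.
#' @slot mask the shared \linkS4class{BrainMask}.
#' @slot z numeric participants x voxels matrix, >= 3 rows.
#'
#' @export ExperimentZStack
#' @exportClass ExperimentZStack
setClass("ExperimentZStack",
    representation(studyId = "character", group = "character",
                   mask = "BrainMask", z = "matrix"),
    validity = function(object) {
        msg <- character()
        if (nrow(object@z) < 3L)
            msg <- c(msg, "need at least 3 participants")
        if (ncol(object@z) != nVoxels(object@mask))
            msg <- c(msg, "columns must equal the in-mask voxel count")
        if (length(msg)) msg else TRUE
    })

ExperimentZStack <- function(studyId, group, mask, z) {
    new("ExperimentZStack", studyId = as.character(studyId),
        group = as.character(group), mask = mask, z = z)
}

setMethod("show", "ExperimentZStack", function(object) {
    cat(sprintf("ExperimentZStack: study %s (%s), %d participants x %d voxels\n",
        object@studyId, object@group, nrow(object@z), ncol(object@z)))
})

## ---------------------------------------------------------------------------
## AnmConfig
## ---------------------------------------------------------------------------

#' AnmConfig: tunable parameters of the mapping pipeline
#'
#' @slot radius sphere radius in mm around each peak (default 6).
#' @slot tThreshold fixed critical t for binarisation and group-map
#'   thresholding (default 5.66, applied at both statistical levels).
#' @slot alpha two-sided alpha used when \code{thresholdMode="alpha_derived"};
#'   \code{NA} means 0.05 divided by the in-mask voxel count (voxelwise
#'   Bonferroni).
#' @slot overlapFraction strict retention fraction for the overlap map
#'   (default 0.60: a voxel is retained iff count/E > 0.60).
#' @slot thresholdMode \code{"fixed_t"} (use \code{tThreshold}) or
#'   \code{"alpha_derived"} (use \code{\link{criticalT}} at the stack's df).
#' @slot contrastMode \code{"set_difference"}, \code{"proportion_test"} or
#'   \code{"two_sample_t"}.
#' @slot similarityOperands \code{"unthresholded"} (correlate the overlap
#'   fraction volume with the unthresholded t volume) or \code{"binarized"}.
#' @slot excludeSeedVoxels zero the seed's own voxels in each Fisher z map
#'   (default FALSE: seed self-connectivity is kept).
#' @slot clipR correlations are clipped to +/- clipR before atanh (default
#'   1 - 1e-7) so z stays finite.
#' @slot rngSeed integer seed recorded in provenance.
#'
#' @param ... named slot overrides, e.g. \code{anmConfig(tThreshold = 4)}.
#' @return an \code{AnmConfig}.
#' @export anmConfig
#' @exportClass AnmConfig
#' @examples
#' cfg <- anmConfig(overlapFraction = 0.5)
#' cfg
setClass("AnmConfig",
    representation(radius = "numeric", tThreshold = "numeric",
                   alpha = "numeric", overlapFraction = "numeric",
                   thresholdMode = "character", contrastMode = "character",
                   similarityOperands = "character",
                   excludeSeedVoxels = "logical", clipR = "numeric",
                   rngSeed = "integer"),
    prototype(radius = 6, tThreshold = 5.66, alpha = NA_real_,
              overlapFraction = 0.60, thresholdMode = "fixed_t",
              contrastMode = "set_difference",
              similarityOperands = "unthresholded",
              excludeSeedVoxels = FALSE, clipR = 1 - 1e-7, rngSeed = 1L),
    validity = function(object) {
        msg <- character()
        if (object@radius <= 0) msg <- c(msg, "radius must be > 0")
        if (object@tThreshold <= 0) msg <- c(msg, "tThreshold must be > 0")
        if (!is.na(object@alpha) &&
            (object@alpha <= 0 || object@alpha >= 1))
            msg <- c(msg, "alpha must lie in (0,1)")
        if (object@overlapFraction <= 0 || object@overlapFraction >= 1)
            msg <- c(msg, "overlapFraction must lie in (0,1)")
        if (!object@thresholdMode %in% c("fixed_t", "alpha_derived"))
            msg <- c(msg, "thresholdMode must be fixed_t or alpha_derived")
        if (!object@contrastMode %in%
            c("set_difference", "proportion_test", "two_sample_t"))
            msg <- c(msg, "unknown contrastMode")
        if (!object@similarityOperands %in% c("unthresholded", "binarized"))
            msg <- c(msg, "similarityOperands must be unthresholded or binarized")
        if (object@clipR <= 0 || object@clipR >= 1)
            msg <- c(msg, "clipR must lie in (0,1)")
        if (length(msg)) msg else TRUE
    })

anmConfig <- function(...) {
    args <- list(...)
    if ("rngSeed" %in% names(args))
        args$rngSeed <- as.integer(args$rngSeed)
    do.call(new, c(list(Class = "AnmConfig"), args))
}

setMethod("show", "AnmConfig", function(object) {
    cat(sprintf(
        paste0("AnmConfig: radius=%g mm, t>%g (%s), overlap fraction>%g,\n",
               "  contrast=%s, similarity operands=%s, seed voxels %s, seed=%d\n"),
        object@radius, object@tThreshold, object@thresholdMode,
        object@overlapFraction, object@contrastMode,
        object@similarityOperands,
        if (object@excludeSeedVoxels) "excluded" else "included",
        object@rngSeed))
})

## ---------------------------------------------------------------------------
## OverlapMap / GroupTMap / ContrastResult
## ---------------------------------------------------------------------------

#' OverlapMap: group-level network by seed-overlap counting
#'
#' Voxelwise count of experiments whose binarised connectivity t map covers
#' the voxel, the corresponding fraction count/E, and the retained mask
#' (fraction strictly greater than the configured overlap fraction).
#'
#' @slot group \code{"ASD"} or \code{"NT"}.
#' @slot count \linkS4class{ScalarVolume} kind \code{count}.
#' @slot fraction \linkS4class{ScalarVolume} kind \code{fraction}.
#' @slot retained binary \linkS4class{ScalarVolume}.
#' @slot nExperiments integer E.
#'
#' @export OverlapMap
#' @exportClass OverlapMap
setClass("OverlapMap",
    representation(group = "character", count = "ScalarVolume",
                   fraction = "ScalarVolume", retained = "ScalarVolume",
                   nExperiments = "integer"),
    validity = function(object) {
        msg <- character()
        if (object@nExperiments < 1L)
            msg <- c(msg, "need at least one experiment")
        if (max(object@count@data) > object@nExperiments + 1e-9)
            msg <- c(msg, "count exceeds number of experiments")
        if (min(object@count@data) < 0)
            msg <- c(msg, "count must be non-negative")
        if (length(msg)) msg else TRUE
    })

OverlapMap <- function(group, count, fraction, retained, nExperiments) {
    new("OverlapMap", group = group, count = count, fraction = fraction,
        retained = retained, nExperiments = as.integer(nExperiments))
}

setMethod("voxelGrid", "OverlapMap", function(x) x@count@grid)
setMethod("nVoxels", "OverlapMap", function(x) sum(x@retained@data > 0))

setMethod("show", "OverlapMap", function(object) {
    cat(sprintf("OverlapMap (%s): E=%d experiments, %d voxels retained\n",
        object@group, object@nExperiments, nVoxels(object)))
})

#' GroupTMap: group-level network by one-sample t on mean Fisher z
#'
#' Voxelwise one-sample t statistic, across experiments, of experiment-level
#' mean Fisher z maps against zero, with its thresholded binary mask.
#'
#' @slot group \code{"ASD"} or \code{"NT"}.
#' @slot t \linkS4class{ScalarVolume} kind \code{t}.
#' @slot thresholded binary \linkS4class{ScalarVolume} (t strictly above the
#'   configured threshold, in-mask).
#' @slot df integer degrees of freedom (E - 1).
#'
#' @export GroupTMap
#' @exportClass GroupTMap
setClass("GroupTMap",
    representation(group = "character", t = "ScalarVolume",
                   thresholded = "ScalarVolume", df = "integer"),
    validity = function(object) {
        if (object@df < 2L) "df must be >= 2 (at least 3 experiments)" else TRUE
    })

GroupTMap <- function(group, t, thresholded, df) {
    new("GroupTMap", group = group, t = t, thresholded = thresholded,
        df = as.integer(df))
}

setMethod("voxelGrid", "GroupTMap", function(x) x@t@grid)
setMethod("nVoxels", "GroupTMap", function(x) sum(x@thresholded@data > 0))

setMethod("show", "GroupTMap", function(object) {
    cat(sprintf("GroupTMap (%s): df=%d, %d voxels above threshold\n",
        object@group, object@df, nVoxels(object)))
})

#' ContrastResult: voxelwise group contrast of network maps
#'
#' Both directions of the NT vs autistic contrast, with the mode that
#' produced them and a provenance snapshot. In \code{set_difference} mode the
#' two volumes are binary and disjoint.
#'
#' @slot mode contrast mode tag.
#' @slot ntMinusAsd \linkS4class{ScalarVolume}.
#' @slot asdMinusNt \linkS4class{ScalarVolume}.
#' @slot provenance list (config snapshot, operand choices).
#'
#' @export ContrastResult
#' @exportClass ContrastResult
setClass("ContrastResult",
    representation(mode = "character", ntMinusAsd = "ScalarVolume",
                   asdMinusNt = "ScalarVolume", provenance = "list"),
    validity = function(object) {
        if (object@mode == "set_difference" &&
            any(object@ntMinusAsd@data * object@asdMinusNt@data != 0))
            "set-difference contrast volumes must be disjoint" else TRUE
    })

ContrastResult <- function(mode, ntMinusAsd, asdMinusNt,
                           provenance = list()) {
    new("ContrastResult", mode = mode, ntMinusAsd = ntMinusAsd,
        asdMinusNt = asdMinusNt, provenance = provenance)
}

setMethod("show", "ContrastResult", function(object) {
    cat(sprintf("ContrastResult (%s): NT-ASD %d voxels, ASD-NT %d voxels\n",
        object@mode, sum(object@ntMinusAsd@data != 0),
        sum(object@asdMinusNt@data != 0)))
})

## ---------------------------------------------------------------------------
## AtlasVolume
## ---------------------------------------------------------------------------

#' AtlasVolume: integer-labelled parcellation with a name lookup
#'
#' Grid-aligned integer label volume (0 = unlabeled) plus a lookup table
#' mapping each nonzero label id to a region name and scheme (e.g. AAL or
#' Brodmann), used to name peak coordinates.
#'
#' @slot volume \linkS4class{ScalarVolume} with integer-valued data.
#' @slot lookup data.frame with columns \code{label}, \code{name},
#'   \code{scheme}.
#'
#' @export AtlasVolume
#' @exportClass AtlasVolume
setClass("AtlasVolume",
    representation(volume = "ScalarVolume", lookup = "data.frame"),
    validity = function(object) {
        msg <- character()
        req <- c("label", "name", "scheme")
        if (!all(req %in% names(object@lookup)))
            msg <- c(msg, "lookup needs columns label, name, scheme")
        else {
            ids <- setdiff(unique(as.vector(object@volume@data)), 0)
            miss <- setdiff(ids, object@lookup$label)
            if (length(miss))
                msg <- c(msg, sprintf("label id(s) missing from lookup: %s",
                                      paste(miss, collapse = ", ")))
        }
        if (any(object@volume@data != round(object@volume@data)))
            msg <- c(msg, "atlas labels must be integers")
        if (length(msg)) msg else TRUE
    })

AtlasVolume <- function(volume, lookup) {
    lookup$label <- as.integer(lookup$label)
    lookup$name <- as.character(lookup$name)
    lookup$scheme <- as.character(lookup$scheme)
    new("AtlasVolume", volume = volume, lookup = lookup)
}

setMethod("voxelGrid", "AtlasVolume", function(x) x@volume@grid)

setMethod("show", "AtlasVolume", function(object) {
    cat(sprintf("AtlasVolume: %d labelled regions (%s)\n",
        nrow(object@lookup),
        paste(unique(object@lookup$scheme), collapse = ", ")))
})

## ---------------------------------------------------------------------------
## SyntheticSpec / GroundTruth
## ---------------------------------------------------------------------------

#' SyntheticSpec: design of the synthetic normative connectome
#'
#' Declares the simulated study conditions: grid geometry, participant and
#' timepoint counts, the planted networks (axis-aligned voxel blocks whose
#' voxels share a latent signal), noise level, and the per-group study corpus
#' (how many foci each study reports and which planted network(s) they
#' target). The expected within-network correlation is
#' rho = signalSd^2 / (signalSd^2 + noiseSd^2).
#'
#' @slot shape integer length-3 grid shape.
#' @slot voxelSizeMm numeric isotropic voxel edge in mm.
#' @slot nParticipants integer number of simulated participants.
#' @slot nTimepoints integer timepoints T per participant.
#' @slot networks named list; each element \code{list(origin=, size=)} gives
#'   a block's 0-based corner voxel and its extent in voxels.
#' @slot signalSd numeric sd of each network's latent signal.
#' @slot noiseSd numeric sd of i.i.d. voxel noise.
#' @slot studies data.frame with columns \code{study_id}, \code{group},
#'   \code{n_foci}, \code{targets} (comma-separated network ids, or
#'   \code{"none"} for foci in unstructured tissue).
#' @slot fociJitterMm numeric max isotropic jitter applied to each focus.
#' @slot rngSeed integer master seed; participants and studies consume
#'   independent substreams derived from it, so earlier entities are
#'   unchanged when counts grow.
#'
#' @param ... named slot overrides of the defaults (see
#'   \code{\link{defaultSyntheticSpec}}).
#' @return a \code{SyntheticSpec}.
#' @export syntheticSpec
#' @exportClass SyntheticSpec
setClass("SyntheticSpec",
    representation(shape = "integer", voxelSizeMm = "numeric",
                   nParticipants = "integer", nTimepoints = "integer",
                   networks = "list", signalSd = "numeric",
                   noiseSd = "numeric", studies = "data.frame",
                   fociJitterMm = "numeric", rngSeed = "integer"),
    validity = function(object) {
        msg <- character()
        if (length(object@shape) != 3L || any(object@shape < 2L))
            msg <- c(msg, "shape must be 3 integers >= 2")
        if (object@voxelSizeMm <= 0)
            msg <- c(msg, "voxelSizeMm must be > 0")
        if (object@nParticipants < 1L)
            msg <- c(msg, "need at least one participant")
        if (object@nTimepoints < 8L)
            msg <- c(msg, "need at least 8 timepoints")
        if (object@signalSd < 0 || object@noiseSd < 0)
            msg <- c(msg, "signalSd and noiseSd must be >= 0")
        if (object@fociJitterMm < 0)
            msg <- c(msg, "fociJitterMm must be >= 0")
        if (is.null(names(object@networks)) &&
            length(object@networks) > 0L)
            msg <- c(msg, "networks must be a named list")
        for (nm in names(object@networks)) {
            nw <- object@networks[[nm]]
            if (!all(c("origin", "size") %in% names(nw)))
                msg <- c(msg, sprintf("network %s needs origin and size", nm))
            else if (any(nw$origin < 0) ||
                     any(nw$origin + nw$size > object@shape))
                msg <- c(msg, sprintf("network %s exceeds the grid", nm))
        }
        ## pairwise disjointness of planted blocks
        if (length(object@networks) > 1L && length(msg) == 0L) {
            occ <- array(0L, object@shape)
            for (nw in object@networks) {
                ix <- lapply(1:3, function(d)
                    seq.int(nw$origin[d] + 1L, nw$origin[d] + nw$size[d]))
                occ[ix[[1]], ix[[2]], ix[[3]]] <-
                    occ[ix[[1]], ix[[2]], ix[[3]]] + 1L
            }
            if (any(occ > 1L))
                msg <- c(msg, "networks must be pairwise disjoint")
        }
        st <- object@studies
        req <- c("study_id", "group", "n_foci", "targets")
        if (!all(req %in% names(st)))
            msg <- c(msg, "studies needs study_id, group, n_foci, targets")
        else {
            tgt <- setdiff(unlist(strsplit(st$targets, ",")), "none")
            miss <- setdiff(tgt, names(object@networks))
            if (length(miss))
                msg <- c(msg, sprintf("unknown target network(s): %s",
                                      paste(unique(miss), collapse = ", ")))
            if (!all(st$group %in% c("ASD", "NT")))
                msg <- c(msg, "study group must be ASD or NT")
            if (any(st$n_foci < 1))
                msg <- c(msg, "each study needs >= 1 focus")
        }
        if (length(msg)) msg else TRUE
    })

syntheticSpec <- function(...) {
    args <- list(...)
    def <- defaultSyntheticSpec()
    for (nm in names(args)) slot(def, nm) <- .coerceSpecSlot(nm, args[[nm]])
    validObject(def)
    def
}

.coerceSpecSlot <- function(nm, val) {
    if (nm %in% c("shape", "nParticipants", "nTimepoints", "rngSeed"))
        as.integer(val) else val
}

setMethod("show", "SyntheticSpec", function(object) {
    cat(sprintf(
        paste0("SyntheticSpec: %dx%dx%d @ %g mm, %d participants x %d timepoints\n",
               "  %d networks, signalSd=%g noiseSd=%g (rho=%.3g), %d studies, seed=%d\n"),
        object@shape[1], object@shape[2], object@shape[3], object@voxelSizeMm,
        object@nParticipants, object@nTimepoints, length(object@networks),
        object@signalSd, object@noiseSd,
        object@signalSd^2 / (object@signalSd^2 + object@noiseSd^2),
        nrow(object@studies), object@rngSeed))
})

#' GroundTruth: planted-network answer key for a synthetic run
#'
#' Per-network binary masks plus, per group, the retained mask the pipeline
#' is expected to recover: the union of networks targeted by strictly more
#' than the configured overlap fraction of that group's studies.
#'
#' @slot networks named list of binary \linkS4class{ScalarVolume}s.
#' @slot expectedRetained named list (\code{NT}, \code{ASD}) of binary
#'   \linkS4class{ScalarVolume}s.
#'
#' @export GroundTruth
#' @exportClass GroundTruth
setClass("GroundTruth",
    representation(networks = "list", expectedRetained = "list"))

GroundTruth <- function(networks, expectedRetained) {
    new("GroundTruth", networks = networks,
        expectedRetained = expectedRetained)
}

setMethod("show", "GroundTruth", function(object) {
    cat(sprintf("GroundTruth: %d networks; expected retained NT=%d, ASD=%d voxels\n",
        length(object@networks),
        sum(object@expectedRetained$NT@data),
        sum(object@expectedRetained$ASD@data)))
})
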