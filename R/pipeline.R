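#' @include AllClasses.R
NULL

#' Run the full mapping pipeline for one group
#'
#' Orchestrates, for one diagnostic group: foci normalisation to MNI,
#' per-study coactivation seed construction, participant-level Fisher z
#' connectivity, and both group-level branches (overlap map and t map). All
#' volumes must share one grid; a mismatch is an error, never a resample.
#' When \code{outDir} is given, all result volumes plus a JSON run manifest
#' (config snapshot and hash, input hashes, per-stage counts, warnings,
#' software version, timestamp) are written there.
#'
#' @param foci a \linkS4class{StudyFociTable} or path to a foci TSV.
#' @param participants list of \linkS4class{ParticipantTimeSeries} (the
#'   normative connectome).
#' @param mask the shared \linkS4class{BrainMask}.
#' @param group \code{"NT"} or \code{"ASD"}.
#' @param config an \linkS4class{AnmConfig}.
#' @param outDir optional output directory (created if missing).
#' @return list with \code{overlap}, \code{tmap}, \code{stacks},
#'   \code{meanZ}, \code{experimentT}, \code{seeds}, \code{manifest}.
#' @export
runGroup <- function(foci, participants, mask, group,
                     config = anmConfig(), outDir = NULL) {
    t0 <- Sys.time()
    fociPath <- NULL
    if (is.character(foci)) {
        fociPath <- foci
        foci <- readFoci(foci)
    }
    warnings <- character()
    withCallingHandlers({
        foci <- suppressMessages(normalizeToMni(foci))
        nStudies <- length(studyFoci(foci, group))
        if (nStudies < 3L)
            stop("too few experiments in group ", group, ": ", nStudies)
        seeds <- lapply(studyFoci(foci, group), function(f)
            makeCoactivationSeed(f, radius = config@radius,
                                 grid = mask@grid, mask = mask))
        stacks <- buildZStacks(foci, participants, mask, group, config)
        maps <- buildGroupMaps(stacks, mask, config, group = group)
    }, warning = function(w) {
        warnings <<- c(warnings, conditionMessage(w))
        invokeRestart("muffleWarning")
    })
    manifest <- list(
        stage = "run_group", group = group,
        config = configSnapshot(config), config_hash = configHash(config),
        inputs = if (is.null(fociPath)) list() else fileHashes(fociPath),
        n_studies = nStudies,
        n_participants = length(participants),
        n_mask_voxels = nVoxels(mask),
        seed_voxels = vapply(seeds, function(s) as.integer(nVoxels(s)), 1L),
        n_retained_overlap = sum(maps$overlap@retained@data),
        n_retained_tmap = sum(maps$tmap@thresholded@data),
        warnings = warnings,
        version = as.character(utils::packageVersion("ANMtools")),
        timestamp = format(t0, "%Y-%m-%dT%H:%M:%S%z"))
    res <- list(overlap = maps$overlap, tmap = maps$tmap, stacks = stacks,
                meanZ = maps$meanZ, experimentT = maps$experimentT,
                seeds = seeds, manifest = manifest)
    if (!is.null(outDir)) {
        dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
        pfx <- file.path(outDir, tolower(group))
        outs <- c(overlap_count = paste0(pfx, "_overlap_count.nii.gz"),
                  overlap_fraction = paste0(pfx, "_overlap_fraction.nii.gz"),
                  overlap_retained = paste0(pfx, "_overlap_retained.nii.gz"),
                  tmap_t = paste0(pfx, "_tmap.nii.gz"),
                  tmap_thresholded = paste0(pfx, "_tmap_thresholded.nii.gz"))
        writeVolume(maps$overlap@count, outs[["overlap_count"]])
        writeVolume(maps$overlap@fraction, outs[["overlap_fraction"]])
        writeVolume(maps$overlap@retained, outs[["overlap_retained"]])
        writeVolume(maps$tmap@t, outs[["tmap_t"]])
        writeVolume(maps$tmap@thresholded, outs[["tmap_thresholded"]])
        for (sid in names(seeds))
            writeVolume(seeds[[sid]]@mask,
                        file.path(outDir, sprintf("seed_%s.nii.gz", sid)))
        manifest$outputs <- as.list(outs)
        res$manifest <- manifest
        writeManifest(manifest, paste0(pfx, "_manifest.json"))
    }
    res
}

#' Contrast two group runs and score map similarity
#'
#' Applies the configured group contrast to both branches (overlap and t
#' map) and computes each group's overlap-vs-t-map similarity (Pearson
#' correlation over in-mask voxels of the unthresholded fraction and t
#' volumes by default, or of the binarised volumes when
#' \code{config@similarityOperands = "binarized"}). Operand choices are
#' recorded in the manifest.
#'
#' @param nt,asd results of \code{\link{runGroup}} for each group.
#' @param mask the shared \linkS4class{BrainMask}.
#' @param config an \linkS4class{AnmConfig} (must match the one used for the
#'   group runs).
#' @param outDir optional output directory.
#' @return list with \code{contrastOverlap}, \code{contrastTmap}
#'   (\linkS4class{ContrastResult}s), \code{similarity} (named numeric, one
#'   value per group) and \code{manifest}.
#' @export
runCompare <- function(nt, asd, mask, config = anmConfig(),
                       outDir = NULL) {
    t0 <- Sys.time()
    stopifnot(sameGrid(voxelGrid(nt$overlap), voxelGrid(asd$overlap)))
    if (!identical(nt$manifest$config_hash, asd$manifest$config_hash))
        stop("group runs were produced under different configs")
    co <- contrastMaps(nt, asd, config, mask, which = "overlap")
    ct <- contrastMaps(nt, asd, config, mask, which = "tmap")
    simOf <- function(res) {
        if (config@similarityOperands == "unthresholded")
            mapSimilarity(res$overlap@fraction, res$tmap@t, mask)
        else
            mapSimilarity(res$overlap@retained, res$tmap@thresholded, mask)
    }
    sim <- c(NT = simOf(nt), ASD = simOf(asd))
    manifest <- list(
        stage = "run_compare",
        config = configSnapshot(config), config_hash = configHash(config),
        similarity_operands = config@similarityOperands,
        similarity = as.list(sim),
        contrast_mode = config@contrastMode,
        n_nt_minus_asd_overlap = sum(co@ntMinusAsd@data != 0),
        n_asd_minus_nt_overlap = sum(co@asdMinusNt@data != 0),
        n_nt_minus_asd_tmap = sum(ct@ntMinusAsd@data != 0),
        n_asd_minus_nt_tmap = sum(ct@asdMinusNt@data != 0),
        version = as.character(utils::packageVersion("ANMtools")),
        timestamp = format(t0, "%Y-%m-%dT%H:%M:%S%z"))
    if (!is.null(outDir)) {
        dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
        outs <- c(
            overlap_nt_minus_asd = file.path(outDir, "contrast_overlap_nt_minus_asd.nii.gz"),
            overlap_asd_minus_nt = file.path(outDir, "contrast_overlap_asd_minus_nt.nii.gz"),
            tmap_nt_minus_asd = file.path(outDir, "contrast_tmap_nt_minus_asd.nii.gz"),
            tmap_asd_minus_nt = file.path(outDir, "contrast_tmap_asd_minus_nt.nii.gz"))
        writeVolume(co@ntMinusAsd, outs[["overlap_nt_minus_asd"]])
        writeVolume(co@asdMinusNt, outs[["overlap_asd_minus_nt"]])
        writeVolume(ct@ntMinusAsd, outs[["tmap_nt_minus_asd"]])
        writeVolume(ct@asdMinusNt, outs[["tmap_asd_minus_nt"]])
        manifest$outputs <- as.list(outs)
        writeManifest(manifest, file.path(outDir, "compare_manifest.json"))
    }
    list(contrastOverlap = co, contrastTmap = ct, similarity = sim,
         manifest = manifest)
}
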