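#' @include AllClasses.R
NULL

#' Read an atlas (integer NIfTI + TSV lookup)
#'
#' @param niftiPath integer-labelled NIfTI on the pipeline grid (0 =
#'   unlabeled).
#' @param lookupPath TSV with columns \code{label}, \code{name},
#'   \code{scheme}.
#' @return an \linkS4class{AtlasVolume}.
#' @export
readAtlas <- function(niftiPath, lookupPath) {
    vol <- readVolume(niftiPath, asMask = FALSE, kind = "other")
    lk <- utils::read.delim(lookupPath, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
    AtlasVolume(vol, lk)
}

#' Extract peaks from a statistic or binary volume
#'
#' For graded volumes: strict local maxima over the 26-neighbourhood within
#' the mask, accepted greedily in descending value order subject to pairwise
#' world distance >= \code{minDistanceMm}; ties are broken by (x, y, z)
#' lexicographic order of the world coordinate. For binary volumes: one peak
#' per 26-connected component, the voxel closest to the component's
#' world-coordinate center of mass (ties again lexicographic).
#'
#' @param vol a \linkS4class{ScalarVolume}.
#' @param mask a \linkS4class{BrainMask}; only in-mask voxels are scanned.
#' @param minDistanceMm minimum pairwise peak separation in mm (default 8).
#' @param maxPeaks maximum number of peaks returned (default unlimited).
#' @return data.frame with columns \code{x, y, z} (MNI mm), \code{value},
#'   \code{i, j, k} (0-based voxel index); zero rows for an empty map.
#' @export
findPeaks <- function(vol, mask, minDistanceMm = 8, maxPeaks = Inf) {
    stopifnot(minDistanceMm >= 0, sameGrid(vol@grid, mask@grid))
    d <- vol@data
    d[!mask@data] <- 0
    if (all(d == 0)) return(.emptyPeaks())
    if (vol@kind == "binary")
        return(.componentPeaks(d, vol@grid, maxPeaks))
    .localMaximaPeaks(d, vol@grid, mask, minDistanceMm, maxPeaks)
}

.emptyPeaks <- function() {
    data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
               value = numeric(0), i = integer(0), j = integer(0),
               k = integer(0))
}

## strict 26-neighbourhood local maxima + greedy distance suppression
.localMaximaPeaks <- function(d, grid, mask, minDistanceMm, maxPeaks) {
    sh <- dim(d)
    offs <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
    offs <- offs[rowSums(offs == 0) != 3L, , drop = FALSE]
    ## pad with -Inf so border voxels compare against nothing
    pad <- array(-Inf, sh + 2L)
    pad[2:(sh[1] + 1), 2:(sh[2] + 1), 2:(sh[3] + 1)] <- ifelse(mask@data, d, -Inf)
    core <- function(oi, oj, ok)
        pad[(2 + oi):(sh[1] + 1 + oi),
            (2 + oj):(sh[2] + 1 + oj),
            (2 + ok):(sh[3] + 1 + ok)]
    isMax <- mask@data & d != 0
    for (r in seq_len(nrow(offs))) {
        nb <- core(offs[r, 1], offs[r, 2], offs[r, 3])
        isMax <- isMax & (d > nb)
        if (!any(isMax)) break
    }
    lin <- which(isMax)
    if (length(lin) == 0L) return(.emptyPeaks())
    ijk <- arrayInd(lin, .dim = sh) - 1L
    w <- voxelToWorld(grid, ijk)
    vals <- d[lin]
    ord <- order(-vals, w[, 1], w[, 2], w[, 3])
    sel <- integer(0)
    for (cand in ord) {
        if (length(sel) >= maxPeaks) break
        if (length(sel) == 0L) { sel <- cand; next }
        dd <- sqrt(rowSums((w[sel, , drop = FALSE] -
                            matrix(w[cand, ], length(sel), 3,
                                   byrow = TRUE))^2))
        if (all(dd >= minDistanceMm)) sel <- c(sel, cand)
    }
    data.frame(x = w[sel, 1], y = w[sel, 2], z = w[sel, 3],
               value = vals[sel],
               i = ijk[sel, 1], j = ijk[sel, 2], k = ijk[sel, 3])
}

## one representative voxel per 26-connected component of a binary volume
.componentPeaks <- function(d, grid, maxPeaks) {
    labs <- labelComponents(d != 0)
    ncomp <- max(labs)
    if (ncomp == 0L) return(.emptyPeaks())
    rows <- vector("list", ncomp)
    for (cc in seq_len(ncomp)) {
        lin <- which(labs == cc)
        ijk <- arrayInd(lin, .dim = dim(d)) - 1L
        w <- voxelToWorld(grid, ijk)
        com <- colMeans(w)
        dist <- rowSums((w - matrix(com, nrow(w), 3, byrow = TRUE))^2)
        ord <- order(dist, w[, 1], w[, 2], w[, 3])
        b <- ord[1]
        rows[[cc]] <- data.frame(x = w[b, 1], y = w[b, 2], z = w[b, 3],
                                 value = 1, i = ijk[b, 1], j = ijk[b, 2],
                                 k = ijk[b, 3], size = length(lin))
    }
    out <- do.call(rbind, rows)
    out <- out[order(-out$size, out$x, out$y, out$z), , drop = FALSE]
    out$size <- NULL
    rownames(out) <- NULL
    utils::head(out, maxPeaks)
}

#' Label 26-connected components of a logical 3-D array
#'
#' Vectorised frontier-expansion flood fill over the 26-neighbourhood.
#' Small grids only; used for binary-map peak extraction.
#'
#' @param x logical 3-D array.
#' @return integer array of the same shape: 0 background, 1..n component ids.
#' @export
labelComponents <- function(x) {
    sh <- dim(x)
    stopifnot(length(sh) == 3L)
    offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
    offs <- offs[rowSums(offs == 0) != 3L, , drop = FALSE]
    labs <- array(0L, sh)
    todo <- which(x)
    nextLab <- 0L
    while (length(todo)) {
        seed <- todo[1]
        nextLab <- nextLab + 1L
        frontier <- seed
        labs[seed] <- nextLab
        while (length(frontier)) {
            ijk <- arrayInd(frontier, .dim = sh)
            nb <- do.call(rbind, lapply(seq_len(nrow(offs)), function(r)
                sweep(ijk, 2L, -offs[r, ], check.margin = FALSE)))
            ok <- nb[, 1] >= 1 & nb[, 1] <= sh[1] &
                  nb[, 2] >= 1 & nb[, 2] <= sh[2] &
                  nb[, 3] >= 1 & nb[, 3] <= sh[3]
            nb <- nb[ok, , drop = FALSE]
            lin <- unique(nb[, 1] + sh[1] * (nb[, 2] - 1L) +
                          sh[1] * sh[2] * (nb[, 3] - 1L))
            lin <- lin[x[lin] & labs[lin] == 0L]
            labs[lin] <- nextLab
            frontier <- lin
        }
        todo <- todo[labs[todo] == 0L]
    }
    labs
}

#' Label one coordinate against an atlas
#'
#' Returns the atlas name at the containing voxel; if that voxel is
#' unlabeled, the nearest nonzero label within \code{searchRadiusMm}
#' (world-distance, ties by smaller distance then lexicographic coordinate);
#' otherwise \code{"Unlabeled"}.
#'
#' @param xyz numeric length-3 MNI mm coordinate.
#' @param atlas an \linkS4class{AtlasVolume} on the pipeline grid.
#' @param searchRadiusMm fallback search radius in mm (default 5).
#' @return character label.
#' @export
labelPeak <- function(xyz, atlas, searchRadiusMm = 5) {
    grid <- atlas@volume@grid
    v <- worldToVoxelNearest(grid, xyz)
    lab <- 0
    if (all(v >= 0) && all(v < grid@shape))
        lab <- atlas@volume@data[v[1] + 1, v[2] + 1, v[3] + 1]
    if (lab == 0 && searchRadiusMm > 0) {
        lin <- which(atlas@volume@data != 0)
        if (length(lin)) {
            w <- voxelCenters(grid, lin)
            d2 <- rowSums((w - matrix(xyz, length(lin), 3, byrow = TRUE))^2)
            ord <- order(d2, w[, 1], w[, 2], w[, 3])
            if (d2[ord[1]] <= searchRadiusMm^2)
                lab <- atlas@volume@data[lin[ord[1]]]
        }
    }
    if (lab == 0) return("Unlabeled")
    atlas@lookup$name[match(lab, atlas@lookup$label)]
}

#' Labeled peak tables for group and contrast maps
#'
#' Emits one table per map in the layout of the published peak tables: map
#' type, MNI coordinates, peak value, and one label column per atlas
#' (typically AAL and Brodmann). Overlap-map peaks are taken from the
#' connected components of the retained mask, valued and ordered by the
#' overlap fraction (descending); t-map peaks are local maxima of the t
#' volume within the thresholded mask, ordered by t; binary contrast maps
#' use component peaks. Output is deterministic: identical inputs give a
#' byte-identical file.
#'
#' @param maps named list; elements may be \linkS4class{OverlapMap},
#'   \linkS4class{GroupTMap}, \linkS4class{ContrastResult} (both directions
#'   reported) or \linkS4class{ScalarVolume}.
#' @param atlases named list of \linkS4class{AtlasVolume}s (e.g.
#'   \code{list(AAL = ..., BA = ...)}); may be empty.
#' @param mask the shared \linkS4class{BrainMask}.
#' @param path optional output TSV path; written with \code{write.table}.
#' @param minDistanceMm peak separation passed to \code{\link{findPeaks}}.
#' @param maxPeaks cap per map.
#' @return data.frame of all rows (column \code{map_type} distinguishes
#'   maps), invisibly also written to \code{path} when given.
#' @export
makeReport <- function(maps, atlases = list(), mask, path = NULL,
                       minDistanceMm = 8, maxPeaks = 50) {
    rows <- list()
    for (nm in names(maps)) {
        m <- maps[[nm]]
        if (is(m, "OverlapMap")) {
            pk <- findPeaks(m@retained, mask, minDistanceMm, maxPeaks)
            if (nrow(pk))
                pk$value <- m@fraction@data[cbind(pk$i + 1, pk$j + 1,
                                                  pk$k + 1)]
            pk <- pk[order(-pk$value, pk$x, pk$y, pk$z), , drop = FALSE]
        } else if (is(m, "GroupTMap")) {
            tmasked <- m@t
            tmasked@data[m@thresholded@data == 0] <- 0
            pk <- findPeaks(tmasked, mask, minDistanceMm, maxPeaks)
            pk <- pk[order(-pk$value, pk$x, pk$y, pk$z), , drop = FALSE]
        } else if (is(m, "ContrastResult")) {
            sub <- makeReport(list(nt_minus_asd = m@ntMinusAsd,
                                   asd_minus_nt = m@asdMinusNt),
                              atlases, mask, path = NULL,
                              minDistanceMm = minDistanceMm,
                              maxPeaks = maxPeaks)
            if (nrow(sub)) sub$map_type <- paste(nm, sub$map_type, sep = ":")
            rows[[nm]] <- sub
            next
        } else if (is(m, "ScalarVolume")) {
            pk <- findPeaks(m, mask, minDistanceMm, maxPeaks)
            pk <- pk[order(-pk$value, pk$x, pk$y, pk$z), , drop = FALSE]
        } else stop("unsupported map object: ", class(m))
        rows[[nm]] <- .labelPeakTable(pk, nm, atlases)
    }
    out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
    if (is.null(out)) out <- .labelPeakTable(.emptyPeaks(), "none", atlases)[0, ]
    rownames(out) <- NULL
    if (!is.null(path)) {
        utils::write.table(format(out, digits = 6, trim = TRUE,
                                  scientific = FALSE),
                           path, sep = "\t", quote = FALSE,
                           row.names = FALSE, fileEncoding = "UTF-8")
    }
    invisible(out)
}

.labelPeakTable <- function(pk, mapName, atlases) {
    base <- data.frame(map_type = rep(mapName, nrow(pk)),
                       x = pk$x, y = pk$y, z = pk$z, value = pk$value)
    for (anm in names(atlases)) {
        lab <- character(nrow(pk))
        for (r in seq_len(nrow(pk)))
            lab[r] <- labelPeak(c(pk$x[r], pk$y[r], pk$z[r]), atlases[[anm]])
        base[[paste0(anm, "_label")]] <- lab
    }
    base
}
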