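#' @include AllClasses.R
NULL

#' Default synthetic study conditions
#'
#' The standing conditions for validation runs: a 24 x 24 x 24 grid at 4 mm
#' (origin-centred), 24 participants x 120 timepoints, three disjoint
#' 4 x 4 x 4-voxel networks (A, B, C) with signalSd = noiseSd = 1 (expected
#' within-network correlation rho = 0.5), and 18 studies per group reporting
#' 3 foci each with 2 mm jitter. Each neurotypical study targets networks A
#' and B (foci assigned round-robin); each autistic-group study targets A
#' only; network C is planted but untargeted, probing false positives. The
#' planted group difference (network B) is therefore recoverable by the
#' NT-minus-ASD contrast.
#'
#' @param rngSeed integer master seed (default 1).
#' @return a \linkS4class{SyntheticSpec}.
#' @export
defaultSyntheticSpec <- function(rngSeed = 1L) {
    studies <- rbind(
        data.frame(study_id = sprintf("nt%02d", 1:18), group = "NT",
                   n_foci = 3L, targets = "A,B",
                   stringsAsFactors = FALSE),
        data.frame(study_id = sprintf("asd%02d", 1:18), group = "ASD",
                   n_foci = 3L, targets = "A",
                   stringsAsFactors = FALSE))
    new("SyntheticSpec",
        shape = c(24L, 24L, 24L), voxelSizeMm = 4,
        nParticipants = 24L, nTimepoints = 120L,
        networks = list(
            A = list(origin = c(4L, 4L, 4L),   size = c(4L, 4L, 4L)),
            B = list(origin = c(14L, 6L, 6L),  size = c(4L, 4L, 4L)),
            C = list(origin = c(6L, 14L, 14L), size = c(4L, 4L, 4L))),
        signalSd = 1, noiseSd = 1, studies = studies,
        fociJitterMm = 2, rngSeed = as.integer(rngSeed))
}

#' Grid and all-true brain mask of a synthetic spec
#'
#' The grid is isotropic at \code{voxelSizeMm} with the world origin at the
#' lattice center (MNI-like); the synthetic brain mask covers the whole
#' grid.
#'
#' @param spec a \linkS4class{SyntheticSpec}.
#' @return list with elements \code{grid} and \code{mask}.
#' @export
syntheticGrid <- function(spec) {
    s <- spec@voxelSizeMm
    origin <- -(spec@shape - 1) / 2 * s
    grid <- VolumeGrid(spec@shape, affineScaled(rep(s, 3), origin))
    list(grid = grid, mask = BrainMask(grid, array(TRUE, spec@shape)))
}

## deterministic per-entity substream seed (31-bit), so earlier entities are
## unaffected when participant/study counts grow
.substreamSeed <- function(master, kind, index) {
    k <- switch(kind, participant = 101L, study = 211L,
                stop("unknown substream kind"))
    ((as.double(master) * 7919 + k * 104729 + index * 15485863)
        %% 2147483629)
}

.networkVoxelLinear <- function(spec, name) {
    nw <- spec@networks[[name]]
    ix <- lapply(1:3, function(d)
        seq.int(nw$origin[d], length.out = nw$size[d]))   # 0-based
    g <- as.matrix(expand.grid(i = ix[[1]], j = ix[[2]], k = ix[[3]]))
    1L + g[, 1] + spec@shape[1] * (g[, 2] + spec@shape[2] * g[, 3])
}

#' Binary volumes of the planted networks
#'
#' @param spec a \linkS4class{SyntheticSpec}.
#' @return named list of binary \linkS4class{ScalarVolume}s.
#' @export
networkMasks <- function(spec) {
    g <- syntheticGrid(spec)
    out <- lapply(names(spec@networks), function(nm) {
        d <- array(0, spec@shape)
        d[.networkVoxelLinear(spec, nm)] <- 1
        ScalarVolume(g$grid, d, kind = "binary")
    })
    names(out) <- names(spec@networks)
    out
}

#' Simulate the synthetic normative connectome
#'
#' For each participant, each planted network k receives an independent
#' latent series (T standard normal draws scaled by \code{signalSd});
#' every voxel's series is its network's latent (if any) plus i.i.d.
#' Gaussian noise scaled by \code{noiseSd}. The expected correlation between
#' two voxels of the same network is rho = signalSd^2 / (signalSd^2 +
#' noiseSd^2); voxels of different networks (or outside all networks) are
#' uncorrelated in expectation. Each participant consumes an independent RNG
#' substream derived from \code{spec@rngSeed}, so the simulation is
#' bit-reproducible and earlier participants are unchanged when
#' \code{nParticipants} grows.
#'
#' @param spec a \linkS4class{SyntheticSpec}.
#' @return list with elements \code{participants} (list of
#'   \linkS4class{ParticipantTimeSeries}), \code{mask}
#'   (\linkS4class{BrainMask}) and \code{grid}.
#' @export
simulateConnectome <- function(spec) {
    validObject(spec)
    g <- syntheticGrid(spec)
    mask <- g$mask
    V <- nVoxels(mask)
    Tn <- spec@nTimepoints
    netCols <- lapply(names(spec@networks), function(nm)
        .networkVoxelLinear(spec, nm))   # mask = full grid: linear == column
    participants <- vector("list", spec@nParticipants)
    for (p in seq_len(spec@nParticipants)) {
        set.seed(.substreamSeed(spec@rngSeed, "participant", p))
        dat <- matrix(stats::rnorm(Tn * V, sd = spec@noiseSd), Tn, V)
        for (ki in seq_along(netCols)) {
            latent <- stats::rnorm(Tn, sd = spec@signalSd)
            dat[, netCols[[ki]]] <- dat[, netCols[[ki]]] + latent
        }
        participants[[p]] <- ParticipantTimeSeries(
            sprintf("sub%04d", p), mask, dat)
    }
    list(participants = participants, mask = mask, grid = g$grid)
}

#' Simulate the per-study foci corpus
#'
#' Each study's foci are drawn uniformly (without replacement per network)
#' from its target networks' voxel centers, assigned round-robin across the
#' study's targets, then jittered isotropically (uniform in a ball of radius
#' \code{fociJitterMm}) and clamped into the mask's bounding box. Studies
#' targeting \code{"none"} draw from mask voxels outside every network.
#' Deterministic per study under \code{spec@rngSeed} substreams.
#'
#' @param spec a \linkS4class{SyntheticSpec}.
#' @return a \linkS4class{StudyFociTable} (all MNI).
#' @export
simulateFoci <- function(spec) {
    validObject(spec)
    g <- syntheticGrid(spec)
    allNet <- unlist(lapply(names(spec@networks), .networkVoxelLinear,
                            spec = spec))
    rows <- vector("list", nrow(spec@studies))
    for (si in seq_len(nrow(spec@studies))) {
        st <- spec@studies[si, ]
        set.seed(.substreamSeed(spec@rngSeed, "study", si))
        targets <- strsplit(st$targets, ",")[[1]]
        assign <- targets[((seq_len(st$n_foci) - 1L) %% length(targets)) + 1L]
        pick <- integer(st$n_foci)
        for (tg in unique(assign)) {
            idx <- which(assign == tg)
            pool <- if (tg == "none")
                setdiff(which(g$mask@data), allNet)
            else .networkVoxelLinear(spec, tg)
            if (length(pool) < length(idx))
                stop(sprintf("target '%s' has %d voxels < %d foci (study %s)",
                             tg, length(pool), length(idx), st$study_id))
            pick[idx] <- sample(pool, length(idx), replace = FALSE)
        }
        w <- voxelCenters(g$grid, pick)
        if (spec@fociJitterMm > 0) {
            u <- matrix(stats::rnorm(3 * st$n_foci), ncol = 3)
            u <- u / sqrt(rowSums(u^2))
            rad <- spec@fociJitterMm * stats::runif(st$n_foci)^(1 / 3)
            w <- w + u * rad
        }
        ## clamp into the mask's world bounding box
        lo <- voxelToWorld(g$grid, c(0, 0, 0))
        hi <- voxelToWorld(g$grid, spec@shape - 1)
        for (d in 1:3) w[, d] <- pmin(pmax(w[, d], min(lo[d], hi[d])),
                                      max(lo[d], hi[d]))
        rows[[si]] <- data.frame(study_id = st$study_id, group = st$group,
                                 x = w[, 1], y = w[, 2], z = w[, 3],
                                 space = "MNI", stringsAsFactors = FALSE)
    }
    StudyFociTable(do.call(rbind, rows))
}

#' Ground truth for a synthetic run
#'
#' Per-group expected retained mask: the union of networks targeted by
#' strictly more than \code{config@overlapFraction} of that group's studies
#' (the same strict rule the overlap map applies; 11 of 18 studies suffice
#' at the default 0.60).
#'
#' @param spec a \linkS4class{SyntheticSpec}.
#' @param config an \linkS4class{AnmConfig}.
#' @return a \linkS4class{GroundTruth}.
#' @export
groundTruth <- function(spec, config = anmConfig()) {
    nets <- networkMasks(spec)
    g <- syntheticGrid(spec)
    expected <- lapply(c(NT = "NT", ASD = "ASD"), function(grp) {
        st <- spec@studies[spec@studies$group == grp, , drop = FALSE]
        E <- nrow(st)
        d <- array(0, spec@shape)
        if (E > 0) {
            for (nm in names(nets)) {
                hits <- sum(vapply(strsplit(st$targets, ","),
                                   function(t) nm %in% t, logical(1)))
                if (hits / E > config@overlapFraction)
                    d <- pmax(d, nets[[nm]]@data)
            }
        }
        ScalarVolume(g$grid, d, kind = "binary")
    })
    GroundTruth(nets, expected)
}
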