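#' @include AllClasses.R
NULL

## Group-level network mapping: the binarised-overlap branch, the t-map
## branch, group contrasts and map similarity. Everything here is fully
## deterministic given its inputs; zero-variance voxels yield t = 0 (never
## NaN) so overlap counting stays well defined on degenerate inputs.

#' Voxelwise one-sample t statistic
#'
#' For each voxel (column), t = mean / (sd / sqrt(n)) of the n stacked values
#' against zero, with the n-1 (sample) sd. Zero-variance voxels get t = 0;
#' their count is reported via \code{message}.
#'
#' @param x numeric n x V matrix (rows = observations, e.g. participants or
#'   experiments; columns = in-mask voxels), n >= 3.
#' @return numeric vector of V t statistics.
#' @export
#' @examples
#' oneSampleT(matrix(c(1, 2, 3), ncol = 1))  # 2 / (1 / sqrt(3)) = 3.4641
oneSampleT <- function(x) {
    stopifnot(is.matrix(x))
    n <- nrow(x)
    if (n < 3L) stop("one-sample t needs at least 3 observations, got ", n)
    m <- colMeans(x)
    ss <- colSums(x^2) - n * m^2
    v <- pmax(ss, 0) / (n - 1)
    zero <- v <= 0
    if (any(zero))
        message(sum(zero), " zero-variance voxel(s) set to t = 0")
    t <- numeric(length(m))
    t[!zero] <- m[!zero] / sqrt(v[!zero] / n)
    t
}

#' Binarise a statistic vector or volume at a threshold
#'
#' Strictly greater than: a value exactly equal to the threshold is not
#' retained.
#'
#' @param x numeric vector, or a \linkS4class{ScalarVolume}.
#' @param threshold finite numeric scalar.
#' @param mask for a volume input, an optional \linkS4class{BrainMask};
#'   out-of-mask voxels are always 0.
#' @return 0/1 numeric vector, or a binary \linkS4class{ScalarVolume}.
#' @export
binarize <- function(x, threshold, mask = NULL) {
    stopifnot(is.finite(threshold))
    if (is(x, "ScalarVolume")) {
        d <- as.numeric(x@data > threshold)
        d <- array(d, dim = x@grid@shape)
        if (!is.null(mask)) d[!mask@data] <- 0
        ScalarVolume(x@grid, d, kind = "binary")
    } else {
        as.numeric(x > threshold)
    }
}

#' Overlap map across binarised experiment maps
#'
#' Counts, per voxel, how many of the E experiments' binarised connectivity
#' maps cover it; the voxel is retained iff count / E strictly exceeds
#' \code{overlapFraction}. With E = 18 and fraction 0.60 the minimal
#' retaining count is 11 (10/18 = 55.6\% fails, 11/18 = 61.1\% passes).
#'
#' @param binaries list of E binary vectors (over in-mask voxels) or binary
#'   \linkS4class{ScalarVolume}s on one shared grid.
#' @param mask the shared \linkS4class{BrainMask}.
#' @param overlapFraction strict retention fraction in (0,1), default 0.60.
#' @param group group tag stored on the result.
#' @return an \linkS4class{OverlapMap}.
#' @export
overlapMap <- function(binaries, mask, overlapFraction = 0.60,
                       group = "NT") {
    stopifnot(length(binaries) >= 1L)
    vecs <- lapply(binaries, function(b) {
        if (is(b, "ScalarVolume")) {
            stopifnot(sameGrid(b@grid, mask@grid))
            maskVector(b, mask)
        } else as.numeric(b)
    })
    V <- nVoxels(mask)
    stopifnot(all(vapply(vecs, length, 1L) == V))
    E <- length(vecs)
    count <- Reduce(`+`, vecs)
    fraction <- count / E
    retained <- as.numeric(fraction > overlapFraction)
    OverlapMap(group,
               count = vectorToVolume(count, mask, "count"),
               fraction = vectorToVolume(fraction, mask, "fraction"),
               retained = vectorToVolume(retained, mask, "binary"),
               nExperiments = E)
}

#' Minimal retaining experiment count under the strict overlap rule
#'
#' Smallest integer k with k / E strictly above the fraction; the count a
#' voxel needs before it enters the overlap network.
#'
#' @param nExperiments integer E >= 1.
#' @param overlapFraction strict retention fraction (default 0.60).
#' @return integer k.
#' @export
#' @examples
#' minRetainCount(18)  # 11
minRetainCount <- function(nExperiments, overlapFraction = 0.60) {
    k <- floor(nExperiments * overlapFraction) + 1L
    ## floor(E*f)+1 can overshoot by issues only when E*f is integral and
    ## floating error pushed it down; recheck strictly
    while (k > 1L && (k - 1L) / nExperiments > overlapFraction) k <- k - 1L
    as.integer(k)
}

#' Experiment-level mean Fisher z map
#'
#' Voxelwise arithmetic mean of a study's participant-level Fisher z values:
#' the experiment-level summary consumed by the t-map branch.
#'
#' @param stack an \linkS4class{ExperimentZStack}, or a numeric
#'   participants x voxels matrix.
#' @return numeric vector over in-mask voxels.
#' @export
experimentMeanZ <- function(stack) {
    z <- if (is(stack, "ExperimentZStack")) stack@z else stack
    stopifnot(is.matrix(z), nrow(z) >= 1L)
    colMeans(z)
}

#' Group-level t map over experiment-level mean Fisher z maps
#'
#' Stacks the E experiment-level mean z vectors and applies the voxelwise
#' one-sample t test against zero (df = E - 1), then thresholds at the
#' configured critical t (strict).
#'
#' @param meanZ list of E numeric vectors (one per experiment) over in-mask
#'   voxels, E >= 3.
#' @param mask the shared \linkS4class{BrainMask}.
#' @param config an \linkS4class{AnmConfig}; \code{thresholdMode}
#'   \code{"fixed_t"} uses \code{config@tThreshold}, \code{"alpha_derived"}
#'   uses \code{\link{criticalT}} at alpha (default 0.05 / in-mask voxels)
#'   and df = E - 1.
#' @param group group tag stored on the result.
#' @return a \linkS4class{GroupTMap}.
#' @export
groupTMap <- function(meanZ, mask, config = anmConfig(), group = "NT") {
    E <- length(meanZ)
    if (E < 3L) stop("group t map needs at least 3 experiments, got ", E)
    m <- do.call(rbind, meanZ)
    t <- suppressMessages(oneSampleT(m))
    thr <- .resolveThreshold(config, df = E - 1L, mask = mask)
    GroupTMap(group,
              t = vectorToVolume(t, mask, "t"),
              thresholded = vectorToVolume(binarize(t, thr), mask, "binary"),
              df = E - 1L)
}

.resolveThreshold <- function(config, df, mask) {
    if (config@thresholdMode == "fixed_t") return(config@tThreshold)
    alpha <- if (is.na(config@alpha)) 0.05 / nVoxels(mask) else config@alpha
    criticalT(alpha, df)
}

#' Two-sided Student-t critical value
#'
#' The t value with upper-tail probability alpha/2 at df degrees of freedom:
#' the df-consistent alternative to the fixed threshold, used when
#' \code{thresholdMode = "alpha_derived"}. At alpha = 0.05 and large df it
#' approaches 1.96.
#'
#' @param alpha two-sided significance level in (0,1).
#' @param df degrees of freedom, >= 1.
#' @return numeric critical t.
#' @export
#' @examples
#' criticalT(0.5, 1)                 # 1 (Cauchy quartile)
#' criticalT(0.05 / 285903, 999)     # voxelwise Bonferroni on a 285,903-voxel mask
criticalT <- function(alpha, df) {
    stopifnot(alpha > 0, alpha < 1, df >= 1)
    stats::qt(1 - alpha / 2, df = df)
}

#' Build both group-level network maps for one group
#'
#' The two complementary branches from the same per-study Fisher z stacks:
#' \itemize{
#'   \item overlap branch: per experiment, a one-sample t across participants
#'     then strict binarisation at the critical t; voxels retained iff
#'     connected to more than the configured fraction of coactivation seeds;
#'   \item t branch: per experiment, the mean Fisher z across participants;
#'     then a one-sample t across experiments, thresholded at the critical t.
#' }
#' In \code{fixed_t} mode both levels use the same fixed threshold (default
#' 5.66); \code{alpha_derived} mode uses the df-appropriate critical value at
#' each level.
#'
#' @param stacks named list of \linkS4class{ExperimentZStack}s (one group).
#' @param mask the shared \linkS4class{BrainMask}.
#' @param config an \linkS4class{AnmConfig}.
#' @param group group tag; default taken from the first stack.
#' @return list with elements \code{overlap} (\linkS4class{OverlapMap}),
#'   \code{tmap} (\linkS4class{GroupTMap}), \code{experimentT} (list of
#'   per-experiment t vectors) and \code{meanZ} (list of per-experiment mean
#'   z vectors).
#' @export
buildGroupMaps <- function(stacks, mask, config = anmConfig(),
                           group = NULL) {
    stopifnot(length(stacks) >= 3L)
    if (is.null(group)) group <- stacks[[1]]@group
    nP <- nrow(stacks[[1]]@z)
    for (s in stacks) {
        stopifnot(sameGrid(s@mask@grid, mask@grid))
        if (nrow(s@z) != nP)
            stop("experiments must share one participant roster")
    }
    expThr <- .resolveThreshold(config, df = nP - 1L, mask = mask)
    expT <- lapply(stacks, function(s) suppressMessages(oneSampleT(s@z)))
    binaries <- lapply(expT, binarize, threshold = expThr)
    overlap <- overlapMap(binaries, mask,
                          overlapFraction = config@overlapFraction,
                          group = group)
    meanZ <- lapply(stacks, experimentMeanZ)
    tmap <- groupTMap(meanZ, mask, config = config, group = group)
    list(overlap = overlap, tmap = tmap, experimentT = expT, meanZ = meanZ)
}

#' Contrast the two groups' network maps
#'
#' Default \code{set_difference} mode: voxels retained for one group and not
#' the other (both directions; applied separately to overlap and t-map
#' branches via \code{which}). \code{proportion_test} mode: voxelwise
#' two-proportion z test on the overlap counts at Bonferroni-corrected
#' alpha. \code{two_sample_t} mode: voxelwise Welch t across the two groups'
#' experiment-level mean z maps, thresholded at the configured critical t.
#'
#' @param nt,asd results of \code{\link{buildGroupMaps}} for each group.
#' @param config an \linkS4class{AnmConfig}.
#' @param mask the shared \linkS4class{BrainMask}.
#' @param which \code{"overlap"} or \code{"tmap"}: which branch to contrast
#'   in \code{set_difference} mode.
#' @return a \linkS4class{ContrastResult}.
#' @export
contrastMaps <- function(nt, asd, config = anmConfig(), mask,
                         which = c("overlap", "tmap")) {
    which <- match.arg(which)
    mode <- config@contrastMode
    prov <- list(mode = mode, branch = which,
                 overlapFraction = config@overlapFraction,
                 tThreshold = config@tThreshold,
                 thresholdMode = config@thresholdMode)
    if (mode == "set_difference") {
        a <- if (which == "overlap") nt$overlap@retained else nt$tmap@thresholded
        b <- if (which == "overlap") asd$overlap@retained else asd$tmap@thresholded
        stopifnot(sameGrid(a@grid, b@grid))
        ntm <- ScalarVolume(a@grid, pmax(a@data - b@data, 0), "binary")
        atm <- ScalarVolume(a@grid, pmax(b@data - a@data, 0), "binary")
        return(ContrastResult(mode, ntm, atm, prov))
    }
    if (mode == "proportion_test") {
        cntN <- maskVector(nt$overlap@count, mask)
        cntA <- maskVector(asd$overlap@count, mask)
        eN <- nt$overlap@nExperiments
        eA <- asd$overlap@nExperiments
        p1 <- cntN / eN; p2 <- cntA / eA
        pp <- (cntN + cntA) / (eN + eA)
        se <- sqrt(pp * (1 - pp) * (1 / eN + 1 / eA))
        z <- ifelse(se > 0, (p1 - p2) / se, 0)
        alpha <- if (is.na(config@alpha)) 0.05 / nVoxels(mask) else config@alpha
        zcrit <- stats::qnorm(1 - alpha / 2)
        ntm <- vectorToVolume(as.numeric(z > zcrit), mask, "binary")
        atm <- vectorToVolume(as.numeric(z < -zcrit), mask, "binary")
        return(ContrastResult(mode, ntm, atm, c(prov, list(alpha = alpha))))
    }
    ## two_sample_t: Welch t across experiment-level mean z maps
    mN <- do.call(rbind, nt$meanZ)
    mA <- do.call(rbind, asd$meanZ)
    t <- .welchT(mN, mA)
    dfW <- attr(t, "df")
    thr <- if (config@thresholdMode == "fixed_t") config@tThreshold
           else criticalT(if (is.na(config@alpha)) 0.05 / nVoxels(mask)
                          else config@alpha,
                          df = max(1, floor(stats::median(dfW))))
    ntm <- vectorToVolume(as.numeric(t > thr), mask, "binary")
    atm <- vectorToVolume(as.numeric(t < -thr), mask, "binary")
    ContrastResult(mode, ntm, atm, c(prov, list(welch = TRUE)))
}

## column-wise Welch (unequal-variance) two-sample t; zero-variance-in-both
## columns yield t = 0
.welchT <- function(a, b) {
    n1 <- nrow(a); n2 <- nrow(b)
    m1 <- colMeans(a); m2 <- colMeans(b)
    v1 <- pmax(colSums(a^2) - n1 * m1^2, 0) / (n1 - 1)
    v2 <- pmax(colSums(b^2) - n2 * m2^2, 0) / (n2 - 1)
    se2 <- v1 / n1 + v2 / n2
    t <- ifelse(se2 > 0, (m1 - m2) / sqrt(se2), 0)
    df <- ifelse(se2 > 0,
                 se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1)),
                 n1 + n2 - 2)
    structure(t, df = df)
}

#' Pearson similarity of two maps over the brain mask
#'
#' The similarity statistic between a group's overlap map and its t map:
#' Pearson correlation over in-mask voxels. By default the unthresholded
#' operands are used (the overlap fraction volume and the raw t volume); the
#' thresholded/binarised operands are available via
#' \code{config@similarityOperands = "binarized"} upstream.
#'
#' @param a,b \linkS4class{ScalarVolume}s on one grid, or numeric vectors
#'   over in-mask voxels.
#' @param mask the shared \linkS4class{BrainMask} (required for volumes).
#' @return Pearson r.
#' @export
mapSimilarity <- function(a, b, mask = NULL) {
    va <- if (is(a, "ScalarVolume")) maskVector(a, mask) else as.numeric(a)
    vb <- if (is(b, "ScalarVolume")) maskVector(b, mask) else as.numeric(b)
    stopifnot(length(va) == length(vb), length(va) >= 2L)
    if (stats::sd(va) == 0 || stats::sd(vb) == 0)
        stop("map similarity undefined: zero variance in an operand")
    stats::cor(va, vb)
}

#' Dice coefficient of two binary volumes or vectors
#'
#' 2|A & B| / (|A| + |B|); 1 when both are empty (perfect vacuous agreement).
#'
#' @param a,b binary \linkS4class{ScalarVolume}s or 0/1 vectors.
#' @return numeric in [0, 1].
#' @export
dice <- function(a, b) {
    va <- if (is(a, "ScalarVolume")) as.numeric(a@data != 0) else as.numeric(a != 0)
    vb <- if (is(b, "ScalarVolume")) as.numeric(b@data != 0) else as.numeric(b != 0)
    stopifnot(length(va) == length(vb))
    denom <- sum(va) + sum(vb)
    if (denom == 0) return(1)
    2 * sum(va * vb) / denom
}
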