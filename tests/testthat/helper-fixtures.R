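# Shared fixtures and independent brute-force oracles. Oracles are written
# as plain loops / direct formulas, deliberately not reusing the package's
# vectorised code paths.

makeTestGrid <- function(shape = c(10L, 10L, 10L), scale = 2,
                         origin = -(shape - 1) / 2 * scale) {
    VolumeGrid(as.integer(shape), affineScaled(rep(scale, 3), origin))
}

makeFullMask <- function(grid) {
    BrainMask(grid, array(TRUE, grid@shape))
}

# random invertible affine: scaled rotation plus translation
randomAffine <- function() {
    q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
    s <- diag(runif(3, 0.5, 4))
    a <- diag(4)
    a[1:3, 1:3] <- q %*% s
    a[1:3, 4] <- runif(3, -50, 50)
    a
}

# exhaustive lattice scan: count voxels whose world center is within radius
oracleSphereCount <- function(center, radius, grid, maskArr) {
    n <- 0L
    for (i in 0:(grid@shape[1] - 1)) for (j in 0:(grid@shape[2] - 1))
        for (k in 0:(grid@shape[3] - 1)) {
            if (!maskArr[i + 1, j + 1, k + 1]) next
            w <- as.vector(grid@affine %*% c(i, j, k, 1))[1:3]
            if (sum((w - center)^2) <= radius^2) n <- n + 1L
        }
    n
}

# textbook per-column one-sample t, plain loop
oracleOneSampleT <- function(mat) {
    out <- numeric(ncol(mat))
    for (v in seq_len(ncol(mat))) {
        x <- mat[, v]
        s <- sd(x)
        out[v] <- if (s == 0) 0 else mean(x) / (s / sqrt(length(x)))
    }
    out
}

# direct covariance-formula Pearson r then atanh, per voxel
oracleFisherZ <- function(seedSeries, mat, clip = 1 - 1e-7) {
    out <- numeric(ncol(mat))
    for (v in seq_len(ncol(mat))) {
        x <- mat[, v]
        if (sd(x) == 0 || sd(seedSeries) == 0) { out[v] <- 0; next }
        r <- sum((x - mean(x)) * (seedSeries - mean(seedSeries))) /
            ((length(x) - 1) * sd(x) * sd(seedSeries))
        out[v] <- atanh(min(max(r, -clip), clip))
    }
    out
}

# per-voxel counting oracle for the overlap rule
oracleOverlapRetained <- function(binaryVectors, fraction) {
    E <- length(binaryVectors)
    V <- length(binaryVectors[[1]])
    out <- numeric(V)
    for (v in seq_len(V)) {
        cnt <- 0
        for (e in seq_len(E)) cnt <- cnt + binaryVectors[[e]][v]
        out[v] <- as.numeric(cnt / E > fraction)
    }
    out
}

# exhaustive 26-neighbourhood strict local-maximum scan
oracleLocalMaxima <- function(d, maskArr) {
    sh <- dim(d)
    hits <- matrix(numeric(0), ncol = 3)
    for (i in 1:sh[1]) for (j in 1:sh[2]) for (k in 1:sh[3]) {
        if (!maskArr[i, j, k] || d[i, j, k] == 0) next
        best <- TRUE
        for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
            if (di == 0 && dj == 0 && dk == 0) next
            ii <- i + di; jj <- j + dj; kk <- k + dk
            if (ii < 1 || jj < 1 || kk < 1 ||
                ii > sh[1] || jj > sh[2] || kk > sh[3]) next
            nb <- if (maskArr[ii, jj, kk]) d[ii, jj, kk] else -Inf
            if (d[i, j, k] <= nb) { best <- FALSE; break }
        }
        if (best) hits <- rbind(hits, c(i, j, k) - 1L)
    }
    hits
}

# small two-study-per-group synthetic spec for fast pipeline tests
smallSyntheticSpec <- function(rngSeed = 11L, nStudies = 4L) {
    syntheticSpec(
        shape = c(12L, 12L, 12L), voxelSizeMm = 4,
        nParticipants = 6L, nTimepoints = 60L,
        networks = list(
            A = list(origin = c(2L, 2L, 2L), size = c(3L, 3L, 3L)),
            B = list(origin = c(7L, 7L, 7L), size = c(3L, 3L, 3L))),
        signalSd = 1, noiseSd = 1,
        studies = rbind(
            data.frame(study_id = sprintf("nt%02d", seq_len(nStudies)),
                       group = "NT", n_foci = 2L, targets = "A,B",
                       stringsAsFactors = FALSE),
            data.frame(study_id = sprintf("as%02d", seq_len(nStudies)),
                       group = "ASD", n_foci = 2L, targets = "A",
                       stringsAsFactors = FALSE)),
        fociJitterMm = 1, rngSeed = rngSeed)
}

writeFociTsv <- function(df, path) {
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                fileEncoding = "UTF-8")
    path
}
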