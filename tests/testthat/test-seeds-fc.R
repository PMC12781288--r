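test_that("6-mm sphere voxelisation matches the exhaustive lattice oracle", {
    # 2 mm isotropic grid, center on a voxel center: i^2+j^2+k^2 <= 9
    g <- VolumeGrid(c(15L, 15L, 15L),
                    affineScaled(c(2, 2, 2), c(-14, -14, -14)))
    m <- makeFullMask(g)
    sph <- makeSphere(c(0, 0, 0), 6, g, m)
    expect_identical(sum(sph@data), oracleSphereCount(c(0, 0, 0), 6, g,
                                                      m@data) * 1)
    expect_identical(sum(sph@data), 123)

    # radius below half a voxel edge: only the central voxel
    tiny <- makeSphere(c(0, 0, 0), 0.9, g, m)
    expect_identical(sum(tiny@data), 1)

    # half-space mask: count agrees with the masked enumeration
    half <- array(TRUE, g@shape)
    w1 <- voxelCenters(g)[, 1]
    half[array(w1 < 0, g@shape)] <- FALSE
    mh <- BrainMask(g, half)
    sphHalf <- makeSphere(c(0, 0, 0), 6, g, mh)
    expect_identical(sum(sphHalf@data),
                     oracleSphereCount(c(0, 0, 0), 6, g, half) * 1)
})

test_that("off-center and anisotropic spheres agree with the oracle", {
    set.seed(3)
    g <- VolumeGrid(c(12L, 10L, 8L),
                    affineScaled(c(2, 3, 4), c(-11, -13, -14)))
    m <- makeFullMask(g)
    for (i in 1:5) {
        ctr <- runif(3, -8, 8)     # not on a voxel center
        r <- runif(1, 3, 9)
        sph <- makeSphere(ctr, r, g, m)
        expect_identical(sum(sph@data),
                         oracleSphereCount(ctr, r, g, m@data) * 1)
    }
})

test_that("sphere membership is invariant under joint world translation", {
    shift <- c(13, -7, 5)
    g1 <- VolumeGrid(c(11L, 11L, 11L),
                     affineScaled(c(2, 2, 2), c(-10, -10, -10)))
    g2 <- VolumeGrid(c(11L, 11L, 11L),
                     affineScaled(c(2, 2, 2), c(-10, -10, -10) + shift))
    s1 <- makeSphere(c(1, 2, -3), 6, g1, makeFullMask(g1))
    s2 <- makeSphere(c(1, 2, -3) + shift, 6, g2, makeFullMask(g2))
    expect_identical(s1@data, s2@data)
})

test_that("sphere entirely outside the mask warns and is empty", {
    g <- makeTestGrid(c(8L, 8L, 8L))
    d <- array(TRUE, g@shape); d[1:4, , ] <- FALSE
    m <- BrainMask(g, d)
    ctr <- voxelToWorld(g, c(0, 3, 3))
    expect_warning(sph <- makeSphere(ctr, 1.5, g, m), "no in-mask voxel")
    expect_identical(sum(sph@data), 0)
})

test_that("coactivation seeds are sphere unions with the expected algebra", {
    g <- VolumeGrid(c(21L, 21L, 21L),
                    affineScaled(c(2, 2, 2), c(-20, -20, -20)))
    m <- makeFullMask(g)
    one <- data.frame(x = 0, y = 0, z = 0)
    seedOne <- makeCoactivationSeed(one, 6, g, m, studyId = "s", group = "NT")
    expect_identical(seedOne@mask@data, makeSphere(c(0, 0, 0), 6, g, m)@data)

    # idempotent union of two identical foci
    two <- rbind(one, one)
    expect_identical(makeCoactivationSeed(two, 6, g, m, "s", "NT")@mask@data,
                     seedOne@mask@data)

    # disjoint spheres (> 2r apart): count is the sum
    far <- data.frame(x = c(-10, 10), y = 0, z = 0)
    seedFar <- makeCoactivationSeed(far, 6, g, m, "s", "NT")
    expect_equal(nVoxels(seedFar), 2 * nVoxels(seedOne))

    # union monotonicity: adding a focus never shrinks the seed
    three <- rbind(far, data.frame(x = 0, y = 4, z = 0))
    seedThree <- makeCoactivationSeed(three, 6, g, m, "s", "NT")
    expect_true(all(seedThree@mask@data >= seedFar@mask@data))
})

test_that("seed mean time series averages exactly the seed's voxels", {
    g <- makeTestGrid(c(5L, 5L, 5L))
    m <- makeFullMask(g)
    Tn <- 20
    set.seed(5)
    dat <- matrix(rnorm(Tn * 125), Tn, 125)
    p <- ParticipantTimeSeries("p1", m, dat)

    oneVox <- array(0, g@shape); oneVox[3, 3, 3] <- 1
    s1 <- CoactivationSeed("s", "NT", ScalarVolume(g, oneVox, "binary"))
    col <- which(oneVox[m@data] != 0)
    expect_identical(seedMeanTimeseries(p, s1), dat[, col])

    # cancellation: two voxels with series s and -s average to zero
    d2 <- dat; d2[, 2] <- -d2[, 1]
    p2 <- ParticipantTimeSeries("p2", m, d2)
    pair <- array(0, g@shape); pair[1:2, 1, 1] <- 1
    s2 <- CoactivationSeed("s", "NT", ScalarVolume(g, pair, "binary"))
    expect_lt(max(abs(seedMeanTimeseries(p2, s2))), 1e-12)

    # 5-voxel seed vs loop-based averaging oracle
    idx <- sample(125, 5)
    arr <- array(0, g@shape); arr[idx] <- 1
    s5 <- CoactivationSeed("s", "NT", ScalarVolume(g, arr, "binary"))
    manual <- sapply(seq_len(Tn), function(t) mean(dat[t, sort(idx)]))
    expect_equal(seedMeanTimeseries(p, s5), manual, tolerance = 1e-12)
})

test_that("fisher z maps reproduce the direct covariance-formula oracle", {
    g <- makeTestGrid(c(4L, 4L, 4L))
    m <- makeFullMask(g)
    Tn <- 30
    set.seed(6)
    dat <- matrix(rnorm(Tn * 64), Tn, 64)
    arr <- array(0, g@shape); arr[sample(64, 3)] <- 1
    seed <- CoactivationSeed("s", "NT", ScalarVolume(g, arr, "binary"))
    p <- ParticipantTimeSeries("p", m, dat)
    z <- fisherZValues(p, seed)
    sMean <- seedMeanTimeseries(p, seed)
    expect_equal(z, oracleFisherZ(sMean, dat), tolerance = 1e-10)
})

test_that("perfect, orthogonal and degenerate correlations follow the declared rules", {
    g <- makeTestGrid(c(2L, 2L, 2L))
    m <- makeFullMask(g)
    Tn <- 16
    base <- sin(seq_len(Tn))
    dat <- matrix(rnorm(Tn * 8), Tn, 8)
    dat[, 1] <- base
    dat[, 2] <- base                             # identical to the seed voxel
    orth <- rep(c(1, -1), Tn / 2)
    orth <- orth - mean(orth)
    bc <- base - mean(base)
    dat[, 3] <- orth - bc * sum(orth * bc) / sum(bc^2)  # orthogonalised
    dat[, 4] <- 7                                 # zero variance
    arr <- array(0, g@shape); arr[1] <- 1
    seed <- CoactivationSeed("s", "NT", ScalarVolume(g, arr, "binary"))
    p <- ParticipantTimeSeries("p", m, dat)
    z <- suppressMessages(fisherZValues(p, seed))
    expect_equal(z[1], atanh(1 - 1e-7))           # clipped perfect r
    expect_equal(z[2], atanh(1 - 1e-7))
    expect_lt(abs(z[3]), 1e-10)                   # r = 0 => z = 0
    expect_identical(z[4], 0)                     # zero-variance rule
    expect_message(fisherZValues(p, seed), "zero-variance")
})

test_that("fisher z is scale invariant and antisymmetric under sign flip", {
    g <- makeTestGrid(c(3L, 3L, 3L))
    m <- makeFullMask(g)
    set.seed(9)
    dat <- matrix(rnorm(20 * 27), 20, 27)
    arr <- array(0, g@shape); arr[14] <- 1
    seed <- CoactivationSeed("s", "NT", ScalarVolume(g, arr, "binary"))
    z0 <- fisherZValues(ParticipantTimeSeries("p", m, dat), seed)

    sc <- dat; sc[, 5] <- 3.7 * sc[, 5] + 11      # affine rescale of voxel 5
    z1 <- fisherZValues(ParticipantTimeSeries("p", m, sc), seed)
    expect_equal(z1[5], z0[5], tolerance = 1e-10)

    fl <- dat; fl[, 6] <- -fl[, 6]                # sign flip of voxel 6
    z2 <- fisherZValues(ParticipantTimeSeries("p", m, fl), seed)
    expect_equal(z2[6], -z0[6], tolerance = 1e-10)
})

test_that("zero-variance seed yields an all-zero map with a warning", {
    g <- makeTestGrid(c(2L, 2L, 2L))
    m <- makeFullMask(g)
    dat <- matrix(rnorm(16 * 8), 16, 8)
    dat[, 1] <- 2                                  # constant seed voxel
    arr <- array(0, g@shape); arr[1] <- 1
    seed <- CoactivationSeed("s", "NT", ScalarVolume(g, arr, "binary"))
    p <- ParticipantTimeSeries("p", m, dat)
    expect_warning(z <- suppressMessages(fisherZValues(p, seed)),
                   "zero variance")
    expect_true(all(z == 0))
})

test_that("seed voxels can be excluded from their own connectivity map", {
    g <- makeTestGrid(c(3L, 3L, 3L))
    m <- makeFullMask(g)
    set.seed(10)
    dat <- matrix(rnorm(20 * 27), 20, 27)
    arr <- array(0, g@shape); arr[c(2, 9)] <- 1
    seed <- CoactivationSeed("s", "NT", ScalarVolume(g, arr, "binary"))
    p <- ParticipantTimeSeries("p", m, dat)
    zIn <- fisherZValues(p, seed, excludeSeedVoxels = FALSE)
    zEx <- fisherZValues(p, seed, excludeSeedVoxels = TRUE)
    expect_true(all(zEx[c(2, 9)] == 0))
    expect_identical(zIn[-c(2, 9)], zEx[-c(2, 9)])
})
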