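test_that("one-sample t reproduces the hand oracle and textbook formula", {
    expect_equal(oneSampleT(matrix(c(1, 2, 3), ncol = 1)), 2 * sqrt(3),
                 tolerance = 1e-12)                  # mean 2, sd 1, sqrt(3)
    set.seed(21)
    m <- matrix(rnorm(10 * 50), 10, 50)
    expect_equal(oneSampleT(m), oracleOneSampleT(m), tolerance = 1e-10)
})

test_that("degenerate stacks follow the zero-variance t rule", {
    z <- matrix(0, 5, 7)
    expect_identical(suppressMessages(oneSampleT(z)), rep(0, 7))
    expect_message(oneSampleT(z), "zero-variance")
    const <- matrix(2, 5, 3)                        # nonzero but constant
    expect_identical(suppressMessages(oneSampleT(const)), rep(0, 3))
    expect_error(oneSampleT(matrix(1:4, 2, 2)), "at least 3")
})

test_that("binarisation is strictly greater-than and mask-restricted", {
    expect_identical(binarize(c(1, 2, 3), 2), c(0, 0, 1))
    g <- makeTestGrid(c(3L, 3L, 3L))
    vol <- ScalarVolume(g, array(5.66, c(3, 3, 3)), "t")
    expect_true(all(binarize(vol, 5.66)@data == 0))  # boundary: not retained
    d <- array(TRUE, g@shape); d[1, , ] <- FALSE
    m <- BrainMask(g, d)
    big <- ScalarVolume(g, array(100, c(3, 3, 3)), "t")
    bb <- binarize(big, 5.66, mask = m)
    expect_true(all(bb@data[1, , ] == 0))
    expect_true(all(bb@data[2:3, , ] == 1))
    # element-wise comparison oracle on a mixed map
    set.seed(22)
    mixed <- array(rnorm(27), c(3, 3, 3))
    expect_identical(binarize(ScalarVolume(g, mixed, "t"), 0.3)@data,
                     array(as.numeric(mixed > 0.3), c(3, 3, 3)))
})

test_that("overlap retention implements the strict more-than-60% rule", {
    g <- makeTestGrid(c(3L, 3L, 3L))
    m <- makeFullMask(g)
    V <- 27
    # voxel v is covered by exactly v-1 of the 18 experiment maps
    E <- 18
    bins <- lapply(seq_len(E), function(e) as.numeric(e <= 0:(V - 1)))
    om <- overlapMap(bins, m, overlapFraction = 0.60)
    cnt <- maskVector(om@count, m)
    ret <- maskVector(om@retained, m)
    expect_identical(cnt, pmin(as.numeric(0:(V - 1)), 18))
    expect_identical(ret, as.numeric(0:(V - 1) >= 11))   # minimal count 11
    expect_identical(minRetainCount(18, 0.60), 11L)
    expect_identical(minRetainCount(1, 0.60), 1L)        # E=1: 1/1 > 0.6
    expect_identical(minRetainCount(10, 0.50), 6L)       # boundary not enough
})

test_that("overlap map agrees with the per-voxel counting oracle", {
    g <- makeTestGrid(c(3L, 3L, 3L))
    m <- makeFullMask(g)
    set.seed(23)
    for (rep in 1:3) {
        bins <- lapply(1:7, function(e) as.numeric(runif(27) > 0.5))
        om <- overlapMap(bins, m, overlapFraction = 0.60)
        expect_identical(maskVector(om@retained, m),
                         oracleOverlapRetained(bins, 0.60))
        # count > 4.2 means >= 5 of 7
        expect_identical(maskVector(om@retained, m),
                         as.numeric(maskVector(om@count, m) >= 5))
        # conservation: total count equals the sum of per-experiment voxels
        expect_equal(sum(om@count@data), sum(unlist(bins)))
    }
})

test_that("single-experiment overlap equals that experiment's map", {
    g <- makeTestGrid(c(3L, 3L, 3L))
    m <- makeFullMask(g)
    b <- as.numeric(runif(27) > 0.5)
    om <- overlapMap(list(b), m, overlapFraction = 0.60)
    expect_identical(maskVector(om@retained, m), b)
    # duplicated experiment: retained equals the single binarised map
    om18 <- overlapMap(rep(list(b), 18), m, overlapFraction = 0.60)
    expect_identical(maskVector(om18@retained, m), b)
})

test_that("experiment mean z is an exact voxelwise average", {
    set.seed(24)
    z <- matrix(rnorm(9 * 20), 9, 20)
    acc <- numeric(20)
    for (i in 1:9) acc <- acc + z[i, ]
    expect_equal(experimentMeanZ(z), acc / 9, tolerance = 1e-12)
    expect_identical(experimentMeanZ(z[1, , drop = FALSE]), z[1, ])
    expect_equal(experimentMeanZ(rbind(z[1, ], -z[1, ])), numeric(20),
                 tolerance = 1e-15)
})

test_that("group t map applies the hand oracle and permutation invariance", {
    g <- makeTestGrid(c(2L, 2L, 2L))
    m <- makeFullMask(g)
    mz <- list(rep(1, 8), rep(2, 8), rep(3, 8))
    mz[[1]][2] <- 1; mz[[2]][2] <- 2; mz[[3]][2] <- 3
    gt <- suppressMessages(groupTMap(mz, m, anmConfig(), group = "NT"))
    expect_equal(maskVector(gt@t, m)[1], 2 * sqrt(3), tolerance = 1e-10)
    expect_identical(gt@df, 2L)

    set.seed(25)
    mzr <- lapply(1:6, function(i) rnorm(8))
    g1 <- suppressMessages(groupTMap(mzr, m, anmConfig()))
    g2 <- suppressMessages(groupTMap(mzr[c(4, 1, 6, 2, 5, 3)], m, anmConfig()))
    expect_equal(g1@t@data, g2@t@data, tolerance = 1e-12)

    # identical positive constants across experiments: zero variance => t = 0
    gc <- suppressMessages(groupTMap(rep(list(rep(0.7, 8)), 5), m, anmConfig()))
    expect_true(all(gc@t@data == 0))
    expect_true(all(gc@thresholded@data == 0))
    expect_error(groupTMap(mz[1:2], m), "at least 3")
})

test_that("build_group_maps matches brute-force per-voxel oracles", {
    g <- makeTestGrid(c(10L, 10L, 10L))
    m <- makeFullMask(g)
    set.seed(26)
    cfg <- anmConfig(tThreshold = 1.5)
    stacks <- lapply(1:5, function(e)
        ExperimentZStack(sprintf("s%d", e), "NT", m,
                         matrix(rnorm(6 * 1000, mean = 0.1), 6, 1000)))
    names(stacks) <- sprintf("s%d", 1:5)
    res <- buildGroupMaps(stacks, m, cfg)

    binsOracle <- lapply(stacks, function(s) {
        t <- oracleOneSampleT(s@z)
        as.numeric(t > cfg@tThreshold)
    })
    expect_identical(maskVector(res$overlap@retained, m),
                     oracleOverlapRetained(binsOracle, cfg@overlapFraction))

    mzOracle <- lapply(stacks, function(s) colMeans(s@z))
    tOracle <- oracleOneSampleT(do.call(rbind, mzOracle))
    expect_equal(maskVector(res$tmap@t, m), tOracle, tolerance = 1e-10)
    expect_identical(maskVector(res$tmap@thresholded, m),
                     as.numeric(tOracle > cfg@tThreshold))
})

test_that("build_group_maps is invariant to experiment and participant order", {
    g <- makeTestGrid(c(4L, 4L, 4L))
    m <- makeFullMask(g)
    set.seed(27)
    stacks <- lapply(1:4, function(e)
        ExperimentZStack(sprintf("s%d", e), "NT", m,
                         matrix(rnorm(5 * 64), 5, 64)))
    names(stacks) <- sprintf("s%d", 1:4)
    cfg <- anmConfig(tThreshold = 1)
    r1 <- buildGroupMaps(stacks, m, cfg)
    shuffled <- stacks[c(3, 1, 4, 2)]
    shuffled <- lapply(shuffled, function(s) {
        s@z <- s@z[sample(nrow(s@z)), , drop = FALSE]; s })
    r2 <- buildGroupMaps(shuffled, m, cfg)
    expect_equal(r1$overlap@count@data, r2$overlap@count@data,
                 tolerance = 1e-12)
    expect_equal(r1$tmap@t@data, r2$tmap@t@data, tolerance = 1e-10)
})

test_that("contrasts of identical groups are empty in every mode", {
    g <- makeTestGrid(c(4L, 4L, 4L))
    m <- makeFullMask(g)
    set.seed(28)
    stacks <- lapply(1:4, function(e)
        ExperimentZStack(sprintf("s%d", e), "NT", m,
                         matrix(rnorm(5 * 64, mean = 0.3), 5, 64)))
    names(stacks) <- sprintf("s%d", 1:4)
    cfg0 <- anmConfig(tThreshold = 1.2)
    res <- buildGroupMaps(stacks, m, cfg0)
    for (mode in c("set_difference", "proportion_test", "two_sample_t")) {
        cfg <- anmConfig(tThreshold = 1.2, contrastMode = mode)
        for (branch in c("overlap", "tmap")) {
            ct <- contrastMaps(res, res, cfg, m, which = branch)
            expect_true(all(ct@ntMinusAsd@data == 0), info = mode)
            expect_true(all(ct@asdMinusNt@data == 0), info = mode)
        }
    }
})

test_that("set-difference contrast is exact Boolean algebra", {
    g <- makeTestGrid(c(3L, 3L, 3L))
    m <- makeFullMask(g)
    set.seed(29)
    aRet <- as.numeric(runif(27) > 0.4)
    bRet <- pmin(aRet, as.numeric(runif(27) > 0.3))   # subset of aRet
    mk <- function(ret) list(
        overlap = OverlapMap("NT", vectorToVolume(ret, m, "count"),
                             vectorToVolume(ret, m, "fraction"),
                             vectorToVolume(ret, m, "binary"), 1L),
        tmap = NULL, meanZ = NULL)
    ct <- contrastMaps(mk(aRet), mk(bRet), anmConfig(), m, which = "overlap")
    expect_identical(maskVector(ct@ntMinusAsd, m),
                     as.numeric(aRet == 1 & bRet == 0))
    expect_true(all(maskVector(ct@asdMinusNt, m) == 0))  # b is a subset of a
    expect_true(all(ct@ntMinusAsd@data * ct@asdMinusNt@data == 0))
})

test_that("map similarity is Pearson r with the declared degenerate error", {
    g <- makeTestGrid(c(3L, 3L, 3L))
    m <- makeFullMask(g)
    set.seed(30)
    a <- vectorToVolume(rnorm(27), m, kind = "t")
    expect_equal(mapSimilarity(a, a, m), 1, tolerance = 1e-12)
    neg <- ScalarVolume(g, -a@data, "t")
    expect_equal(mapSimilarity(a, neg, m), -1, tolerance = 1e-12)
    b <- vectorToVolume(rnorm(27), m, kind = "t")
    direct <- {
        va <- maskVector(a, m); vb <- maskVector(b, m)
        sum((va - mean(va)) * (vb - mean(vb))) /
            ((length(va) - 1) * sd(va) * sd(vb))
    }
    expect_equal(mapSimilarity(a, b, m), direct, tolerance = 1e-12)
    expect_error(mapSimilarity(a, ScalarVolume(g, array(1, c(3, 3, 3)), "t"),
                               m), "zero variance")
})

test_that("critical t has its closed-form limits and Bonferroni behaviour", {
    expect_equal(criticalT(0.5, 1), 1, tolerance = 1e-10)  # Cauchy quartile
    expect_equal(criticalT(0.05, 1e7), qnorm(0.975), tolerance = 1e-4)
    # numeric tail-integration oracle at the voxelwise-Bonferroni alpha
    alpha <- 0.05 / 285903
    tcrit <- criticalT(alpha, 999)
    tail <- 2 * integrate(function(x) dt(x, df = 999), tcrit, Inf,
                          rel.tol = 1e-12)$value
    expect_equal(tail, alpha, tolerance = 1e-6)
    expect_gt(tcrit, 5)        # same order as the conventional fixed 5.66
    expect_lt(tcrit, 6)
    expect_error(criticalT(0, 10))
    expect_error(criticalT(0.05, 0))
})

test_that("raising thresholds never grows any retained mask", {
    g <- makeTestGrid(c(5L, 5L, 5L))
    m <- makeFullMask(g)
    set.seed(31)
    stacks <- lapply(1:5, function(e)
        ExperimentZStack(sprintf("s%d", e), "NT", m,
                         matrix(rnorm(6 * 125, mean = 0.4), 6, 125)))
    names(stacks) <- sprintf("s%d", 1:5)
    thresholds <- sort(runif(4, 0.5, 3))
    fracs <- sort(runif(3, 0.2, 0.9))
    prevO <- NULL; prevT <- NULL
    for (th in thresholds) {
        res <- buildGroupMaps(stacks, m, anmConfig(tThreshold = th))
        if (!is.null(prevO)) {
            expect_true(all(res$overlap@count@data <= prevO))
            expect_true(all(res$tmap@thresholded@data <= prevT))
        }
        prevO <- res$overlap@count@data
        prevT <- res$tmap@thresholded@data
    }
    res <- buildGroupMaps(stacks, m, anmConfig(tThreshold = 1))
    prevR <- NULL
    for (f in fracs) {
        om <- overlapMap(lapply(res$experimentT, binarize, threshold = 1),
                         m, overlapFraction = f)
        if (!is.null(prevR))
            expect_true(all(om@retained@data <= prevR))
        prevR <- om@retained@data
    }
})
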