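# Cardiac synchronization: heart-rate spectra, screening, phases, cyclic
# shifts and slice-slice alignment.

test_that("heart rate is recovered from pulsatile series across the band", {
    for (rate in c(115, 137.5, 150, 180)) {
        est <- estimateHeartRate(pulsatileSeries(rate))
        expect_true(est$reliable)
        expect_lt(abs(est$rate - rate), 1)
    }
    # constant series has no spectral peak
    flat <- lapply(pulsatileSeries(150), function(f)
        FrameImage(matrix(1, 12, 12), f@grid, time = f@time, slice = 1L))
    estFlat <- estimateHeartRate(flat)
    expect_false(estFlat$reliable)
    expect_true(is.na(estFlat$rate))
    expect_error(estimateHeartRate(pulsatileSeries(150, nFrames = 8L)),
                 "16 frames")
})

test_that("MAD screening flags weak peaks and interpolates them", {
    mk <- function(slice, rate, height, width, t, reliable = TRUE)
        data.frame(slice = slice, stack = 1L, time = t, rate = rate,
                   height = height, width = width, reliable = reliable,
                   source = "measured")
    est <- do.call(rbind, lapply(1:6, function(i)
        mk(i, 150 + 0.1 * i, 0.05, 10, i)))
    same <- screenAndFillRates(est)
    expect_true(all(same$reliable))
    # one slice with 10x lower peak height is flagged and interpolated
    est2 <- est
    est2$height[3] <- 0.005
    out <- screenAndFillRates(est2)
    expect_false(out$reliable[3])
    expect_equal(out$source[3], "interpolated")
    expect_equal(out$rate[3],
                 approx(out$time[-3], est$rate[-3], xout = out$time[3])$y)
    # endpoint takes the nearest reliable value
    est3 <- est
    est3$height[6] <- 0.001
    out3 <- screenAndFillRates(est3)
    expect_equal(out3$rate[6], est$rate[5])
    # a stack with no reliable slice is an error
    est4 <- est
    est4$reliable <- FALSE
    est4$rate <- NA_real_
    expect_error(screenAndFillRates(est4), "no reliable")
    expect_error(screenAndFillRates(est[1:2, ]), "3 slices")
})

test_that("phase assignment wraps on the R-R interval", {
    times <- c(0, 0.1, 0.4, 0.472)
    th <- assignPhases(times, 150)      # tRR = 0.4 s
    expect_equal(th[1], 0)
    expect_equal(th[3], 0)              # exactly one cycle later
    expect_equal(th[2], 2 * pi * 0.25)
    expect_equal(th[4] - th[1], 0.36 * pi, tolerance = 1e-12)
})

test_that("cyclic Fourier time shift is exact on bin shifts and cyclic", {
    set.seed(41)
    g <- VoxelGrid(c(4, 4, 4), 2)
    X <- CineVolume(array(rnorm(4^3 * 8), c(4, 4, 4, 8)), g)
    expect_equal(cyclicTimeShift(X, 0)@voxels, X@voxels, tolerance = 1e-12)
    expect_equal(cyclicTimeShift(X, 2 * pi)@voxels, X@voxels,
                 tolerance = 1e-9)
    # one phase bin advance equals an integer roll of the phase axis
    sh <- cyclicTimeShift(X, 2 * pi / 8)
    expect_equal(sh@voxels, X@voxels[, , , c(2:8, 1)], tolerance = 1e-9)
    # real input stays real through the Hermitian-symmetric shift
    arb <- cyclicTimeShift(X, 1.234)
    expect_true(is.numeric(arb@voxels))
    expect_error(cyclicTimeShift(CineVolume(array(0, c(4, 4, 4, 1)), g), 1),
                 "2 phases")
})

test_that("slice cines accumulate non-negative volume weights", {
    sim <- testSim(coarseChi, coarseSpec, nStacks = 2L, nSlices = 3L,
                   framesPerSlice = 8L, noiseSd = 0)
    grid <- VoxelGrid(c(16, 16, 16), 3)
    idt <- RigidTransform()
    ks <- which(sim$sliceOfFrame == 1)
    r <- sliceCineAndWeights(sim$frames[ks], rep(list(idt), length(ks)),
                             sim$theta[ks], grid, nPhases = 6L, tRR = 0.4)
    expect_true(all(r$weights >= 0))
    expect_gt(sum(r$weights^2), 0)      # overlap of a slice with itself
    # single-frame slice: weights equal that frame's footprint over phases
    r1 <- sliceCineAndWeights(sim$frames[ks[1]], list(idt),
                              sim$theta[ks[1]], grid, nPhases = 6L,
                              tRR = 0.4)
    w <- psfWeights(sim$frames[[ks[1]]], grid, idt, sim$theta[ks[1]],
                    nPhases = 6L, tRR = 0.4, temporalKernel = "sincPos")
    foot <- outer(as.numeric(Matrix::colSums(w@spatial)), w@temporal)
    expect_equal(unname(as.matrix(r1$weights)), foot, tolerance = 1e-9)
    # slices moved far from the grid leave no footprint: zero overlap
    ks2 <- which(sim$sliceOfFrame == 3)
    far <- RigidTransform(translation = c(500, 0, 0))
    r2 <- sliceCineAndWeights(sim$frames[ks2], rep(list(far), length(ks2)),
                              sim$theta[ks2], grid, nPhases = 6L,
                              tRR = 0.4)
    expect_equal(sum(r$weights * r2$weights), 0)
    expect_error(sliceCineAndWeights(list(), list(), numeric(0), grid,
                                     nPhases = 6L, tRR = 0.4), "empty")
})

test_that("synchronization recovers injected offsets and is gauge invariant", {
    # build one slice cine from the phantom and pre-shift a copy
    g <- VoxelGrid(c(12, 12, 12), 3)
    tc <- resampleCineToGrid(coarseChi, g, 8L)
    w <- matrix(1, prod(g@shape), 8L)
    for (inj in c(pi / 2, 2.3)) {
        shifted <- cyclicTimeShift(tc, inj)   # content advanced by inj
        off <- synchronizeSlices(list(tc, shifted), list(w, w))
        # the shifted slice needs its phases advanced by inj to re-align
        err <- abs(fetalcine4d:::circDist(off[2] - off[1], inj))
        expect_lt(err, 2 * pi / 64)
    }
    # single slice: offset 0 by construction
    expect_equal(unname(synchronizeSlices(list(tc), list(w))), 0)
    # no overlap: offset 0 with a warning
    w0 <- matrix(0, prod(g@shape), 8L)
    expect_warning(off0 <- synchronizeSlices(list(tc, tc), list(w, w0)),
                   "no overlap")
    expect_equal(unname(off0[2]), 0)
})

test_that("sync objective at the chosen offset is no worse than at zero", {
    g <- VoxelGrid(c(12, 12, 12), 3)
    tc <- resampleCineToGrid(coarseChi, g, 8L)
    w <- matrix(1, prod(g@shape), 8L)
    sh1 <- cyclicTimeShift(tc, 1.0)
    sh2 <- cyclicTimeShift(tc, 2.5)
    off <- synchronizeSlices(list(tc, sh1, sh2), list(w, w, w))
    # all relative offsets recovered
    expect_lt(abs(fetalcine4d:::circDist(off[2] - off[1], 1.0)), 2 * pi / 64)
    expect_lt(abs(fetalcine4d:::circDist(off[3] - off[1], 2.5)), 2 * pi / 64)
    # gauge invariance: shifting every slice identically shifts all offsets
    shAll <- lapply(list(tc, sh1, sh2), cyclicTimeShift, thetaOffset = 0.7)
    off2 <- synchronizeSlices(shAll, list(w, w, w))
    expect_lt(abs(fetalcine4d:::circDist(off2[2] - off2[1],
                                         off[2] - off[1])), 2 * pi / 64)
})

test_that("phase error metrics remove the cyclic gauge and convert units", {
    set.seed(43)
    th <- runif(50, 0, 2 * pi)
    expect_equal(phaseRmse(th, (th + 1.1) %% (2 * pi)), 0, tolerance = 1e-9)
    noisy <- (th + rnorm(50, 0, 0.1)) %% (2 * pi)
    expect_lt(abs(phaseRmse(noisy, th) - 0.1), 0.03)
    expect_equal(phaseRmseToMs(pi / 20, 0.404), 10.1)
    expect_equal(phaseRmsePercent(pi / 20), 2.5)
})

test_that("offset screening repairs anti-phase flips in the stack
          progression", {
    tRR <- rep(0.4, 8)
    t0 <- 4.608 * (0:7)              # 64 frames at 72 ms per slice
    truth <- (2 * pi * t0 / 0.4 + 1.1) %% (2 * pi)
    est <- (truth + rnorm(8, 0, 0.05)) %% (2 * pi)
    est[4] <- (est[4] + pi) %% (2 * pi)        # anti-phase flip
    sso <- screenSyncOffsets(est, t0, tRR, rep(1L, 8))
    expect_true(sso$flagged[4])
    expect_lt(sum(sso$flagged), 3)
    expect_lt(abs(fetalcine4d:::circDist(sso$offsets[4], truth[4])), 0.3)
    # a clean progression is left untouched
    clean <- screenSyncOffsets((truth + rnorm(8, 0, 0.03)) %% (2 * pi),
                               t0, tRR, rep(1L, 8))
    expect_false(any(clean$flagged))
})
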