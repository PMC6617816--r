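# Acquisition forward model: PSF weights, projection, residuals,
# intensity matching.

test_that("temporal sinc weight has unit peak, nulls and cyclic symmetry", {
    tRR <- 0.4
    expect_equal(temporalPsfWeight(1.3, 1.3, tRR = tRR), 1)
    dtheta <- 2 * pi * 0.072 / tRR
    expect_equal(temporalPsfWeight(dtheta, 0, tRR = tRR), 0,
                 tolerance = 1e-12)
    th <- seq(0, 2 * pi, length.out = 17)
    expect_equal(temporalPsfWeight(th, 1, tRR = tRR),
                 temporalPsfWeight(1, th, tRR = tRR))
    expect_equal(temporalPsfWeight(th + 2 * pi, 1, tRR = tRR),
                 temporalPsfWeight(th, 1, tRR = tRR))
    expect_error(temporalPsfWeight(0, 0, tRR = 0), "positive")
})

test_that("spatial PSF weights have the expected footprint", {
    # matched grids, thin slice: dominant diagonal
    g <- VoxelGrid(c(8, 8, 8), 2)
    fgThin <- VoxelGrid(c(8, 8, 1), c(2, 2, 0.5),
                        origin = c(-7, -7, 1))   # slice on the z = 1 plane
    fr <- FrameImage(matrix(1, 8, 8), fgThin)
    W <- spatialPsfWeights(fr, g)
    dense <- as.matrix(W)
    # for every pixel the strongest voxel weight is at its own position
    ownVox <- sapply(1:64, function(j) {
        ij <- c((j - 1) %% 8, (j - 1) %/% 8)
        1 + ij[1] + 8 * ij[2] + 64 * 4   # z index 4 (0-based): plane z=1
    })
    for (j in c(1, 12, 33, 64))
        expect_equal(which.max(dense[j, ]), ownVox[j])
    # 6 mm slice on a 1.25 mm grid: through-plane footprint spans >= 4 voxels
    g2 <- VoxelGrid(c(16, 16, 16), 1.25)
    fg6 <- VoxelGrid(c(4, 4, 1), c(1.25, 1.25, 6),
                     origin = c(-1.875, -1.875, 0.3))
    W2 <- spatialPsfWeights(FrameImage(matrix(1, 4, 4), fg6), g2)
    centrePix <- 6
    nz <- which(as.matrix(W2)[centrePix, ] > 0)
    zIdx <- unique((nz - 1) %/% 256)
    expect_gte(length(zIdx), 4)
    expect_error(spatialPsfWeights(FrameImage(matrix(1, 4, 4), fg6),
                                   VoxelGrid(c(4, 4, 4), c(0, 1, 1))),
                 "spacing|degenerate")
})

test_that("weights are equivariant under grid-aligned translation", {
    g <- VoxelGrid(c(10, 10, 10), 2)
    fg <- VoxelGrid(c(6, 6, 1), c(2, 2, 6), origin = c(-5, -5, 1))
    fr <- FrameImage(matrix(1, 6, 6), fg)
    W0 <- spatialPsfWeights(fr, g)
    Wt <- spatialPsfWeights(fr, g, RigidTransform(translation = c(2, 0, 0)))
    # shifting by one voxel along x shifts the sparse pattern by one voxel
    d0 <- as.matrix(W0); dt <- as.matrix(Wt)
    shifted <- array(0, dim(d0))
    a0 <- array(d0, c(36, 10, 10, 10))
    at <- array(dt, c(36, 10, 10, 10))
    expect_equal(at[, 2:10, , ], a0[, 1:9, , ], tolerance = 1e-9)
})

test_that("projection matches a dense brute-force evaluation of the model", {
    # 8^3 grid x 4 phases against a dense triple-loop oracle
    set.seed(21)
    g <- VoxelGrid(c(8, 8, 8), 2)
    fg <- VoxelGrid(c(6, 6, 1), c(2, 2, 6), origin = c(-5, -5, 0.7))
    fr <- FrameImage(matrix(1, 6, 6), fg)
    tr <- RigidTransform(rotation = c(4, -3, 7), translation = c(1, 0.5, -1))
    w <- psfWeights(fr, g, tr, theta = 2.1, nPhases = 4L, tRR = 0.4)
    X <- CineVolume(array(rnorm(8^3 * 4), c(8, 8, 8, 4)), g)
    yhat <- projectFrame(X, w)
    dense <- as.matrix(w@spatial)
    oracle <- numeric(36)
    for (j in 1:36) {
        acc <- 0
        for (h in 1:4) {
            xh <- as.numeric(X@voxels[, , , h])
            acc <- acc + w@temporal[h] * sum(dense[j, ] * xh)
        }
        oracle[j] <- acc
    }
    expect_lt(max(abs(yhat - oracle)), 1e-9)
    # constant preservation and impulse response
    Xc <- CineVolume(array(2.5, c(8, 8, 8, 4)), g)
    expect_lt(max(abs(projectFrame(Xc, w) - 2.5)), 1e-9)
    Ximp <- array(0, c(8, 8, 8, 4)); Ximp[4, 4, 4, 2] <- 1
    imp <- projectFrame(CineVolume(Ximp, g), w)
    vox <- 4 + 8 * 3 + 64 * 3
    expect_equal(imp, w@temporal[2] * dense[, vox], tolerance = 1e-12)
})

test_that("projection is linear and consistent with its adjoint", {
    set.seed(22)
    g <- VoxelGrid(c(8, 8, 8), 2)
    fg <- VoxelGrid(c(6, 6, 1), c(2, 2, 6), origin = c(-5, -5, 0))
    fr <- FrameImage(matrix(1, 6, 6), fg)
    w <- psfWeights(fr, g, theta = 0.4, nPhases = 3L, tRR = 0.4)
    X1 <- CineVolume(array(rnorm(8^3 * 3), c(8, 8, 8, 3)), g)
    X2 <- CineVolume(array(rnorm(8^3 * 3), c(8, 8, 8, 3)), g)
    lhs <- projectFrame(CineVolume(3 * X1@voxels - 2 * X2@voxels, g), w)
    rhs <- 3 * projectFrame(X1, w) - 2 * projectFrame(X2, w)
    expect_lt(max(abs(lhs - rhs)), 1e-9)
    y <- rnorm(36)
    ip1 <- sum(projectFrame(X1, w) * y)
    ad <- fetalcine4d:::adjointFrame(y, w, 8^3, 3)
    ip2 <- sum(matrix(X1@voxels, 8^3, 3) * ad)
    expect_lt(abs(ip1 - ip2) / abs(ip1), 1e-6)
})

test_that("frame residuals subtract elementwise", {
    y <- matrix(runif(4), 2, 2)
    expect_equal(frameResidual(y, y), matrix(0, 2, 2))
    expect_equal(frameResidual(y, matrix(0, 2, 2)), y)
    yhat <- matrix(c(0.1, 0.2, 0.3, 0.4), 2, 2)
    expect_equal(frameResidual(y, yhat), y - yhat)
    expect_error(frameResidual(y, matrix(0, 3, 3)), "mismatch")
})

test_that("intensity matching recovers per-frame scales and shading", {
    g <- testFrameGrid(16L)
    set.seed(23)
    base <- matrix(runif(256, 0.5, 1.5), 16, 16)
    frames <- lapply(1:4, function(k)
        FrameImage(base, g, time = k * 0.1, slice = 1L))
    predicted <- lapply(1:4, function(k) base)
    im <- intensityMatch(frames, predicted, biasSigmaMm = NA)
    expect_equal(im$scales, rep(1, 4), tolerance = 1e-6)
    # one frame multiplied by 2 -> recovered scale 0.5
    frames2 <- frames
    frames2[[2]] <- FrameImage(2 * base, g, time = 0.2, slice = 1L)
    im2 <- intensityMatch(frames2, predicted, biasSigmaMm = NA)
    expect_equal(im2$scales[2], 0.5, tolerance = 1e-6)
    expect_equal(im2$corrected[[2]], base, tolerance = 1e-6)
    # smooth multiplicative shading across the slice is recovered to <2% RMS
    xv <- (seq_len(16) - 8.5) / 16
    shade <- exp(outer(0.3 * xv, 0.2 * xv, `+`))
    frames3 <- lapply(1:6, function(k)
        FrameImage(base * shade, g, time = k * 0.1, slice = 1L))
    predicted3 <- lapply(1:6, function(k) base)
    im3 <- intensityMatch(frames3, predicted3, biasSigmaMm = 8)
    rec <- im3$corrected[[1]]
    expect_lt(sqrt(mean((rec / base - 1)^2)), 0.02)
})
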