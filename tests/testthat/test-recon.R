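# Reconstruction engine: initialization, robust EM, super-resolution steps.

test_that("voxel robust EM separates Gaussian inliers from gross outliers", {
    set.seed(51)
    e <- c(rnorm(2000, 0, 0.05), runif(200, -1, 1))
    fit <- voxelRobustWeights(e, nIter = 30L)
    expect_true(all(diff(fit$loglik) > -1e-8))   # EM monotonicity
    expect_gt(mean(fit$p[1:2000] > 0.5), 0.95)
    # gross residuals at 10 sigma get tiny posteriors
    sigma <- sqrt(fit$params$sigma2)
    e2 <- c(rnorm(500, 0, sigma), rep(10 * sigma, 20))
    fit2 <- voxelRobustWeights(e2, params = fit$params, nIter = 3L)
    expect_lt(max(fit2$p[501:520]), 0.05)
    # all-zero residuals give maximal inlier probability
    fit0 <- voxelRobustWeights(rep(0, 100))
    expect_true(all(fit0$p > 0.999))
    expect_error(voxelRobustWeights(c(1, NA)), "finite")
})

test_that("frame robust EM accepts uniform quality and flags corruption", {
    masks <- rep(list(matrix(TRUE, 8, 8)), 20)
    pv <- rep(list(matrix(0.95, 8, 8)), 20)
    same <- frameRobustWeights(pv, masks)
    expect_equal(same$p, rep(1, 20))
    # 10% corrupted frames: low voxel probabilities -> p_frame < 0.5
    set.seed(52)
    pv2 <- c(rep(list(matrix(0.95, 8, 8)), 18),
             rep(list(matrix(0.30, 8, 8)), 2))
    out <- frameRobustWeights(pv2, rep(list(matrix(TRUE, 8, 8)), 20))
    expect_true(all(out$p[19:20] < 0.5))
    expect_true(all(out$p[1:18] > 0.5))
    expect_true(all(diff(out$loglik) > -1e-6))
    expect_error(frameRobustWeights(pv[1], masks[1]), "2 frames")
})

test_that("initialization reproduces constants and matches the phantom", {
    sim <- testSim(staticChi, staticSpec, nStacks = 3L, nSlices = 6L,
                   framesPerSlice = 2L, noiseSd = 0)
    idt <- lapply(sim$frames, function(f) RigidTransform())
    grid <- VoxelGrid(c(24, 24, 24), 2)
    # constant frames -> constant volume over the covered region
    const <- lapply(sim$frames, function(f)
        FrameImage(matrix(3.3, nrow(f@pixels), ncol(f@pixels)), f@grid,
                   time = f@time, slice = f@slice, stack = f@stack))
    ini <- initializeCine(const, idt, volGrid = grid)
    covered <- ini$weightSum[, 1] > 1e-6
    expect_lt(max(abs(ini$cine@voxels[, , , 1][covered] - 3.3)), 1e-6)
    # dense noiseless sampling of the static phantom: blur-limited NRMSE
    ini2 <- initializeCine(sim$frames, idt, volGrid = grid)
    hm <- heartMaskVolume(grid, staticSpec)
    nrmse <- evaluateNrmse(ini2$cine, staticChi, mask = hm)
    expect_lt(nrmse, 0.15)
    # zero-weight voxels are flagged and filled
    expect_true(any(ini2$filled) || all(ini2$weightSum > 0))
    expect_error(initializeCine(sim$frames[1], idt[1],
                                volGrid = VoxelGrid(c(4, 4, 4), 1,
                                                    origin = c(500, 0, 0))),
                 "empty")
})

test_that("with unit weights and no regularisation the dense least-squares
          solution is a fixed point (normal-equations oracle)", {
    set.seed(53)
    g <- VoxelGrid(c(8, 8, 8), 2)
    frames <- list()
    for (z in c(-3, 0.5, 3)) for (d in 1:2) {
        D <- if (d == 1) diag(3) else
            cbind(c(0, 1, 0), c(0, 0, 1), c(1, 0, 0))
        og <- as.numeric(D[, 3] * z - D[, 1] * 7 - D[, 2] * 7)
        fg <- VoxelGrid(c(8, 8, 1), c(2, 2, 6), origin = og, directions = D)
        frames[[length(frames) + 1]] <-
            FrameImage(matrix(runif(64), 8, 8), fg,
                       slice = length(frames) + 1L)
    }
    idt <- lapply(frames, function(f) RigidTransform())
    cfg <- ReconConfig(spacing = 2, nPhases = 1L, lambda = 0, nSR = 1L)
    A <- do.call(rbind, lapply(frames, function(f)
        as.matrix(spatialPsfWeights(f, g))))
    y <- unlist(lapply(frames, function(f) as.numeric(f@pixels)))
    ls <- lm.fit(A, y)
    xls <- ifelse(is.na(ls$coefficients), 0, ls$coefficients)
    Xls <- CineVolume(array(xls, c(8, 8, 8, 1)), g)
    cache <- fetalcine4d:::buildPsfCache(frames, g, idt, NULL, 1L, NA)
    ys <- lapply(frames, function(f) f@pixels)
    p1 <- lapply(ys, function(v) array(1, dim(v)))
    st <- srStep(Xls, ys, p1, cache, cfg, 1)
    # the gradient of the data term vanishes at the least-squares solution;
    # check where the system is well observed (elsewhere the LS solution is
    # not unique and numerically ill-conditioned)
    den <- as.numeric(crossprod(A, rep(1, nrow(A))))
    idx <- den > 0.05 * max(den)
    diffv <- abs(as.numeric(st$X@voxels) - xls)
    expect_lt(max(diffv[idx]), 1e-6 * max(1, max(abs(xls[idx]))))
})

test_that("a volume exactly consistent with the frames is stationary", {
    set.seed(54)
    g <- VoxelGrid(c(8, 8, 8), 2)
    X0 <- CineVolume(array(runif(8^3), c(8, 8, 8, 1)), g)
    fg <- VoxelGrid(c(8, 8, 1), c(2, 2, 6), origin = c(-7, -7, 1))
    frames <- lapply(c(0, 1), function(i) {
        f <- FrameImage(matrix(1, 8, 8), fg, slice = i + 1L)
        w <- psfWeights(f, g)
        FrameImage(matrix(projectFrame(X0, w), 8, 8), fg, slice = i + 1L)
    })
    idt <- lapply(frames, function(f) RigidTransform())
    cfg <- ReconConfig(spacing = 2, nPhases = 1L, lambda = 0, nSR = 1L)
    cache <- fetalcine4d:::buildPsfCache(frames, g, idt, NULL, 1L, NA)
    ys <- lapply(frames, function(f) f@pixels)
    p1 <- lapply(ys, function(v) array(1, dim(v)))
    st <- srStep(X0, ys, p1, cache, cfg, 1)
    expect_lt(max(abs(st$X@voxels - X0@voxels)), 1e-9)
})

test_that("the super-resolution objective is non-increasing", {
    sim <- testSim(staticChi, staticSpec, nStacks = 3L, nSlices = 6L,
                   framesPerSlice = 2L, noiseSd = 0)
    idt <- lapply(sim$frames, function(f) RigidTransform())
    grid <- VoxelGrid(c(20, 20, 20), 2.5)
    cfg <- ReconConfig(spacing = 2.5, nPhases = 1L, lambda = 0.02,
                       delta = 0.15, nSR = 10L)
    rec <- reconstruct(sim$frames, idt, volGrid = grid, config = cfg,
                       mode = "static", robust = FALSE, bias = FALSE,
                       intensity = FALSE)
    expect_true(all(diff(rec$diagnostics$objective) < 1e-8))
})

test_that("static mode equals cine mode with a single phase", {
    sim <- testSim(staticChi, staticSpec, nStacks = 2L, nSlices = 4L,
                   framesPerSlice = 2L, noiseSd = 0)
    idt <- lapply(sim$frames, function(f) RigidTransform())
    grid <- VoxelGrid(c(16, 16, 16), 3)
    cfg <- ReconConfig(spacing = 3, nPhases = 1L, nSR = 3L)
    a <- reconstruct(sim$frames, idt, volGrid = grid, config = cfg,
                     mode = "static", robust = FALSE, bias = FALSE)
    b <- reconstruct(sim$frames, idt, theta = rep(0, length(sim$frames)),
                     volGrid = grid, config = cfg, tRR = 0.4, mode = "cine",
                     robust = FALSE, bias = FALSE)
    expect_equal(a$cine@voxels, b$cine@voxels, tolerance = 1e-12)
})

test_that("reconstruction error is unchanged when frames and truth move
          together", {
    sim <- testSim(staticChi, staticSpec, nStacks = 2L, nSlices = 4L,
                   framesPerSlice = 2L, noiseSd = 0)
    grid <- VoxelGrid(c(20, 20, 20), 2.5)
    cfg <- ReconConfig(spacing = 2.5, nPhases = 1L, nSR = 5L)
    hm <- heartMaskVolume(grid, staticSpec)
    idt <- lapply(sim$frames, function(f) RigidTransform())
    base <- reconstruct(sim$frames, idt, volGrid = grid, config = cfg,
                        mode = "static", robust = FALSE, bias = FALSE,
                        truth = staticChi, truthMask = hm)
    # same frames with all transforms (and the evaluation) rigidly moved
    mv <- RigidTransform(rotation = c(0, 0, 10), translation = c(3, -2, 1))
    moved <- lapply(sim$frames, function(f) f)
    trs <- lapply(sim$frames, function(f) mv)
    gridMv <- grid
    recMv <- reconstruct(moved, trs, volGrid = gridMv, config = cfg,
                         mode = "static", robust = FALSE, bias = FALSE)
    # resample the moved reconstruction back and compare NRMSE
    co <- fetalcine4d:::gridWorldCoords(grid)
    back <- sampleVolume(recMv$cine@voxels[, , , 1], grid,
                         transformPoints(mv, co))
    truthVol <- resampleCineToGrid(staticChi, grid, 1L)@voxels[, , , 1]
    inref <- hm & array(is.finite(back) & back > 0, grid@shape)
    nrmseMv <- sqrt(mean((back[inref] - truthVol[inref])^2)) /
        sqrt(mean(truthVol[inref]^2))
    nrmseBase <- tail(base$diagnostics$nrmse, 1)
    expect_lt(abs(nrmseMv - nrmseBase), 0.05)
})
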