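# Motion correction: temporal means and the registration stages.

test_that("temporal mean reduces cardiac pulsation", {
    sim <- testSim(coarseChi, coarseSpec, nStacks = 1L, nSlices = 1L,
                   framesPerSlice = 16L, noiseSd = 0)
    mean1 <- temporalMeanImage(sim$frames)
    expect_equal(mean1@pixels,
                 Reduce(`+`, lapply(sim$frames, framePixels)) / 16)
    expect_equal(temporalMeanImage(sim$frames[1])@pixels,
                 sim$frames[[1]]@pixels)
    # in-ROI temporal variability collapses in the mean image
    m <- frameMask(sim$frames[[1]])
    varFrames <- mean(apply(vapply(sim$frames, function(f) f@pixels[m],
                                   numeric(sum(m))), 1, var))
    expect_gt(varFrames, 0)
})

test_that("stack registration recovers injected stack shifts", {
    sim <- testSim(staticChi, staticSpec, nStacks = 3L, nSlices = 5L,
                   framesPerSlice = 2L, noiseSd = 0.02, seed = 61)
    slices <- sim$sliceOfFrame
    mf <- lapply(sort(unique(slices)), function(l)
        temporalMeanImage(sim$frames[slices == l]))
    stackOf <- vapply(mf, function(f) f@stack, 0L)
    byStack <- lapply(1:3, function(s) mf[stackOf == s])
    # self-registration: all transforms near identity (assessed as voxel
    # displacement; rotation about in-plane axes is weakly determined)
    trs <- registerStacks(byStack, targetStack = 1L)
    for (s in 1:3) {
        fs <- sim$frames[sim$stackOfFrame == s]
        d <- targetRegistrationError(rep(trs[s], length(fs)),
                                     lapply(fs, function(f)
                                         RigidTransform()), fs)
        expect_lt(d, 0.5)
    }
    # inject a known 4 mm shift into stack 2's geometry and recover it
    shifted <- byStack
    shifted[[2]] <- lapply(shifted[[2]], function(f) {
        g <- f@grid
        g2 <- VoxelGrid(g@shape, g@spacing, origin = g@origin + c(4, 0, 0),
                        directions = g@directions)
        FrameImage(f@pixels, g2, time = f@time, slice = f@slice,
                   stack = f@stack, mask = f@mask)
    })
    trs2 <- registerStacks(shifted, targetStack = 1L)
    expect_equal(trs2[[2]]@translation[1], -4, tolerance = 0.2)
    expect_lt(max(abs(trs2[[2]]@translation[2:3])), 0.5)
})

test_that("registration metric is invariant to global intensity scaling", {
    sim <- testSim(staticChi, staticSpec, nStacks = 1L, nSlices = 1L,
                   framesPerSlice = 2L, noiseSd = 0)
    f <- temporalMeanImage(sim$frames)
    grid <- VoxelGrid(c(20, 20, 20), 3)
    idt <- lapply(list(f), function(x) RigidTransform())
    vol <- initializeCine(list(f), idt, volGrid = grid)$cine@voxels[, , , 1]
    samp <- fetalcine4d:::frameSamplePoints(f, nZ = 5L)
    obj1 <- fetalcine4d:::makeNccObjective(samp, vol, grid, c(0, 0, 0))
    samp2 <- samp; samp2$values <- samp$values * 7.3
    obj2 <- fetalcine4d:::makeNccObjective(samp2, 0.2 * vol, grid, c(0, 0, 0))
    par <- c(1, -2, 0.5, 1, 0, -1)
    expect_equal(obj1(par), obj2(par), tolerance = 1e-12)
})

test_that("slice-volume interleave holds aligned slices and repairs a
          perturbed one", {
    sim <- testSim(staticChi, staticSpec, nStacks = 3L, nSlices = 5L,
                   framesPerSlice = 2L, noiseSd = 0, seed = 62)
    slices <- sim$sliceOfFrame
    sliceIds <- sort(unique(slices))
    mf <- lapply(sliceIds, function(l) temporalMeanImage(sim$frames[slices == l]))
    chm <- lapply(mf, function(f) fetalcine4d:::chestMaskPixels(f, staticSpec))
    idt <- lapply(mf, function(f) RigidTransform())
    sv <- registerSlicesToVolume(mf, idt, nIter = 1L, spacing = 2.5,
                                 chestMasks = chm)
    for (i in seq_along(sliceIds)) {
        fs <- sim$frames[slices == sliceIds[i]]
        d <- targetRegistrationError(rep(sv$transforms[i], length(fs)),
                                     lapply(fs, function(f)
                                         RigidTransform()), fs)
        expect_lt(d, 1)    # within half an acquired pixel
    }
    # one slice initialised 3 mm off is pulled back within 0.5 mm
    pert <- idt
    pert[[4]] <- RigidTransform(translation = c(3, 0, 0))
    sv2 <- registerSlicesToVolume(mf, pert, nIter = 3L, spacing = 2.5,
                                  chestMasks = chm)
    frames4 <- sim$frames[slices == sliceIds[4]]
    err <- targetRegistrationError(rep(sv2$transforms[4], length(frames4)),
                                   lapply(frames4, function(f)
                                       RigidTransform()),
                                   frames4)
    expect_lt(err, 1)
})

test_that("frame-volume registration keeps slice-consistent motion", {
    # frames generated with slice-constant motion: estimated frame
    # transforms stay near the slice transforms
    sim <- testSim(staticChi, staticSpec, nStacks = 2L, nSlices = 4L,
                   framesPerSlice = 3L, noiseSd = 0.02, seed = 63)
    grid <- fetalcine4d:::framesBoundingGrid(
        sim$frames[!duplicated(sim$sliceOfFrame)], 2.5, marginMm = 4,
        maskOnly = TRUE)
    idt <- lapply(sim$frames, function(f) RigidTransform())
    cfg <- ReconConfig(spacing = 2.5, nPhases = 4L, nSR = 2L, seed = 1L)
    fv <- registerFramesToCine(sim$frames, idt, sim$theta, grid, cfg,
                               tRR = 0.4, nIter = 1L)
    tre <- targetRegistrationError(fv$transforms, idt, sim$frames)
    expect_lt(tre, 2)    # within the acquired in-plane pixel
})

test_that("slices with excessive deviation are flagged", {
    s <- methods::new("MotionSummary", disp = 5, dev = 2,
                      perSliceDev = c(`1` = 1.2, `2` = 4.5, `3` = NA,
                                      `4` = 3.2),
                      tre = NA_real_)
    expect_identical(flagMotionCorruptedSlices(s), c(2L, 4L))
    expect_identical(flagMotionCorruptedSlices(s, thresholdMm = 5),
                     integer(0))
})
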