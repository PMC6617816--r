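# Rigid-body geometry, Frechet means and motion metrics.

test_that("transformPoints applies rotations and translations correctly", {
    pts <- matrix(rnorm(15), 5, 3)
    expect_equal(transformPoints(RigidTransform(), pts), pts)
    expect_equal(as.numeric(
        transformPoints(RigidTransform(translation = c(1, 0, 0)),
                        c(0, 0, 0))), c(1, 0, 0))
    # 90 degrees about z maps x onto y (hand rotation-matrix check)
    expect_equal(as.numeric(
        transformPoints(RigidTransform(rotation = c(0, 0, 90)),
                        c(1, 0, 0))), c(0, 1, 0), tolerance = 1e-12)
    expect_error(transformPoints(RigidTransform(), matrix(c(1, NA, 0), 1, 3)),
                 "finite")
})

test_that("rigid transforms preserve distances and compose/invert exactly", {
    set.seed(7)
    for (i in 1:10) {
        tr <- RigidTransform(rotation = runif(3, -90, 90),
                             translation = runif(3, -20, 20),
                             centre = runif(3, -10, 10))
        pts <- matrix(rnorm(30, sd = 20), 10, 3)
        out <- transformPoints(tr, pts)
        expect_lt(max(abs(dist(out) - dist(pts))), 1e-9)
        # rotation matrix is proper
        expect_equal(det(rotationMatrix <- transformMatrix(tr)[1:3, 1:3]), 1,
                     tolerance = 1e-12)
        # composition with the inverse is the identity to 1e-9 mm
        back <- transformPoints(invertTransform(tr), out)
        expect_lt(max(abs(back - pts)), 1e-9)
        both <- composeTransforms(invertTransform(tr), tr)
        expect_lt(max(abs(transformPoints(both, pts) - pts)), 1e-9)
    }
})

test_that("se(3) log and exp are mutually inverse", {
    set.seed(11)
    for (i in 1:10) {
        v <- c(runif(3, -1, 1), runif(3, -10, 10))
        expect_equal(fetalcine4d:::logSE3(fetalcine4d:::expSE3(v)), v,
                     tolerance = 1e-9)
    }
    expect_equal(fetalcine4d:::logSE3(diag(4)), rep(0, 6))
})

test_that("Frechet mean degenerate and symmetric cases", {
    tr <- RigidTransform(rotation = c(5, -3, 10), translation = c(1, 2, 3))
    m <- meanSliceTransform(list(tr, tr, tr), c(0.2, 0.5, 0.3))
    expectTransformsEqual(m, tr, 1e-6, 1e-6)
    # linear sub-case: two pure translations average
    m2 <- meanSliceTransform(list(RigidTransform(),
                                  RigidTransform(translation = c(2, 0, 0))))
    expectTransformsEqual(m2, RigidTransform(translation = c(1, 0, 0)),
                          1e-6, 1e-6)
    # opposite rotations cancel (log-space average oracle)
    m3 <- meanSliceTransform(list(RigidTransform(rotation = c(0, 0, 10)),
                                  RigidTransform(rotation = c(0, 0, -10))))
    expectTransformsEqual(m3, RigidTransform(), 1e-5, 1e-5)
    # weights concentrated on one transform return that transform
    other <- RigidTransform(rotation = c(20, 0, 0), translation = c(5, 5, 5))
    m4 <- meanSliceTransform(list(tr, other), c(1, 0))
    expectTransformsEqual(m4, tr, 1e-6, 1e-6)
    # invariant under permutation of inputs
    set.seed(3)
    trs <- lapply(1:4, function(i)
        RigidTransform(runif(3, -10, 10), runif(3, -5, 5)))
    w <- c(0.1, 0.4, 0.2, 0.3)
    p <- c(3, 1, 4, 2)
    expectTransformsEqual(meanSliceTransform(trs, w),
                          meanSliceTransform(trs[p], w[p]), 1e-5, 1e-5)
    expect_error(meanSliceTransform(trs, rep(0, 4)), "weights")
})

makeToyFrame <- function(maskIdx = NULL, slice = 1L, npx = 5L) {
    g <- VoxelGrid(c(npx, npx, 1L), c(2, 2, 6),
                   origin = c(-(npx - 1), -(npx - 1), 0))
    m <- matrix(FALSE, npx, npx)
    if (is.null(maskIdx)) m[] <- TRUE else m[maskIdx] <- TRUE
    FrameImage(matrix(1, npx, npx), g, slice = slice, mask = m)
}

test_that("global displacement matches a per-voxel brute-force oracle", {
    frames <- list(makeToyFrame(), makeToyFrame(slice = 2L))
    idt <- list(RigidTransform(), RigidTransform())
    expect_equal(globalDisplacement(idt, frames), 0)
    tr3 <- lapply(frames, function(f) RigidTransform(translation = c(3, 0, 0)))
    expect_equal(globalDisplacement(tr3, frames), 3)
    # mixed rotations: compare against an explicit per-voxel loop
    trs <- list(RigidTransform(rotation = c(0, 0, 30), centre = c(1, 2, 0)),
                RigidTransform(rotation = c(10, -5, 3),
                               translation = c(1, -2, 0.5)))
    tot <- 0; n <- 0
    for (k in 1:2) {
        y <- fetalcine4d:::frameMaskWorld(frames[[k]])
        for (j in seq_len(nrow(y))) {
            tot <- tot + sqrt(sum((transformPoints(trs[[k]], y[j, , drop = FALSE]) -
                                       y[j, ])^2))
            n <- n + 1
        }
    }
    expect_equal(globalDisplacement(trs, frames), tot / n, tolerance = 1e-12)
    expect_error(globalDisplacement(list(), list()), "empty")
})

test_that("frames contributing few in-mask voxels are excluded from disp", {
    big <- lapply(1:4, function(i) makeToyFrame(npx = 9L))
    tiny <- makeToyFrame(maskIdx = 1L, npx = 9L)  # 1 voxel < median(81)/10
    frames <- c(big, list(tiny))
    trs <- c(lapply(1:4, function(i) RigidTransform()),
             list(RigidTransform(translation = c(100, 0, 0))))
    expect_equal(globalDisplacement(trs, frames), 0)
})

test_that("deviation from slice mean matches hand computations", {
    f <- list(makeToyFrame(slice = 1L), makeToyFrame(slice = 1L),
              makeToyFrame(slice = 2L))
    shared <- RigidTransform(rotation = c(0, 0, 45), translation = c(3, 1, 0))
    s <- deviationFromSliceMean(list(shared, shared, shared), f)
    expect_lt(s@dev, 1e-6)
    expect_s4_class(s, "MotionSummary")
    # two-frame slice, translations 0 and 2 mm -> mean 1 mm shift, dev 1 mm
    f2 <- list(makeToyFrame(slice = 1L), makeToyFrame(slice = 1L))
    s2 <- deviationFromSliceMean(
        list(RigidTransform(), RigidTransform(translation = c(2, 0, 0))), f2)
    expect_equal(s2@dev, 1, tolerance = 1e-6)
    expect_equal(unname(s2@perSliceDev["1"]), 1, tolerance = 1e-6)
    # slice with zero total weight reports NA
    s3 <- deviationFromSliceMean(
        list(RigidTransform(), RigidTransform(), RigidTransform()), f,
        frameWeights = c(1, 1, 0))
    expect_true(is.na(s3@perSliceDev["2"]))
})

test_that("target registration error matches the brute-force oracle", {
    frames <- list(makeToyFrame(), makeToyFrame())
    idt <- list(RigidTransform(), RigidTransform())
    expect_equal(targetRegistrationError(idt, idt, frames), 0)
    sh <- lapply(idt, function(t) RigidTransform(translation = c(0, 1, 0)))
    expect_equal(targetRegistrationError(sh, idt, frames), 1)
    # symmetry
    set.seed(5)
    est <- lapply(1:2, function(i) RigidTransform(runif(3, -5, 5),
                                                  runif(3, -2, 2)))
    expect_equal(targetRegistrationError(est, idt, frames),
                 targetRegistrationError(idt, est, frames))
    # brute force on random small perturbations
    tot <- 0; n <- 0
    for (k in 1:2) {
        y <- fetalcine4d:::frameMaskWorld(frames[[k]])
        d <- sqrt(rowSums((transformPoints(est[[k]], y) -
                               transformPoints(idt[[k]], y))^2))
        tot <- tot + sum(d); n <- n + length(d)
    }
    expect_equal(targetRegistrationError(est, idt, frames), tot / n)
    expect_error(targetRegistrationError(est[1], idt, frames), "matching")
})

test_that("transform CSV serialization round-trips bit-exactly", {
    set.seed(9)
    trs <- lapply(1:5, function(i)
        RigidTransform(rnorm(3) * pi, rnorm(3) * exp(1), rnorm(3)))
    path <- tempfile(fileext = ".csv")
    writeTransforms(trs, path)
    back <- readTransforms(path)
    for (i in 1:5) {
        expect_identical(back[[i]]@rotation, trs[[i]]@rotation)
        expect_identical(back[[i]]@translation, trs[[i]]@translation)
        expect_identical(back[[i]]@centre, trs[[i]]@centre)
    }
})

test_that("Lie-algebra scaling of transforms is linear for translations", {
    tr <- RigidTransform(translation = c(4, -2, 6))
    half <- scaleTransform(tr, 0.5)
    expect_equal(half@translation, c(2, -1, 3), tolerance = 1e-9)
    expectTransformsEqual(scaleTransform(tr, 0), RigidTransform())
    expect_error(scaleTransform(tr, -1), ">= 0")
})
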