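# Three-stage rigid motion correction: stack-stack, slice-volume and
# frame-volume registration, interleaved with reconstruction.
# Similarity metric: normalized cross-correlation, optimised over the six
# rigid parameters by Nelder-Mead with a multi-resolution pyramid.

#' Temporal mean image of a slice
#'
#' Pixelwise mean of the magnitude frames of one slice: a static reference,
#' largely free of cardiac pulsation, used by the first two registration
#' stages.
#'
#' @param sliceFrames list of [FrameImage-class] from one slice.
#' @return A [FrameImage-class] carrying the mean image (mask and geometry
#'   of the first frame).
#' @export
temporalMeanImage <- function(sliceFrames) {
    if (length(sliceFrames) == 0L) stop("no frames")
    acc <- Reduce(`+`, lapply(sliceFrames, function(f) abs(f@pixels)))
    f1 <- sliceFrames[[1]]
    FrameImage(acc / length(sliceFrames), f1@grid, time = f1@time,
               slice = f1@slice, stack = f1@stack, mask = f1@mask)
}

# in-plane block-mean downsampling of a frame image by integer factor
downsampleFrame <- function(frame, factor) {
    if (factor <= 1L) return(frame)
    g <- frame@grid
    n <- g@shape[1:2] %/% factor
    px <- frame@pixels[seq_len(n[1] * factor), seq_len(n[2] * factor),
                       drop = FALSE]
    dsm <- function(m) {
        m <- (m[seq(1, nrow(m), 2), , drop = FALSE] +
              m[seq(2, nrow(m), 2), , drop = FALSE]) / 2
        (m[, seq(1, ncol(m), 2), drop = FALSE] +
         m[, seq(2, ncol(m), 2), drop = FALSE]) / 2
    }
    out <- px
    f <- factor
    while (f > 1) { out <- dsm(out); f <- f / 2 }
    msk <- frame@mask[seq(1, nrow(frame@mask), factor),
                      seq(1, ncol(frame@mask), factor), drop = FALSE]
    msk <- msk[seq_len(n[1]), seq_len(n[2]), drop = FALSE]
    sp <- c(g@spacing[1:2] * factor, g@spacing[3])
    off <- g@directions[, 1:2] %*% ((factor - 1) / 2 * g@spacing[1:2])
    gd <- VoxelGrid(c(n, 1L), sp, origin = g@origin + as.numeric(off),
                    directions = g@directions)
    FrameImage(pmax(out, 0), gd, time = frame@time, slice = frame@slice,
               stack = frame@stack, mask = msk)
}

# sampled points of a frame: masked pixel centres replicated over the
# through-plane Gaussian quadrature offsets
frameSamplePoints <- function(frame, nZ = 5L, maskOnly = TRUE) {
    g <- frame@grid
    keep <- if (maskOnly) as.logical(frame@mask) else
        rep(TRUE, length(frame@pixels))
    P <- framePixelWorld(g)[keep, , drop = FALSE]
    y <- as.numeric(abs(frame@pixels))[keep]
    sz <- g@spacing[3] * FWHM2SD
    if (nZ > 1L) {
        zoff <- seq(-2 * sz, 2 * sz, length.out = nZ)
        zw <- dnorm(zoff, 0, sz); zw <- zw / sum(zw)
    } else {
        zoff <- 0; zw <- 1
    }
    nrm <- g@directions[, 3]
    pts <- do.call(rbind, lapply(zoff, function(o)
        cbind(P[, 1] + o * nrm[1], P[, 2] + o * nrm[2], P[, 3] + o * nrm[3])))
    list(pts = pts, values = y, zw = zw, n = length(y))
}

# NCC objective for a point set against a volume; returns function(par)
makeNccObjective <- function(sample, vol, volGrid, centre) {
    pts <- sample$pts; y <- sample$values; zw <- sample$zw; n <- sample$n
    function(par) {
        tr <- RigidTransform(rotation = par[1:3], translation = par[4:6],
                             centre = centre)
        q <- transformPoints(tr, pts)
        v <- sampleVolume(vol, volGrid, q, outside = NA_real_)
        acc <- numeric(n); wsum <- numeric(n)
        for (z in seq_along(zw)) {
            vz <- v[(z - 1) * n + seq_len(n)]
            ok <- !is.na(vz)
            acc[ok] <- acc[ok] + zw[z] * vz[ok]
            wsum[ok] <- wsum[ok] + zw[z]
        }
        valid <- wsum > 0.5
        if (sum(valid) < 30) return(2)
        -weightedPearson(y[valid], acc[valid] / wsum[valid],
                         rep(1, sum(valid)))
    }
}

# Nelder-Mead registration of a sampled point set to a volume
registerSampleToVolume <- function(sample, vol, volGrid, init, centre,
                                   maxit = 150L, reltol = 1e-7,
                                   restarts = 1L) {
    if (restarts < 0L) restarts <- 0L
    obj <- makeNccObjective(sample, vol, volGrid, centre)
    tr0 <- transformFromMatrix(transformMatrix(init), centre)
    par0 <- c(tr0@rotation, tr0@translation)
    m0 <- obj(par0)
    op <- optim(par0, obj, method = "Nelder-Mead",
                control = list(maxit = maxit, reltol = reltol))
    # re-start the simplex at the optimum: recovers from premature collapse
    for (r in seq_len(restarts)) {
        op2 <- optim(op$par, obj, method = "Nelder-Mead",
                     control = list(maxit = maxit, reltol = reltol))
        if (op2$value < op$value) op <- op2 else break
    }
    list(transform = RigidTransform(op$par[1:3], op$par[4:6], centre),
         metricInit = -m0, metricFinal = -op$value)
}

#' Register stacks to a target stack
#'
#' Rigid 3D registration of each stack's temporal-mean slices to a static
#' volume interpolated from the target stack, by multi-resolution normalized
#' cross-correlation. The target stack receives the identity; a registration
#' whose final metric is worse than its initial value is discarded with a
#' warning and the identity retained.
#'
#' @param meanFramesByStack list (per stack) of lists of temporal-mean
#'   [FrameImage-class] (one per slice).
#' @param targetStack index of the target stack.
#' @param centre rotation centre, mm (default: heart-mask centroid of the
#'   target stack).
#' @param spacing grid spacing of the intermediate target volume, mm.
#' @param pyramid in-plane downsampling factors, coarse to fine.
#' @return list of per-stack [RigidTransform-class].
#' @export
registerStacks <- function(meanFramesByStack, targetStack = 1L,
                           centre = NULL, spacing = 2.5,
                           pyramid = c(4L, 2L, 1L)) {
    nS <- length(meanFramesByStack)
    tgt <- meanFramesByStack[[targetStack]]
    if (is.null(centre)) centre <- maskCentroid(tgt)
    grid <- framesBoundingGrid(tgt, spacing, marginMm = 8)
    ident <- lapply(tgt, function(f) RigidTransform())
    vinit <- initializeCine(tgt, ident, volGrid = grid)
    vol <- vinit$cine@voxels[, , , 1]
    out <- vector("list", nS)
    for (s in seq_len(nS)) {
        if (s == targetStack) { out[[s]] <- RigidTransform(centre = centre); next }
        tr <- RigidTransform(centre = centre)
        res <- NULL
        for (f in pyramid) {
            frames <- lapply(meanFramesByStack[[s]], downsampleFrame,
                             factor = f)
            samp <- poolSamples(lapply(frames, frameSamplePoints,
                                       nZ = 3L, maskOnly = FALSE))
            vf <- downsampleVolume(vol, f)
            gf <- downsampleGrid(grid, f)
            res <- registerSampleToVolume(samp, vf, gf, tr, centre,
                                          maxit = if (f > 1) 120L else 80L)
            tr <- res$transform
        }
        if (res$metricFinal < res$metricInit - 1e-9) {
            warning("stack ", s, " registration diverged; identity retained")
            tr <- RigidTransform(centre = centre)
        }
        out[[s]] <- tr
    }
    out
}

# pool several frame samples into one point set (shared z-quadrature)
poolSamples <- function(samples) {
    n <- sum(vapply(samples, function(s) s$n, 0L))
    zw <- samples[[1]]$zw
    nz <- length(zw)
    pts <- matrix(0, n * nz, 3)
    vals <- numeric(n)
    pos <- 0
    for (z in seq_len(nz)) {
        pos2 <- 0
        for (s in samples) {
            idx <- (z - 1) * n + pos2 + seq_len(s$n)
            pts[idx, ] <- s$pts[(z - 1) * s$n + seq_len(s$n), , drop = FALSE]
            if (z == 1) vals[pos2 + seq_len(s$n)] <- s$values
            pos2 <- pos2 + s$n
        }
    }
    list(pts = pts, values = vals, zw = zw, n = n)
}

# centroid of the heart masks of a list of frames, world mm
maskCentroid <- function(frames) {
    pts <- do.call(rbind, lapply(frames, frameMaskWorld))
    colMeans(pts)
}

# axis-aligned grid covering the (masked or full) extent of frames
framesBoundingGrid <- function(frames, spacing, marginMm = 5,
                               maskOnly = FALSE) {
    pts <- do.call(rbind, lapply(frames, function(f) {
        if (maskOnly) frameMaskWorld(f) else framePixelWorld(f@grid)
    }))
    lo <- apply(pts, 2, min) - marginMm
    hi <- apply(pts, 2, max) + marginMm
    shape <- pmax(2L, as.integer(ceiling((hi - lo) / spacing)) + 1L)
    VoxelGrid(shape, spacing, origin = lo)
}


# fix the gauge of an interleaved registration: the consensus volume pose
# is a free gauge, so the transform set is rigidly re-anchored after every
# sweep so that its Frechet mean is the identity -- the reconstruction is
# placed at the average pose of the data
reanchorTransforms <- function(transforms, centre) {
    m <- meanSliceTransform(transforms, centre = centre)
    D <- invertTransform(m)
    lapply(transforms, function(t) composeTransforms(D, t, centre = centre))
}

#' Interleaved slice-volume registration and static reconstruction
#'
#' Each slice's temporal-mean image is rigidly registered (2D slice into 3D
#' volume, sampling the volume along the slice PSF footprint) to the static
#' volume interpolated from all *other* slices at their current transforms
#' (a leave-one-out target, so a slice never registers to its own imprint),
#' within the chest volume-of-interest. Transforms and the consensus volume
#' are updated over `nIter` sweeps; the returned volume is a full static
#' reconstruction with the final transforms. Slices with fewer than 10
#' in-mask pixels are skipped, and a result that lowers the similarity
#' metric falls back to the previous transform.
#'
#' @param meanFrames list of temporal-mean [FrameImage-class], one per slice.
#' @param initTransforms per-slice initial transforms (e.g. the stack
#'   transforms).
#' @param nIter number of interleave sweeps (default 3).
#' @param spacing static reconstruction spacing, mm.
#' @param centre rotation centre (default heart-mask centroid).
#' @param chestMasks optional list of logical pixel masks (chest region) per
#'   slice; default: all pixels.
#' @param config optional [ReconConfig-class] controlling the final static
#'   reconstruction.
#' @return list with `transforms` (per slice), `volume` (final static
#'   [CineVolume-class]) and `grid`.
#' @export
registerSlicesToVolume <- function(meanFrames, initTransforms, nIter = 4L,
                                   spacing = 2.5, centre = NULL,
                                   chestMasks = NULL, config = NULL) {
    nl <- length(meanFrames)
    if (is.null(centre)) centre <- maskCentroid(meanFrames)
    if (is.null(config))
        config <- ReconConfig(spacing = spacing, nPhases = 1L, nSR = 3L,
                              lambda = 0.01)
    grid <- framesBoundingGrid(meanFrames, spacing, marginMm = 8)
    nvox <- prod(grid@shape)
    stackOf <- vapply(meanFrames, function(f) f@stack, 0L)
    multiStack <- length(unique(stackOf)) > 1L
    transforms <- lapply(initTransforms, function(t)
        transformFromMatrix(transformMatrix(t), centre))
    regFrames <- lapply(seq_len(nl), function(l) {
        f <- meanFrames[[l]]
        if (!is.null(chestMasks)) f@mask <- chestMasks[[l]]
        f
    })
    samples <- lapply(regFrames, frameSamplePoints, nZ = 5L)
    for (it in seq_len(nIter)) {
        num <- matrix(0, nvox, nl)
        den <- matrix(0, nvox, nl)
        for (l in seq_len(nl)) {
            sp <- spatialPsfWeights(meanFrames[[l]], grid, transforms[[l]],
                                    config@truncation)
            y <- as.numeric(abs(meanFrames[[l]]@pixels))
            num[, l] <- as.numeric(Matrix::crossprod(sp, y))
            den[, l] <- as.numeric(Matrix::crossprod(sp, rep(1, length(y))))
        }
        for (l in seq_len(nl)) {
            if (sum(regFrames[[l]]@mask) < 10) next
            # leave out the slice's own stack: the other stacks carry the
            # independent information, while same-stack neighbours share the
            # slice's pose error and would anchor it in place
            drop <- if (multiStack) stackOf == stackOf[l] else
                seq_len(nl) == l
            d <- rowSums(den[, !drop, drop = FALSE])
            v <- rowSums(num[, !drop, drop = FALSE]) / pmax(d, 1e-9)
            v[d < 1e-6] <- NA_real_
            vol <- array(v, grid@shape)
            res <- registerSampleToVolume(samples[[l]], vol, grid,
                                          transforms[[l]], centre)
            # damped geodesic update: averages registration noise against
            # the fuzzy consensus target over the sweeps
            if (res$metricFinal >= res$metricInit - 1e-9)
                transforms[[l]] <- meanSliceTransform(
                    list(transforms[[l]], res$transform), c(0.4, 0.6),
                    centre = centre)
        }
        transforms <- reanchorTransforms(transforms, centre)
    }
    rec <- reconstruct(meanFrames, transforms, volGrid = grid,
                       config = config, mode = "static", robust = FALSE,
                       bias = FALSE)
    list(transforms = transforms, volume = rec$cine, grid = grid)
}

#' Interleaved frame-volume registration and 4D reconstruction
#'
#' Registers every real-time frame to the cine phase-volume nearest its
#' cardiac phase, interpolated from all *other* frames at their current
#' transforms (leave-one-out target), then repeats for `nIter` iterations
#' (default 3) before a final full 4D reconstruction with outlier rejection.
#' Frame transforms are initialised from their slice transform, and any
#' per-frame registration that lowers the metric falls back to its initial
#' transform.
#'
#' @param frames list of [FrameImage-class].
#' @param initTransforms per-frame initial transforms.
#' @param theta per-frame cardiac phases (after synchronization).
#' @param volGrid reconstruction grid for the cine.
#' @param config a [ReconConfig-class].
#' @param tRR R-R interval, seconds.
#' @param nIter interleave iterations (default 3).
#' @param centre rotation centre (default heart-mask centroid).
#' @param temporalResolution acquisition temporal resolution, seconds.
#' @return list with `transforms`, `recon` (final [reconstruct()] output).
#' @export
registerFramesToCine <- function(frames, initTransforms, theta, volGrid,
                                 config, tRR, nIter = 3L, centre = NULL,
                                 temporalResolution = 0.072) {
    if (is.null(centre)) centre <- maskCentroid(frames)
    transforms <- lapply(initTransforms, function(t)
        transformFromMatrix(transformMatrix(t), centre))
    samples <- lapply(frames, frameSamplePoints, nZ = 5L)
    nh <- config@nPhases
    nvox <- prod(volGrid@shape)
    ph <- 2 * pi * (seq_len(nh) - 1) / nh
    hOf <- vapply(theta, function(t) which.min(abs(circDist(ph, t))), 0L)
    sliceOf <- vapply(frames, function(f) f@slice, 0L)
    sliceIds <- sort(unique(sliceOf))
    si <- match(sliceOf, sliceIds)
    pixs <- lapply(frames, function(f) as.numeric(abs(f@pixels)))
    dPos <- vapply(theta, function(t) {
        tw <- pmax(temporalPsfWeight(t, ph, temporalResolution, tRR), 0)
        tw / sum(tw)
    }, numeric(nh))
    for (it in seq_len(nIter)) {
        # per-slice accumulators: a frame's target leaves out its own
        # slice, whose frames share its (temporally correlated) pose error
        numS <- lapply(seq_along(sliceIds), function(i) matrix(0, nvox, nh))
        denS <- lapply(seq_along(sliceIds), function(i) matrix(0, nvox, nh))
        for (k in seq_along(frames)) {
            sp <- spatialPsfWeights(frames[[k]], volGrid, transforms[[k]],
                                    config@truncation)
            gy <- as.numeric(Matrix::crossprod(sp, pixs[[k]]))
            g1 <- as.numeric(Matrix::crossprod(sp,
                                               rep(1, length(pixs[[k]]))))
            numS[[si[k]]] <- numS[[si[k]]] + outer(gy, dPos[, k])
            denS[[si[k]]] <- denS[[si[k]]] + outer(g1, dPos[, k])
        }
        numAll <- Reduce(`+`, numS)
        denAll <- Reduce(`+`, denS)
        for (k in seq_along(frames)) {
            h <- hOf[k]
            d <- denAll[, h] - denS[[si[k]]][, h]
            v <- (numAll[, h] - numS[[si[k]]][, h]) / pmax(d, 1e-9)
            v[d < 1e-6] <- NA_real_
            vol <- array(v, volGrid@shape)
            res <- registerSampleToVolume(samples[[k]], vol, volGrid,
                                          transforms[[k]], centre,
                                          maxit = 90L, reltol = 1e-6,
                                          restarts = 0L)
            if (res$metricFinal >= res$metricInit - 1e-9)
                transforms[[k]] <- meanSliceTransform(
                    list(transforms[[k]], res$transform), c(0.3, 0.7),
                    centre = centre)
        }
        transforms <- reanchorTransforms(transforms, centre)
    }
    rec <- reconstruct(frames, transforms, theta, volGrid, config,
                       tRR = tRR, mode = "cine",
                       temporalResolution = temporalResolution)
    list(transforms = transforms, recon = rec)
}

#' Screen motion-corrupted slices
#'
#' Optional automatic counterpart of the manual exclusion of slices with
#' gross movement: flags slices whose deviation from the slice-mean
#' transform, dev(A_l), exceeds a threshold.
#'
#' @param summary a [MotionSummary-class] (see [deviationFromSliceMean()]).
#' @param thresholdMm dev(A_l) threshold in mm (default 3).
#' @return integer vector of flagged slice identifiers.
#' @export
flagMotionCorruptedSlices <- function(summary, thresholdMm = 3) {
    dev <- summary@perSliceDev
    as.integer(names(dev)[!is.na(dev) & dev > thresholdMm])
}
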