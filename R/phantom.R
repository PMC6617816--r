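# Numerical beating-heart phantom and real-time acquisition simulator.

#' Construct a beating-heart phantom specification
#'
#' The default phantom is an analytic stand-in for a fetal chest at about 30
#' weeks gestation: four ellipsoidal cardiac chambers (blood pool plus
#' myocardial shell) with a great-vessel analogue, fluid-filled lungs, a
#' low-signal spine analogue and surrounding fetal body tissue, all immersed
#' in amniotic fluid. Ventricular blood pools contract in systole while the
#' atria dilate, with smooth cyclic radius modulation. Defaults follow the
#' simulated study conditions: 0.44 mm isotropic grid, 25 cardiac phases,
#' heart rate 150 bpm; signal levels are bSSFP-like (bright blood and
#' amniotic fluid, mid-grey tissue, dark myocardium).
#'
#' @param fovMm field of view of the phantom grid, mm (cube).
#' @param spacing phantom grid spacing, mm (default 0.44, isotropic).
#' @param nPhases number of cardiac phases (default 25).
#' @param heartRateBpm heart rate, beats per minute (default 150).
#' @param contractionFrac peak fractional shortening of ventricular inner
#'   radii (default 0.25; 0 gives a static heart).
#' @param wallThickness ventricular wall thickness, mm (atrial walls are
#'   55 percent of this).
#' @param signal named numeric signal levels; must contain `blood`,
#'   `myocardium`, `fluid`, `tissue` (optional `lung`, `spine`).
#' @param chambers optional chamber list overriding the default anatomy.
#' @return A [PhantomSpec-class].
#' @examples
#' spec <- PhantomSpec(spacing = 2, nPhases = 5)  # coarse, for quick tests
#' @export
PhantomSpec <- function(fovMm = 64, spacing = 0.44, nPhases = 25L,
                        heartRateBpm = 150, contractionFrac = 0.25,
                        wallThickness = 2.8,
                        signal = c(blood = 1, myocardium = 0.35,
                                   fluid = 0.9, tissue = 0.5,
                                   lung = 0.7, spine = 0.15),
                        chambers = NULL) {
    n <- as.integer(round(fovMm / spacing))
    grid <- VoxelGrid(c(n, n, n), spacing)
    if (is.null(chambers))
        chambers <- list(
            LV = list(centre = c(-6.5, 0, -5),  radii = c(7.5, 7, 10),
                      role = "ventricle"),
            RV = list(centre = c(7, 0, -4.5),   radii = c(8, 7.5, 9),
                      role = "ventricle"),
            LA = list(centre = c(-6, 1, 8),     radii = c(5.5, 6, 5.5),
                      role = "atrium"),
            RA = list(centre = c(6.5, 1, 8),    radii = c(6, 6.5, 6),
                      role = "atrium"))
    methods::new("PhantomSpec", grid = grid, nPhases = as.integer(nPhases),
                 heartRateBpm = as.numeric(heartRateBpm), chambers = chambers,
                 wallThickness = as.numeric(wallThickness),
                 contractionFrac = as.numeric(contractionFrac),
                 signal = signal, bodyRadii = c(30, 30, 40))
}

# smooth cyclic systolic fraction: 0 at end-diastole (theta = 0),
# 1 at end-systole (theta = pi)
systolicFraction <- function(theta) (1 - cos(theta)) / 2

# radius scale factors for one phase
chamberScales <- function(spec, theta) {
    s <- systolicFraction(theta)
    list(ventricle = 1 - spec@contractionFrac * s,
         atrium = 1 - 0.6 * spec@contractionFrac * (1 - s))
}

#' Generate the 4D phantom cine
#'
#' Evaluates the analytic phantom on its grid for each cardiac phase. The
#' result is deterministic given the specification.
#'
#' @param spec a [PhantomSpec-class].
#' @return A [CineVolume-class] with `nPhases` phases and the phantom heart
#'   rate recorded in its `tRR` slot.
#' @export
makePhantomCine <- function(spec) {
    g <- spec@grid
    half <- g@spacing * (g@shape - 1) / 2
    for (ch in spec@chambers) {
        ext <- abs(ch$centre) + ch$radii + spec@wallThickness
        if (any(ext > half + g@spacing))
            stop("chamber '", paste(round(ch$centre), collapse = ","),
                 "' exceeds the phantom grid")
    }
    sig <- spec@signal
    lungSig <- if ("lung" %in% names(sig)) sig[["lung"]] else sig[["fluid"]]
    spineSig <- if ("spine" %in% names(sig)) sig[["spine"]] else
        0.3 * sig[["tissue"]]
    co <- gridWorldCoords(g)
    X <- co[, 1]; Y <- co[, 2]; Z <- co[, 3]
    inEll <- function(c0, r) ((X - c0[1]) / r[1])^2 +
        ((Y - c0[2]) / r[2])^2 + ((Z - c0[3]) / r[3])^2 <= 1
    body <- inEll(c(0, 2, 0), spec@bodyRadii)
    lungL <- inEll(c(-16, 2, 6), c(9, 11, 14)) & body
    lungR <- inEll(c(16, 2, 6), c(9, 11, 14)) & body
    spine <- ((X / 5)^2 + ((Y - 22) / 5)^2 <= 1) & body
    vessel <- (((X + 2) / 3)^2 + ((Y + 6) / 3)^2 <= 1) & Z > 6 & Z < 32
    base <- rep(sig[["fluid"]], length(X))
    base[body] <- sig[["tissue"]]
    base[lungL | lungR] <- lungSig
    base[spine] <- spineSig
    nh <- spec@nPhases
    vox <- array(0, c(g@shape, nh))
    for (h in seq_len(nh)) {
        theta <- 2 * pi * (h - 1) / nh
        sc <- chamberScales(spec, theta)
        vol <- base
        # myocardial shells first, then blood pools (septum stays wall)
        for (ch in spec@chambers) {
            k <- sc[[ch$role]]
            wall <- spec@wallThickness * if (ch$role == "atrium") 0.55 else 1
            vol[inEll(ch$centre, ch$radii * k + wall)] <- sig[["myocardium"]]
        }
        for (ch in spec@chambers)
            vol[inEll(ch$centre, ch$radii * sc[[ch$role]])] <- sig[["blood"]]
        vol[vessel] <- sig[["blood"]]
        vox[, , , h] <- vol
    }
    CineVolume(vox, g, tRR = 60 / spec@heartRateBpm)
}

#' Heart and chest region masks in volume space
#'
#' `heartMaskVolume` marks a sphere covering the heart chambers plus margin;
#' `chestMaskVolume` marks the fetal body cross-section used as the
#' volume-of-interest for slice-volume registration.
#'
#' @param grid target [VoxelGrid-class].
#' @param spec the [PhantomSpec-class] (for chamber extents).
#' @param marginMm extra margin around the chambers, mm.
#' @return logical 3D array.
#' @export
heartMaskVolume <- function(grid, spec, marginMm = 6) {
    co <- gridWorldCoords(grid)
    r <- heartRadius(spec) + marginMm
    m <- rowSums(co^2) <= r^2
    array(m, grid@shape)
}

#' @rdname heartMaskVolume
#' @export
chestMaskVolume <- function(grid, spec) {
    co <- gridWorldCoords(grid)
    r <- spec@bodyRadii * 0.95
    m <- (co[, 1] / r[1])^2 + ((co[, 2] - 2) / r[2])^2 +
        (co[, 3] / r[3])^2 <= 1
    array(m, grid@shape)
}

heartRadius <- function(spec) {
    max(vapply(spec@chambers, function(ch)
        max(abs(ch$centre) + ch$radii + spec@wallThickness), 0))
}

#' Simulated fetal motion trajectory
#'
#' A piecewise-smooth random trajectory in the rigid-motion Lie algebra
#' mimicking fetal behaviour during acquisition: a slowly varying
#' mean-reverting (Ornstein-Uhlenbeck) component models drift of the fetal
#' trunk between quiescent periods, and sparse jump events model episodic
#' gross fetal movements that persist and then decay back towards the
#' resting pose. The 6-vector state is scaled by `scale` and exponentiated,
#' so `scale = 0` yields identity transforms and expected displacement grows
#' monotonically with `scale`.
#'
#' @param nFrames number of frames.
#' @param frameInterval frame spacing, seconds (default 0.072).
#' @param scale dimensionless displacement scale (default 1).
#' @param seed RNG seed.
#' @param centre rotation centre (mm), default the heart centre.
#' @param tauS correlation time of the smooth component, seconds.
#' @param sdTransMm,sdRotDeg stationary standard deviation of the smooth
#'   component per axis.
#' @param jumpRateHz rate of episodic movement events, per second.
#' @param jumpTransMm,jumpRotDeg standard deviation of jump amplitudes.
#' @return A [MotionTrajectory-class].
#' @export
makeMotionTrajectory <- function(nFrames, frameInterval = 0.072, scale = 1,
                                 seed = 1L, centre = c(0, 0, 0),
                                 tauS = 6, sdTransMm = 1.5, sdRotDeg = 1.5,
                                 jumpRateHz = 0.05, jumpTransMm = 5,
                                 jumpRotDeg = 5) {
    if (scale < 0) stop("scale must be >= 0")
    set.seed(seed)
    rho <- exp(-frameInterval / tauS)
    sdv <- c(rep(deg2rad(sdRotDeg), 3), rep(sdTransMm, 3))
    jsd <- c(rep(deg2rad(jumpRotDeg), 3), rep(jumpTransMm, 3))
    states <- matrix(0, nFrames, 6)
    x <- rnorm(6, 0, sdv)      # start in the stationary distribution
    for (k in seq_len(nFrames)) {
        x <- rho * x + sqrt(1 - rho^2) * rnorm(6, 0, sdv)
        if (runif(1) < jumpRateHz * frameInterval)
            x <- x + rnorm(6, 0, jsd)
        states[k, ] <- x
    }
    # centre the trajectory: the phantom reference pose is defined as the
    # mean pose over the acquisition, so displacement measures excursions
    # about the anatomy actually sampled
    states <- sweep(states, 2, colMeans(states))
    transforms <- lapply(seq_len(nFrames), function(k)
        transformFromMatrix(expSE3(scale * states[k, ]), centre))
    methods::new("MotionTrajectory", transforms = transforms,
                 scale = scale,
                 times = frameInterval * (seq_len(nFrames) - 1))
}

#' Rescale a motion trajectory
#'
#' Applies a new displacement scale to the trajectory's Lie-algebra states.
#'
#' @param traj a [MotionTrajectory-class] with positive scale.
#' @param newScale new non-negative scale.
#' @return A [MotionTrajectory-class].
#' @export
rescaleTrajectory <- function(traj, newScale) {
    if (newScale < 0) stop("scale must be >= 0")
    if (traj@scale == 0) stop("cannot rescale a zero-scale trajectory")
    f <- newScale / traj@scale
    transforms <- lapply(traj@transforms, scaleTransform, s = f)
    methods::new("MotionTrajectory", transforms = transforms,
                 scale = newScale, times = traj@times)
}

#' Scale a trajectory to a target global displacement
#'
#' Iteratively rescales the trajectory until `disp(A*)` over the given
#' frames matches `targetDispMm`.
#'
#' @param traj a [MotionTrajectory-class].
#' @param frames frames whose heart masks define the displacement metric.
#' @param targetDispMm desired disp(A*), mm.
#' @param iters fixed-point iterations (default 3).
#' @return A rescaled [MotionTrajectory-class].
#' @export
calibrateMotionScale <- function(traj, frames, targetDispMm, iters = 3L) {
    for (i in seq_len(iters)) {
        d <- globalDisplacement(traj@transforms, frames)
        if (d <= 0) stop("trajectory has zero displacement; cannot calibrate")
        traj <- rescaleTrajectory(traj, traj@scale * targetDispMm / d)
    }
    traj
}

#' Multi-planar stack geometries around the phantom heart
#'
#' Builds the slice geometries for `nStacks` stacks in roughly orthogonal
#' orientations (transverse, sagittal, coronal), with 2D frames of
#' `fovMm` x `fovMm` at `inPlaneMm` resolution, `thicknessMm` slices and
#' adjacent-slice overlap `overlapMm` (slice centre spacing
#' `thicknessMm - overlapMm`), centred on the heart.
#'
#' @param nStacks number of stacks (default 3).
#' @param nSlices slices per stack (default 8).
#' @param fovMm in-plane field of view, mm (default 64).
#' @param inPlaneMm acquired in-plane resolution, mm (default 2).
#' @param thicknessMm slice thickness, mm (default 6).
#' @param overlapMm overlap of adjacent slices, mm (default 2.5).
#' @return list of stacks, each a list of slice [VoxelGrid-class] objects.
#' @export
makeStackGeometries <- function(nStacks = 3L, nSlices = 8L, fovMm = 64,
                                inPlaneMm = 2, thicknessMm = 6,
                                overlapMm = 2.5) {
    dirs <- list(diag(3),                                  # transverse (z)
                 cbind(c(0, 1, 0), c(0, 0, 1), c(1, 0, 0)), # sagittal (x)
                 cbind(c(1, 0, 0), c(0, 0, 1), c(0, 1, 0))) # coronal (y)
    npx <- as.integer(round(fovMm / inPlaneMm))
    gap <- thicknessMm - overlapMm
    offs <- gap * (seq_len(nSlices) - (nSlices + 1) / 2)
    out <- list()
    for (s in seq_len(nStacks)) {
        D <- dirs[[(s - 1L) %% 3L + 1L]]
        stack <- lapply(offs, function(o) {
            centreOff <- D[, 3] * o
            og <- centreOff - D[, 1] * inPlaneMm * (npx - 1) / 2 -
                D[, 2] * inPlaneMm * (npx - 1) / 2
            VoxelGrid(c(npx, npx, 1L),
                      c(inPlaneMm, inPlaneMm, thicknessMm),
                      origin = og, directions = D)
        })
        out[[s]] <- stack
    }
    out
}

#' Simulate multi-planar real-time frames from the phantom
#'
#' Each frame is the acquisition-model forward projection of the phantom
#' cine at its ground-truth rigid transform and cardiac phase: the phantom
#' is sampled on a 0.5 mm in-plane grid with a Gaussian through-plane
#' profile (FWHM = slice thickness), then down-sampled to the acquired
#' in-plane resolution by central k-space truncation with additive complex
#' Gaussian noise before taking the magnitude. Slices are acquired
#' sequentially within a stack with contiguous frames per slice, and the
#' true cardiac phase of frame `k` is \eqn{2\pi\,\mathrm{frac}(t_k/t_{RR})}.
#'
#' @param chi phantom [CineVolume-class] (from [makePhantomCine()]).
#' @param stackGeoms stack geometries from [makeStackGeometries()].
#' @param traj a [MotionTrajectory-class] with at least as many transforms
#'   as frames, or `NULL` for no motion.
#' @param framesPerSlice real-time frames per slice (default 96).
#' @param frameInterval temporal resolution, seconds (default 0.072).
#' @param noiseSd complex Gaussian noise standard deviation relative to the
#'   blood signal level (default 0.05).
#' @param seed RNG seed for the noise.
#' @param spec the [PhantomSpec-class] (for heart ROI definition).
#' @param hiResMm simulation in-plane resolution before k-space truncation,
#'   mm (default 0.5).
#' @return list with `frames` (list of [FrameImage-class]), `transforms`
#'   (ground-truth A*, one per frame), `theta` (ground-truth phases),
#'   `tRR`, and `sliceOfFrame`/`stackOfFrame` index vectors.
#' @export
simulateFrames <- function(chi, stackGeoms, traj = NULL, framesPerSlice = 96L,
                           frameInterval = 0.072, noiseSd = 0.05, seed = 1L,
                           spec = NULL, hiResMm = 0.5) {
    if (length(stackGeoms) == 0L) stop("empty stack list")
    set.seed(seed + 1L)
    tRR <- chi@tRR
    nh <- nPhases(chi)
    phaseVols <- lapply(seq_len(nh), function(h) chi@voxels[, , , h])
    bloodSig <- max(chi@voxels[, , , 1])
    rHeart <- if (is.null(spec)) 25 else heartRadius(spec) + 6
    frames <- list(); transforms <- list()
    theta <- numeric(); sliceOf <- integer(); stackOf <- integer()
    k <- 0L; sliceId <- 0L; t <- 0
    for (s in seq_along(stackGeoms)) {
        for (g in stackGeoms[[s]]) {
            sliceId <- sliceId + 1L
            factor <- as.integer(round(g@spacing[1] / hiResMm))
            nhi <- g@shape[1] * factor
            # hi-res grid sharing the acquisition grid origin, so that the
            # k-space-truncated samples land exactly on the acquired pixel
            # centres (DFT subsampling keeps the first sample position)
            ghi <- VoxelGrid(c(nhi, nhi, 1L),
                             c(g@spacing[1:2] / factor, g@spacing[3]),
                             origin = g@origin,
                             directions = g@directions)
            Phi <- framePixelWorld(ghi)
            # Gaussian through-plane profile, 7-point quadrature over +-2 SD
            sz <- g@spacing[3] * FWHM2SD
            zoff <- seq(-2 * sz, 2 * sz, length.out = 7)
            zw <- dnorm(zoff, 0, sz); zw <- zw / sum(zw)
            # heart ROI: fixed per slice, disc around the heart centre
            Pacq <- framePixelWorld(g)
            inplane <- Pacq - tcrossprod(Pacq %*% g@directions[, 3],
                                         g@directions[, 3])
            mask <- matrix(rowSums(inplane^2) <= rHeart^2,
                           g@shape[1], g@shape[2])
            for (f in seq_len(framesPerSlice)) {
                k <- k + 1L
                A <- if (is.null(traj)) RigidTransform() else
                    traj@transforms[[k]]
                th <- (2 * pi * (t / tRR)) %% (2 * pi)
                # temporal interpolation between neighbouring phantom phases
                hf <- th / (2 * pi) * nh
                h0 <- floor(hf); fr <- hf - h0
                h1 <- (h0 + 1L) %% nh
                v0 <- phaseVols[[h0 %% nh + 1L]]
                v1 <- phaseVols[[h1 + 1L]]
                R <- rotationMatrix(A@rotation)
                nrm <- as.numeric(R %*% g@directions[, 3])
                Q <- transformPoints(A, Phi)
                acc <- numeric(nhi * nhi)
                for (zi in seq_along(zoff)) {
                    pts <- Q
                    pts[, 1] <- pts[, 1] + zoff[zi] * nrm[1]
                    pts[, 2] <- pts[, 2] + zoff[zi] * nrm[2]
                    pts[, 3] <- pts[, 3] + zoff[zi] * nrm[3]
                    samp0 <- sampleVolume(v0, chi@grid, pts)
                    samp1 <- sampleVolume(v1, chi@grid, pts)
                    acc <- acc + zw[zi] * ((1 - fr) * samp0 + fr * samp1)
                }
                hi <- matrix(acc, nhi, nhi)
                lo <- kspaceTruncate(hi, factor)
                if (noiseSd > 0)
                    lo <- lo + complex(real = rnorm(length(lo), 0,
                                                    noiseSd * bloodSig),
                                       imaginary = rnorm(length(lo), 0,
                                                         noiseSd * bloodSig))
                px <- matrix(Mod(lo), g@shape[1], g@shape[2])
                frames[[k]] <- FrameImage(px, g, time = t, slice = sliceId,
                                          stack = s, mask = mask)
                transforms[[k]] <- A
                theta[k] <- th
                sliceOf[k] <- sliceId; stackOf[k] <- s
                t <- t + frameInterval
            }
        }
    }
    list(frames = frames, transforms = transforms, theta = theta, tRR = tRR,
         sliceOfFrame = sliceOf, stackOfFrame = stackOf)
}

#' Down-sample a 2D image by central k-space truncation
#'
#' Keeps the central `1/factor` of k-space in each dimension. The DC term is
#' preserved, so the image mean is unchanged; the result is complex.
#'
#' @param img real or complex matrix with dimensions divisible by `factor`.
#' @param factor integer down-sampling factor.
#' @return complex matrix of size `dim(img)/factor`.
#' @export
kspaceTruncate <- function(img, factor) {
    if (factor == 1L) return(img * (1 + 0i))
    d <- dim(img)
    if (any(d %% factor != 0)) stop("dimensions must be divisible by factor")
    K <- stats::fft(img)
    nd <- d %/% factor
    keep1 <- c(seq_len(ceiling(nd[1] / 2)),
               seq.int(d[1] - floor(nd[1] / 2) + 1L, d[1]))
    keep2 <- c(seq_len(ceiling(nd[2] / 2)),
               seq.int(d[2] - floor(nd[2] / 2) + 1L, d[2]))
    Kc <- K[keep1, keep2]
    stats::fft(Kc, inverse = TRUE) / length(K)
}
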