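# Cardiac synchronization: per-slice heart-rate estimation from temporal
# frequency spectra, reliability screening, phase assignment and slice-slice
# cyclic alignment by overlap-weighted correlation.

#' Estimate the heart rate of one slice from its temporal frequency spectrum
#'
#' Computes the temporal discrete Fourier transform of every in-ROI pixel
#' series, averages the magnitude spectra spatially, and locates the largest
#' local maximum inside the physiological search band. The peak position is
#' refined by quadratic sub-bin interpolation and (optionally) by maximising
#' the continuous band-limited spectrum around it; peak height and full
#' width at half maximum are recorded for reliability screening.
#'
#' @param sliceFrames list of [FrameImage-class] from one slice, uniformly
#'   spaced in time (at least 16 frames).
#' @param roi logical matrix overriding the frames' heart mask.
#' @param band search band in beats per minute (default `c(115, 180)`).
#' @param refine refine the peak by continuous spectral maximisation
#'   (default `TRUE`).
#' @return one-row `data.frame` with columns `slice`, `stack`, `time`,
#'   `rate` (bpm, `NA` when no in-band local maximum exists), `height`,
#'   `width` (bpm), `reliable`, `source`.
#' @export
estimateHeartRate <- function(sliceFrames, roi = NULL, band = c(115, 180),
                              refine = TRUE) {
    n <- length(sliceFrames)
    if (n < 16L) stop("at least 16 frames required")
    times <- vapply(sliceFrames, frameTime, 0)
    dts <- diff(times)
    if (max(abs(dts - mean(dts))) > 1e-6)
        stop("frames must be uniformly spaced in time")
    dt <- mean(dts)
    if (is.null(roi)) roi <- sliceFrames[[1]]@mask
    series <- vapply(sliceFrames, function(f) abs(f@pixels[roi]),
                     numeric(sum(roi)))           # npix x n
    meanInt <- mean(series)
    series <- series - rowMeans(series)
    spec <- Mod(stats::mvfft(t(series)))          # n x npix
    spectrum <- rowMeans(spec) / (n * max(meanInt, 1e-12))
    bpm <- (seq_len(n) - 1) / (n * dt) * 60
    out <- data.frame(slice = sliceFrames[[1]]@slice,
                      stack = sliceFrames[[1]]@stack,
                      time = times[1], rate = NA_real_, height = NA_real_,
                      width = NA_real_, reliable = FALSE, source = "measured",
                      stringsAsFactors = FALSE)
    binBpm0 <- 60 / (n * dt)
    # pad the discrete search by one bin so peaks at the band edge whose
    # discrete maximum falls just outside are still found
    inBand <- which(bpm >= band[1] - binBpm0 & bpm <= band[2] + binBpm0 &
                    seq_len(n) > 1 & bpm <= 60 / (2 * dt))
    if (length(inBand) == 0L) return(out)
    pk <- inBand[which.max(spectrum[inBand])]
    if (pk <= 1L || pk >= n || spectrum[pk] <= 0 ||
        spectrum[pk] <= spectrum[pk - 1] || spectrum[pk] <= spectrum[pk + 1])
        return(out)                               # not a strict local maximum
    # quadratic sub-bin interpolation on the magnitude spectrum
    y0 <- spectrum[pk - 1]; y1 <- spectrum[pk]; y2 <- spectrum[pk + 1]
    denom <- y0 - 2 * y1 + y2
    delta <- if (abs(denom) > 1e-15) 0.5 * (y0 - y2) / denom else 0
    delta <- max(-0.5, min(0.5, delta))
    binBpm <- 60 / (n * dt)
    rate <- bpm[pk] + delta * binBpm
    height <- y1 - 0.25 * (y0 - y2) * delta
    if (refine) {
        trel <- times - times[1]
        contSpec <- function(fBpm) {
            w <- exp(-2i * pi * (fBpm / 60) * trel)
            mean(Mod(series %*% w)) / (n * max(meanInt, 1e-12))
        }
        op <- optimize(contSpec, lower = rate - binBpm, upper = rate + binBpm,
                       maximum = TRUE, tol = 1e-4)
        rate <- op$maximum
        height <- op$objective
    }
    # FWHM by linear interpolation on the discrete spectrum, walked within
    # the band plus a margin; a genuine cardiac peak falls to half height
    # within a few bins -- if it never does, the in-band maximum is just the
    # top of broadband (motion) power and the estimate is unreliable
    half <- height / 2
    wLo <- max(1L, pk - as.integer(ceiling((band[2] - band[1]) / binBpm)))
    wHi <- min(n, pk + as.integer(ceiling((band[2] - band[1]) / binBpm)))
    lo <- pk
    while (lo > wLo && spectrum[lo] > half) lo <- lo - 1
    hi <- pk
    while (hi < wHi && spectrum[hi] > half) hi <- hi + 1
    loCross <- spectrum[lo] <= half && lo < pk
    hiCross <- spectrum[hi] <= half && hi > pk
    fLo <- if (loCross)
        bpm[lo] + (half - spectrum[lo]) / (spectrum[lo + 1] - spectrum[lo]) *
            binBpm else bpm[wLo]
    fHi <- if (hiCross)
        bpm[hi] - (half - spectrum[hi]) / (spectrum[hi - 1] - spectrum[hi]) *
            binBpm else bpm[wHi]
    if (rate < band[1] - binBpm / 2 || rate > band[2] + binBpm / 2)
        return(out)                               # refined peak out of band
    out$rate <- rate
    out$height <- height
    out$width <- max(fHi - fLo, 1e-6)
    # peak prominence requires enough spectral resolution to be meaningful:
    # with a handful of in-band bins the FWHM cannot be assessed
    out$reliable <- if (wHi - wLo >= 6L) loCross && hiCross else TRUE
    out
}

#' Screen heart-rate estimates and fill unreliable slices
#'
#' Flags estimates whose spectral peak height falls more than three scaled
#' median absolute deviations (3 x 1.4826 MAD, a robust estimate of three
#' normal standard deviations) below the median height, or whose peak width
#' exceeds the median width by the same margin. Flagged or missing rates are
#' replaced by linear interpolation in acquisition time between the nearest
#' reliable slices of the same stack; end slices take the nearest reliable
#' value.
#'
#' @param estimates `data.frame` of per-slice estimates as returned by
#'   [estimateHeartRate()] (rows in acquisition order).
#' @param crossStackFallback when a stack retains no reliable estimate,
#'   interpolate from reliable slices of the other stacks (with a warning)
#'   instead of raising an error (default `FALSE`).
#' @return the `data.frame` with updated `rate`, `reliable` and `source`
#'   columns.
#' @export
screenAndFillRates <- function(estimates, crossStackFallback = FALSE) {
    if (nrow(estimates) < 3L) stop("at least 3 slices required")
    h <- estimates$height; w <- estimates$width
    hThr <- median(h, na.rm = TRUE) - 3 * mad(h, na.rm = TRUE)
    wThr <- median(w, na.rm = TRUE) + 3 * mad(w, na.rm = TRUE)
    bad <- !estimates$reliable | is.na(estimates$rate) |
        (!is.na(h) & h < hThr) | (!is.na(w) & w > wThr)
    estimates$reliable <- !bad
    for (s in unique(estimates$stack)) {
        rows <- which(estimates$stack == s)
        ok <- rows[estimates$reliable[rows]]
        if (length(ok) == 0L) {
            if (!crossStackFallback || !any(estimates$reliable))
                stop("no reliable heart-rate estimate in stack ", s)
            warning("no reliable heart-rate estimate in stack ", s,
                    "; interpolating from the other stacks")
            ok <- which(estimates$reliable)
        }
        for (r in rows[!estimates$reliable[rows]]) {
            tt <- estimates$time[r]
            if (length(ok) == 1L) {
                estimates$rate[r] <- estimates$rate[ok]
            } else {
                estimates$rate[r] <- approx(estimates$time[ok],
                                            estimates$rate[ok], xout = tt,
                                            rule = 2)$y
            }
            estimates$source[r] <- "interpolated"
        }
    }
    estimates
}

#' Assign cardiac phases to frames of a slice
#'
#' \eqn{\theta_k = 2\pi ((t_k - t_{first}) / t_{RR} \bmod 1)} with
#' \eqn{t_{RR} = 60 / rate}; the phase origin of each slice is its first
#' frame, any absolute offset being absorbed later by slice-slice
#' synchronization.
#'
#' @param times frame acquisition times, seconds.
#' @param rateBpm slice heart rate, beats per minute (> 0).
#' @param tFirst phase origin (default `times[1]`).
#' @return numeric vector of phases on \eqn{[0, 2\pi)}.
#' @export
assignPhases <- function(times, rateBpm, tFirst = times[1]) {
    stopifnot(rateBpm > 0)
    tRR <- 60 / rateBpm
    (2 * pi * ((times - tFirst) / tRR)) %% (2 * pi)
}

#' Reconstruct a single-slice cine and its volume weights
#'
#' PSF-weighted interpolation of the frames of one slice into volume space
#' (a per-slice 4D cine `X_l`) together with the accumulated volume weights
#' `V_l` used to measure spatial overlap between slices. Interpolation uses
#' the non-negative part of the temporal sinc kernel so the weights form a
#' positive partition.
#'
#' @param sliceFrames frames of one slice.
#' @param transforms per-frame [RigidTransform-class].
#' @param theta per-frame cardiac phases, radians.
#' @param volGrid reconstruction [VoxelGrid-class].
#' @param nPhases number of cine phases.
#' @param tRR slice R-R interval, seconds.
#' @param temporalResolution acquisition temporal resolution, seconds.
#' @param truncation PSF truncation (default 0.01).
#' @return list with `cine` (a [CineVolume-class]) and `weights`
#'   (`n_voxels` x `nPhases` matrix `V_l`, non-negative).
#' @export
sliceCineAndWeights <- function(sliceFrames, transforms, theta, volGrid,
                                nPhases = 25L, tRR, temporalResolution = 0.072,
                                truncation = 0.01) {
    if (length(sliceFrames) == 0L) stop("empty slice")
    nvox <- prod(volGrid@shape)
    num <- matrix(0, nvox, nPhases)
    den <- matrix(0, nvox, nPhases)
    for (k in seq_along(sliceFrames)) {
        w <- psfWeights(sliceFrames[[k]], volGrid, transforms[[k]], theta[k],
                        nPhases, temporalResolution, tRR, truncation,
                        temporalKernel = "sincPos")
        y <- as.numeric(abs(sliceFrames[[k]]@pixels))
        sp <- w@spatial
        gy <- as.numeric(Matrix::crossprod(sp, y))
        g1 <- as.numeric(Matrix::crossprod(sp, rep(1, length(y))))
        num <- num + outer(gy, w@temporal)
        den <- den + outer(g1, w@temporal)
    }
    x <- num / pmax(den, 1e-12)
    x[den <= 1e-12] <- 0
    list(cine = CineVolume(array(x, c(volGrid@shape, nPhases)), volGrid,
                           tRR = tRR),
         weights = pmax(den, 0))
}

#' Cyclic Fourier time shift of a cine
#'
#' Advances the cine by `thetaOffset`: per-voxel temporal Fourier transform
#' multiplied by a linear phase, with Hermitian symmetry enforced so a real
#' input yields a real output. A shift of \eqn{2\pi} is the identity.
#'
#' @param X a [CineVolume-class] with at least 2 phases, or a
#'   `voxels x phases` matrix.
#' @param thetaOffset shift in radians.
#' @return object of the same kind as `X`, shifted.
#' @export
cyclicTimeShift <- function(X, thetaOffset) {
    isCine <- methods::is(X, "CineVolume")
    m <- if (isCine) matrix(X@voxels, prod(X@grid@shape), nPhases(X)) else X
    nh <- ncol(m)
    if (nh < 2L) stop("at least 2 phases required")
    sh <- cyclicShiftMatrix(nh, thetaOffset)
    out <- m %*% sh
    if (isCine)
        CineVolume(array(out, dim(X@voxels)), X@grid, tRR = X@tRR)
    else out
}

# real nh x nh matrix implementing the cyclic Fourier shift X(theta) ->
# X(theta + delta) by right multiplication
cyclicShiftMatrix <- function(nh, delta) {
    m <- seq_len(nh) - 1
    freq <- ifelse(m > nh / 2, m - nh, m)         # signed frequencies
    fac <- exp(1i * freq * delta)
    if (nh %% 2 == 0)                             # Nyquist stays real
        fac[nh / 2 + 1] <- cos((nh / 2) * delta)
    W <- exp(-2i * pi * outer(m, m) / nh)         # analysis DFT
    Winv <- Conj(W) / nh                          # synthesis
    Re(W %*% (fac * Winv))
}

#' Slice-slice cardiac synchronization
#'
#' Greedy overlap-weighted alignment of the cardiac cycles of all slices.
#' The slice with the greatest total overlap with all others is fixed at
#' offset 0; remaining slices are added in descending order of overlap with
#' the fixed set, each offset found by bounded 1-D minimisation of the
#' negative overlap-weighted Pearson correlation against all fixed slices,
#' started from 16 points spread over \eqn{[0, 2\pi)}.
#'
#' @param sliceCines list of per-slice [CineVolume-class] (common grid and
#'   phase count).
#' @param sliceWeights list of matching `V_l` weight matrices
#'   (`n_voxels x n_phases`).
#' @param mask optional logical volume restricting the comparison (e.g.
#'   heart region).
#' @return named numeric vector of offsets \eqn{\theta_l^{offset}} on
#'   \eqn{[0, 2\pi)}, in the order of `sliceCines`.
#' @export
synchronizeSlices <- function(sliceCines, sliceWeights, mask = NULL) {
    nl <- length(sliceCines)
    if (nl < 2L) {
        off <- setNames(rep(0, nl), names(sliceCines))
        return(off)
    }
    nh <- nPhases(sliceCines[[1]])
    nvox <- prod(sliceCines[[1]]@grid@shape)
    keepVox <- if (is.null(mask)) rep(TRUE, nvox) else as.logical(mask)
    V <- lapply(sliceWeights, function(v) {
        v <- as.matrix(v)
        v[!keepVox, ] <- 0
        v
    })
    Xm <- lapply(sliceCines, function(x)
        matrix(x@voxels, nvox, nh))
    O <- matrix(0, nl, nl)
    for (a in seq_len(nl - 1)) for (b in seq.int(a + 1, nl)) {
        O[a, b] <- O[b, a] <- sum(V[[a]] * V[[b]])
    }
    offsets <- rep(NA_real_, nl)
    target <- which.max(rowSums(O))
    offsets[target] <- 0
    fixed <- target
    shifted <- Xm                       # slices already moved to common phase
    while (length(fixed) < nl) {
        rest <- setdiff(seq_len(nl), fixed)
        ov <- vapply(rest, function(l) sum(O[l, fixed]), 0)
        l <- rest[which.max(ov)]
        if (max(ov) <= 0) {
            warning("slice ", l, " has no overlap with the target set; ",
                    "offset left at 0")
            offsets[l] <- 0
            fixed <- c(fixed, l)
            next
        }
        pairs <- fixed[O[l, fixed] > 0]
        sup <- rowSums(V[[l]]) > 0
        F <- t(stats::mvfft(t(Xm[[l]][sup, , drop = FALSE])))  # nvox x nh coefs
        m <- seq_len(nh) - 1
        freq <- ifelse(m > nh / 2, m - nh, m)
        Winv <- Conj(exp(-2i * pi * outer(m, m) / nh)) / nh
        shiftEval <- function(delta) {
            fac <- exp(1i * freq * delta)
            if (nh %% 2 == 0) fac[nh / 2 + 1] <- cos((nh / 2) * delta)
            Re(F %*% (fac * Winv))
        }
        pairIdx <- lapply(pairs, function(p) {
            w <- (V[[l]] * V[[p]])[sup, , drop = FALSE]
            list(p = p, w = w, use = w > 0,
                 x = Xm[[p]][sup, , drop = FALSE], osum = sum(w))
        })
        objective <- function(delta) {
            Xs <- shiftEval(delta)
            num <- 0; den <- 0
            for (pi in pairIdx) {
                r <- weightedPearson(Xs[pi$use], pi$x[pi$use], pi$w[pi$use])
                num <- num + pi$osum * r
                den <- den + pi$osum
            }
            -num / den
        }
        starts <- 2 * pi * (0:15) / 16
        vals <- vapply(starts, objective, 0)
        best <- order(vals)[1:2]
        cand <- lapply(best, function(b) {
            optimize(objective, lower = starts[b] - 2 * pi / 16,
                     upper = starts[b] + 2 * pi / 16, tol = 1e-4)
        })
        ob <- vapply(cand, function(c) c$objective, 0)
        delta <- cand[[which.min(ob)]]$minimum %% (2 * pi)
        # delta advances the cine; the matching phase correction is -delta
        offsets[l] <- (-delta) %% (2 * pi)
        Xm[[l]] <- cyclicTimeShift(Xm[[l]], delta)
        fixed <- c(fixed, l)
    }
    setNames(offsets, names(sliceCines))
}

weightedPearson <- function(x, y, w) {
    sw <- sum(w)
    if (sw <= 0) return(0)
    mx <- sum(w * x) / sw; my <- sum(w * y) / sw
    cxy <- sum(w * (x - mx) * (y - my))
    cxx <- sum(w * (x - mx)^2); cyy <- sum(w * (y - my)^2)
    if (cxx <= 0 || cyy <= 0) return(0)
    cxy / sqrt(cxx * cyy)
}

#' Circular phase error metrics
#'
#' `phaseRmse` computes the root-mean-square cyclic difference between two
#' phase vectors after removing the global cyclic gauge offset (only
#' relative alignment is identifiable); `phaseRmseToMs` converts a phase
#' RMSE in radians to milliseconds at a given R-R interval, and
#' `phaseRmsePercent` to a percentage of the cardiac cycle.
#'
#' @param est,true phase vectors, radians.
#' @param rmseRad phase RMSE, radians.
#' @param tRR R-R interval, seconds.
#' @return numeric scalar.
#' @examples
#' phaseRmseToMs(pi / 20, 0.404)   # 10.1 ms
#' @export
phaseRmse <- function(est, true) {
    g <- Arg(mean(exp(1i * (true - est))))
    d <- circDist(est + g, true)
    sqrt(mean(d^2))
}

#' @rdname phaseRmse
#' @export
phaseRmseToMs <- function(rmseRad, tRR) rmseRad / (2 * pi) * tRR * 1000

#' @rdname phaseRmse
#' @export
phaseRmsePercent <- function(rmseRad) rmseRad / (2 * pi) * 100

#' Screen synchronization offsets against the within-stack progression
#'
#' With a (near-)constant heart rate the offsets of consecutive slices of a
#' stack advance deterministically by the elapsed acquisition time expressed
#' as cardiac phase. Offsets that deviate from the robust consensus of this
#' progression by more than three scaled median absolute deviations (with a
#' floor of 0.35 rad) — typically anti-phase flips of motion-corrupted
#' slices whose cines carry too little pulsation — are replaced by the
#' progression-consistent prediction. The screen presumes slice-to-slice
#' heart-rate stability and is applied per stack.
#'
#' @param offsets per-slice offsets from [synchronizeSlices()], radians.
#' @param sliceStartTimes acquisition time of each slice's first frame, s.
#' @param tRR per-slice R-R intervals, seconds.
#' @param stackOfSlice integer stack membership per slice.
#' @param floorRad outlier threshold floor, radians (default 0.35).
#' @return list with `offsets` (corrected) and `flagged` (logical).
#' @export
screenSyncOffsets <- function(offsets, sliceStartTimes, tRR, stackOfSlice,
                              floorRad = 0.35) {
    n <- length(offsets)
    flagged <- rep(FALSE, n)
    out <- offsets
    circMedian <- function(x) {
        cost <- vapply(x, function(c) sum(abs(circDist(x, c))), 0)
        x[which.min(cost)]
    }
    for (s in unique(stackOfSlice)) {
        idx <- which(stackOfSlice == s)
        if (length(idx) < 3L) next
        dt <- sliceStartTimes[idx] - sliceStartTimes[idx[1]]
        # the progression frequency accumulates tiny rate errors over many
        # beats: refine it over a small band around the estimated rate by
        # maximising the circular consistency of the residuals
        f0 <- 1 / median(tRR[idx])
        cand <- f0 * (1 + seq(-0.008, 0.008, length.out = 257))
        # consensus (RANSAC-style) frequency: the progression aliases in f
        # over long stacks, so count the slices within the inlier radius of
        # the circular median rather than maximising a mean resultant
        best <- NULL
        for (f in cand) {
            r <- (offsets[idx] - 2 * pi * dt * f) %% (2 * pi)
            med <- circMedian(r)
            dev <- abs(circDist(r, med))
            inl <- dev < floorRad
            key <- c(sum(inl), -sum(dev[inl]))
            if (is.null(best) || key[1] > best$key[1] ||
                (key[1] == best$key[1] && key[2] > best$key[2]))
                best <- list(key = key, f = f, med = med, dev = dev)
        }
        e <- 2 * pi * dt * best$f
        thr <- max(3 * 1.4826 * median(best$dev), floorRad)
        bad <- best$dev > thr
        flagged[idx[bad]] <- TRUE
        out[idx[bad]] <- (best$med + e[bad]) %% (2 * pi)
    }
    list(offsets = out, flagged = flagged)
}
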