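# Volumetric reconstruction: PSF-weighted initialization, robust-statistics
# outlier rejection (EM) and super-resolution gradient descent with
# edge-preserving regularization; static (N_h = 1) and 4D cine variants.

# Build and cache the per-frame PSF factors against a volume grid.
buildPsfCache <- function(frames, volGrid, transforms, theta, nh, tRR,
                          temporalResolution = 0.072, truncation = 0.01) {
    nk <- length(frames)
    spatial <- vector("list", nk)
    dSinc <- matrix(1, nh, nk)
    dPos <- matrix(1, nh, nk)
    valid <- vector("list", nk)
    ph <- 2 * pi * (seq_len(nh) - 1) / nh
    for (k in seq_len(nk)) {
        spatial[[k]] <- spatialPsfWeights(frames[[k]], volGrid,
                                          transforms[[k]], truncation)
        valid[[k]] <- as.numeric(Matrix::rowSums(spatial[[k]])) > 0.5
        if (nh > 1L) {
            tw <- temporalPsfWeight(theta[k], ph, temporalResolution, tRR)
            tp <- pmax(tw, 0)
            s <- sum(tw)
            dSinc[, k] <- if (abs(s) > 1e-9) tw / s else tp / sum(tp)
            dPos[, k] <- tp / sum(tp)
        }
    }
    list(spatial = spatial, dSinc = dSinc, dPos = dPos, valid = valid,
         volGrid = volGrid, nh = nh)
}

#' PSF-weighted initialization of a cine volume
#'
#' Scattered-data interpolation
#' \eqn{x_{ih} = \sum_{jk} w_{ijhk} y^*_{jk} / \sum_{jk} w_{ijhk}} using the
#' non-negative interpolation kernel. Voxels that receive no weight are
#' filled by nearest-neighbour diffusion in space, then across phases, and
#' flagged in the returned provenance mask.
#'
#' @param frames list of [FrameImage-class].
#' @param transforms per-frame [RigidTransform-class].
#' @param theta per-frame cardiac phases (ignored for static volumes).
#' @param volGrid reconstruction [VoxelGrid-class].
#' @param nPhasesRecon number of reconstructed phases (1 = static).
#' @param tRR R-R interval, seconds (cine mode).
#' @param temporalResolution acquisition temporal resolution, seconds.
#' @param truncation PSF truncation fraction.
#' @param cache optional prebuilt PSF cache (internal use).
#' @param pixels optional list of pixel matrices overriding the frames'
#'   (e.g. intensity-corrected values).
#' @return list with `cine` ([CineVolume-class]), `weightSum`
#'   (`n_voxels x n_phases`) and `filled` (logical array of interpolated
#'   voxels).
#' @export
initializeCine <- function(frames, transforms, theta = NULL, volGrid,
                           nPhasesRecon = 1L, tRR = NA_real_,
                           temporalResolution = 0.072, truncation = 0.01,
                           cache = NULL, pixels = NULL) {
    nh <- as.integer(nPhasesRecon)
    if (is.null(cache))
        cache <- buildPsfCache(frames, volGrid, transforms, theta, nh, tRR,
                               temporalResolution, truncation)
    nvox <- prod(volGrid@shape)
    num <- matrix(0, nvox, nh)
    den <- matrix(0, nvox, nh)
    for (k in seq_along(frames)) {
        y <- if (is.null(pixels)) abs(frames[[k]]@pixels) else pixels[[k]]
        sp <- cache$spatial[[k]]
        gy <- as.numeric(Matrix::crossprod(sp, as.numeric(y)))
        g1 <- as.numeric(Matrix::crossprod(sp, rep(1, length(y))))
        num <- num + outer(gy, cache$dPos[, k])
        den <- den + outer(g1, cache$dPos[, k])
    }
    if (all(den <= 1e-12)) stop("entirely empty volume")
    x <- num / pmax(den, 1e-12)
    have <- den > 1e-12
    filled <- array(FALSE, c(volGrid@shape, nh))
    for (h in seq_len(nh)) {
        hv <- array(have[, h], volGrid@shape)
        if (!any(hv)) next
        f <- nnFillVolume(array(x[, h], volGrid@shape), hv)
        x[, h] <- f$vol
        filled[, , , h] <- f$filled
    }
    emptyPhase <- which(vapply(seq_len(nh), function(h) !any(have[, h]), TRUE))
    if (length(emptyPhase)) {
        ok <- setdiff(seq_len(nh), emptyPhase)
        for (h in emptyPhase) {
            nearest <- ok[which.min(abs(circDist(2 * pi * (ok - 1) / nh,
                                                 2 * pi * (h - 1) / nh)))]
            x[, h] <- x[, nearest]
            filled[, , , h] <- TRUE
        }
    }
    list(cine = CineVolume(array(x, c(volGrid@shape, nh)), volGrid, tRR = tRR),
         weightSum = den, filled = filled)
}

#' EM update of voxel-wise robust weights
#'
#' Models pooled residuals as a mixture of a zero-mean Gaussian inlier class
#' and a uniform outlier class over the observed residual range, and returns
#' the posterior inlier probability of every residual. Each call performs EM
#' iterations whose observed-data log-likelihood is non-decreasing.
#'
#' @param residuals numeric vector (or list of matrices) of residuals used
#'   to fit the mixture.
#' @param params previous mixture parameters for warm starting (`sigma2`,
#'   `cInlier`, `outlierRange`), or `NULL`.
#' @param nIter EM iterations per call (default 5).
#' @return list with `p` (posterior inlier probabilities, same shape as
#'   input), `params`, and `loglik` (trace, one value per iteration).
#' @export
voxelRobustWeights <- function(residuals, params = NULL, nIter = 5L) {
    shaped <- is.list(residuals)
    e <- as.numeric(unlist(residuals, use.names = FALSE))
    if (any(!is.finite(e))) stop("residuals must be finite")
    scale <- max(abs(e), 1e-12)
    if (diff(range(e)) < 1e-12 * max(scale, 1)) {
        # identical residuals: no outlier class is identifiable
        p <- rep(1, length(e))
        if (shaped) {
            out <- residuals
            pos <- 0
            for (k in seq_along(out)) {
                nk <- length(out[[k]])
                out[[k]][] <- 1
                pos <- pos + nk
            }
            p <- out
        }
        return(list(p = p, params = list(degenerate = TRUE),
                    loglik = numeric(0)))
    }
    if (isTRUE(params$degenerate)) params <- NULL
    rng <- max(diff(range(e)), 1e-6 * scale)
    if (is.null(params))
        params <- list(sigma2 = max(var(e), 1e-8 * scale^2), cInlier = 0.9,
                       outlierRange = rng)
    params$outlierRange <- rng
    ll <- numeric(0)
    for (it in seq_len(nIter)) {
        di <- params$cInlier * dnorm(e, 0, sqrt(params$sigma2))
        do <- (1 - params$cInlier) / params$outlierRange
        tot <- di + do
        ll <- c(ll, sum(log(pmax(tot, 1e-300))))
        g <- di / pmax(tot, 1e-300)
        params$sigma2 <- max(sum(g * e^2) / max(sum(g), 1e-12),
                             1e-8 * scale^2)
        params$cInlier <- min(max(mean(g), 1e-6), 1 - 1e-6)
    }
    di <- params$cInlier * dnorm(e, 0, sqrt(params$sigma2))
    do <- (1 - params$cInlier) / params$outlierRange
    p <- di / pmax(di + do, 1e-300)
    if (shaped) {
        out <- residuals
        pos <- 0
        for (k in seq_along(out)) {
            nk <- length(out[[k]])
            out[[k]][] <- p[pos + seq_len(nk)]
            pos <- pos + nk
        }
        p <- out
    }
    list(p = p, params = params, loglik = ll)
}

#' EM update of frame-wise robust weights
#'
#' Each frame's potential \eqn{q_k} is the root mean square of its
#' voxel-wise inlier probabilities over the heart mask. The potentials are
#' modelled as a two-class Gaussian mixture fitted by EM; the frame inlier
#' probability is the posterior of the higher-mean class. Frames
#' contributing fewer than `median(N_j)/10` in-mask pixels are excluded from
#' the fit and scored from the fitted model.
#'
#' @param pVoxel list of voxel-probability matrices, one per frame.
#' @param masks list of logical heart masks, one per frame.
#' @param params previous mixture parameters for warm starting, or `NULL`.
#' @param nIter EM iterations (default 30).
#' @return list with `p` (per-frame probabilities), `q` (frame potentials),
#'   `params` and `loglik` trace.
#' @export
frameRobustWeights <- function(pVoxel, masks, params = NULL, nIter = 30L) {
    nk <- length(pVoxel)
    if (nk < 2L) stop("at least 2 frames required")
    q <- vapply(seq_len(nk), function(k) {
        v <- pVoxel[[k]][masks[[k]]]
        if (length(v) == 0) NA_real_ else sqrt(mean(v^2))
    }, 0)
    nj <- vapply(masks, sum, 0)
    fitOn <- which(nj >= median(nj) / 10 & !is.na(q))
    qf <- q[fitOn]
    spread <- sd(qf)
    # potentials live on [0,1]: spreads below 0.02 carry no class structure
    if (!is.finite(spread) || spread < 0.02) {
        return(list(p = rep(1, nk), q = q,
                    params = list(degenerate = TRUE), loglik = numeric(0)))
    }
    if (is.null(params) || isTRUE(params$degenerate))
        params <- list(m1 = quantile(qf, 0.05, names = FALSE),
                       m2 = quantile(qf, 0.95, names = FALSE),
                       s1 = max(spread / 2, 0.02),
                       s2 = max(spread / 2, 0.02), w2 = 0.8)
    ll <- numeric(0)
    for (it in seq_len(nIter)) {
        d1 <- (1 - params$w2) * dnorm(qf, params$m1, params$s1)
        d2 <- params$w2 * dnorm(qf, params$m2, params$s2)
        tot <- pmax(d1 + d2, 1e-300)
        ll <- c(ll, sum(log(tot)))
        g2 <- d2 / tot
        g1 <- 1 - g2
        if (sum(g1) < 1e-9 || sum(g2) < 1e-9) break
        params$m1 <- sum(g1 * qf) / sum(g1)
        params$m2 <- sum(g2 * qf) / sum(g2)
        params$s1 <- max(sqrt(sum(g1 * (qf - params$m1)^2) / sum(g1)),
                         1e-4 * spread)
        params$s2 <- max(sqrt(sum(g2 * (qf - params$m2)^2) / sum(g2)),
                         1e-4 * spread)
        params$w2 <- min(max(mean(g2), 1e-6), 1 - 1e-6)
        if (params$m1 > params$m2) {      # keep class 2 the higher mean
            params[c("m1", "m2")] <- params[c("m2", "m1")]
            params[c("s1", "s2")] <- params[c("s2", "s1")]
            params$w2 <- 1 - params$w2
        }
    }
    if (abs(params$m2 - params$m1) < 0.02) {
        warning("frame potential mixture is degenerate; all frames accepted")
        return(list(p = rep(1, nk), q = q,
                    params = list(degenerate = TRUE), loglik = ll))
    }
    post <- function(x) {
        d1 <- (1 - params$w2) * dnorm(x, params$m1, params$s1)
        d2 <- params$w2 * dnorm(x, params$m2, params$s2)
        d2 / pmax(d1 + d2, 1e-300)
    }
    p <- rep(1, nk)
    p[!is.na(q)] <- post(q[!is.na(q)])
    params$degenerate <- FALSE
    list(p = p, q = q, params = params, loglik = ll)
}

# gradient and value of the edge-preserving regulariser
# phi(t) = 2*sqrt(1+t^2) - 2 on scaled first differences of the 6 spatial
# neighbours, no smoothing across the phase axis
edgeRegulariser <- function(xArr, edgeScale) {
    d <- dim(xArr)
    nh <- d[4]
    grad <- array(0, d)
    val <- 0
    for (h in seq_len(nh)) {
        x <- xArr[, , , h, drop = TRUE]
        dim(x) <- d[1:3]
        for (ax in 1:3) {
            dx <- (x - shiftArray(x, ax, 1L)) / edgeScale
            # zero the wrap rows (difference undefined at the boundary)
            if (ax == 1) dx[1, , ] <- 0
            if (ax == 2) dx[, 1, ] <- 0
            if (ax == 3) dx[, , 1] <- 0
            val <- val + sum(2 * sqrt(1 + dx^2) - 2)
            dphi <- 2 * dx / sqrt(1 + dx^2)
            g <- dphi - shiftArray(dphi, ax, -1L)
            grad[, , , h] <- grad[, , , h] + g / edgeScale
        }
    }
    list(value = val, grad = grad)
}

#' One super-resolution gradient-descent step
#'
#' Performs one preconditioned gradient-descent update on the robust
#' super-resolution objective
#' \eqn{\sum_{jk} p_{jk} e_{jk}^2 + \lambda R(X)}: the data term
#' back-projects probability-weighted residuals through the adjoint of the
#' acquisition model, and \eqn{R} applies the edge-preserving potential
#' \eqn{\varphi(t) = 2\sqrt{1+t^2} - 2} to the six spatial neighbour
#' differences scaled by `delta` times the mean in-mask intensity (no
#' smoothing across the phase axis). Steps producing non-finite values or an
#' increased objective are halved and retried.
#'
#' @param X current [CineVolume-class] estimate.
#' @param yStar list of intensity-corrected pixel matrices.
#' @param p list of combined per-pixel weights \eqn{p_{jk}} (voxel times
#'   frame probability).
#' @param cache PSF cache built against `X` (see [initializeCine()]).
#' @param config a [ReconConfig-class].
#' @param meanIntensity mean in-mask intensity defining the edge scale.
#' @param step step size override (default `config@step`).
#' @return list with `X` (updated cine), `objective` (value before the
#'   step), `dataTerm`, `stepUsed`.
#' @export
srStep <- function(X, yStar, p, cache, config, meanIntensity,
                   step = config@step) {
    d <- dim(X@voxels)
    nvox <- prod(d[1:3]); nh <- d[4]
    Xmat <- matrix(X@voxels, nvox, nh)
    G <- matrix(0, nvox, nh)
    W <- matrix(0, nvox, nh)
    dataTerm <- 0
    for (k in seq_along(yStar)) {
        sp <- cache$spatial[[k]]
        dk <- cache$dSinc[, k]
        pk <- as.numeric(p[[k]]) * cache$valid[[k]]
        yhat <- as.numeric(sp %*% as.numeric(Xmat %*% dk))
        e <- as.numeric(yStar[[k]]) - yhat
        dataTerm <- dataTerm + sum(pk * e^2)
        g <- as.numeric(Matrix::crossprod(sp, pk * e))
        G <- G + outer(g, dk)
        wv <- as.numeric(Matrix::crossprod(sp, pk))
        W <- W + outer(wv, cache$dPos[, k])
    }
    edgeScale <- config@delta * max(meanIntensity, 1e-12)
    reg <- edgeRegulariser(array(Xmat, d), edgeScale)
    objective <- dataTerm + config@lambda * edgeScale^2 * reg$value
    # denominator = data curvature (2W) + regulariser curvature bound
    # (|phi''| <= 2 over 12 neighbour terms => 24*lambda after scaling)
    descent <- (2 * G - config@lambda * edgeScale^2 *
                    matrix(reg$grad, nvox, nh)) /
        (2 * W + 24 * config@lambda + 1e-10)
    for (try in 1:6) {
        Xnew <- Xmat + step * descent
        if (all(is.finite(Xnew))) break
        step <- step / 2
    }
    list(X = CineVolume(array(Xnew, d), X@grid, tRR = X@tRR),
         objective = objective, dataTerm = dataTerm, stepUsed = step)
}

#' Full volumetric reconstruction with outlier rejection
#'
#' Runs PSF-weighted initialization followed by `nSR` iterations of
#' super-resolution gradient descent, with intensity matching, bias
#' correction and voxel- and frame-wise robust statistics re-estimated at
#' every iteration. `mode = "static"` reconstructs a single-phase volume
#' (the special case used inside the slice-volume registration stage);
#' `mode = "cine"` reconstructs the full 4D cine. Deterministic given its
#' inputs and the config seed.
#'
#' @param frames list of [FrameImage-class].
#' @param transforms per-frame [RigidTransform-class].
#' @param theta per-frame cardiac phases (cine mode).
#' @param volGrid reconstruction [VoxelGrid-class].
#' @param config a [ReconConfig-class].
#' @param tRR R-R interval, seconds (cine mode).
#' @param mode `"cine"` or `"static"`.
#' @param temporalResolution acquisition temporal resolution, seconds.
#' @param robust apply robust statistics (default `TRUE`).
#' @param bias estimate per-slice bias fields (default `TRUE`).
#' @param intensity apply per-frame intensity scaling (default `TRUE`).
#' @param fixedWeights optional [RobustWeights-class] applied as fixed
#'   per-pixel/per-frame weights instead of re-estimating them (used by the
#'   complex-valued reconstruction).
#' @param magnitude treat pixels as magnitudes (`abs`); `FALSE` uses the
#'   real part, for signed single-channel reconstructions.
#' @param truth optional ground-truth [CineVolume-class]; when given, the
#'   NRMSE against it is tracked per iteration.
#' @param truthMask optional logical volume restricting the NRMSE.
#' @return list with `cine`, `weights` (a [RobustWeights-class]),
#'   `diagnostics` (`objective`, `dataTerm`, `nrmse`, `scales`, `pFrame`,
#'   `filled`).
#' @export
reconstruct <- function(frames, transforms, theta = NULL, volGrid, config,
                        tRR = NA_real_, mode = c("cine", "static"),
                        temporalResolution = 0.072, robust = TRUE,
                        bias = TRUE, intensity = TRUE, magnitude = TRUE,
                        fixedWeights = NULL, truth = NULL, truthMask = NULL) {
    mode <- match.arg(mode)
    nh <- if (mode == "static") 1L else config@nPhases
    if (mode == "cine" && (is.null(theta) || !is.finite(tRR)))
        stop("cine mode requires theta and tRR")
    set.seed(config@seed)
    cache <- buildPsfCache(frames, volGrid, transforms, theta, nh, tRR,
                           temporalResolution, config@truncation)
    rawPixels <- lapply(frames, function(f)
        if (magnitude) Mod(f@pixels) else Re(f@pixels))
    masks <- lapply(frames, frameMask)
    init <- initializeCine(frames, transforms, theta, volGrid, nh, tRR,
                           temporalResolution, config@truncation,
                           cache = cache, pixels = rawPixels)
    X <- init$cine
    meanInt <- mean(unlist(lapply(seq_along(frames), function(k)
        rawPixels[[k]][masks[[k]]])))
    vox <- NULL; frm <- NULL
    pVox <- lapply(rawPixels, function(y) array(1, dim(y)))
    pFrame <- rep(1, length(frames))
    if (!is.null(fixedWeights)) {
        robust <- FALSE
        pVox <- fixedWeights@pVoxel
        pFrame <- fixedWeights@pFrame
    }
    objTrace <- numeric(0); dataTrace <- numeric(0); nrmseTrace <- numeric(0)
    scales <- rep(1, length(frames))
    nrmseOf <- function(C) {
        if (is.null(truth)) return(NA_real_)
        evaluateNrmse(C, truth, mask = truthMask)
    }
    nrmse0 <- nrmseOf(X)
    yStar <- rawPixels
    stepLocal <- config@step
    objPrev <- Inf
    Xprev <- X
    for (it in seq_len(config@nSR)) {
        d <- dim(X@voxels)
        Xmat <- matrix(X@voxels, prod(d[1:3]), d[4])
        predicted <- lapply(seq_along(frames), function(k) {
            matrix(as.numeric(cache$spatial[[k]] %*%
                       as.numeric(Xmat %*% cache$dSinc[, k])),
                   d0 <- nrow(rawPixels[[k]]), ncol(rawPixels[[k]]))
        })
        if (intensity) {
            im <- intensityMatch(frames, predicted,
                                 biasSigmaMm = if (bias) config@biasSigmaMm
                                               else NA_real_,
                                 valid = cache$valid)
            yStar <- im$corrected
            scales <- im$scales
        } else {
            yStar <- rawPixels
        }
        if (robust) {
            resid <- lapply(seq_along(frames), function(k)
                matrix(yStar[[k]] - predicted[[k]], nrow(yStar[[k]]),
                       ncol(yStar[[k]])))
            maskResid <- lapply(seq_along(frames), function(k)
                resid[[k]][masks[[k]] & matrix(cache$valid[[k]],
                                               nrow(resid[[k]]),
                                               ncol(resid[[k]]))])
            vox <- voxelRobustWeights(maskResid, params = vox$params)
            # evaluate posterior for all pixels from the fitted mixture
            pVox <- lapply(resid, function(e) {
                di <- vox$params$cInlier * dnorm(e, 0, sqrt(vox$params$sigma2))
                do <- (1 - vox$params$cInlier) / vox$params$outlierRange
                di / pmax(di + do, 1e-300)
            })
            frm <- frameRobustWeights(pVox, masks, params = frm$params)
            pFrame <- frm$p
        }
        pComb <- lapply(seq_along(frames), function(k) pVox[[k]] * pFrame[k])
        st <- srStep(X, yStar, pComb, cache, config, meanInt,
                     step = stepLocal)
        # backtrack when the previous step overshot the objective
        if (it > 1 && is.finite(objPrev) &&
            st$objective > objPrev * (1 + 1e-9) && stepLocal > 1e-3) {
            stepLocal <- stepLocal / 2
            st <- srStep(Xprev, yStar, pComb, cache, config, meanInt,
                         step = stepLocal)
        }
        objPrev <- st$objective
        Xprev <- st$X
        X <- st$X
        objTrace <- c(objTrace, st$objective)
        dataTrace <- c(dataTrace, st$dataTerm)
        nrmseTrace <- c(nrmseTrace, nrmseOf(X))
    }
    rw <- methods::new("RobustWeights", pVoxel = pVox, pFrame = pFrame,
                       params = list(voxel = vox$params, frame = frm$params))
    list(cine = X, weights = rw,
         diagnostics = list(objective = objTrace, dataTerm = dataTrace,
                            nrmse = c(nrmse0, nrmseTrace), scales = scales,
                            pFrame = pFrame, filled = init$filled))
}

#' Resample a cine volume onto another grid and phase count
#'
#' Trilinear interpolation in space and linear interpolation in cyclic
#' phase.
#'
#' @param X source [CineVolume-class].
#' @param grid target [VoxelGrid-class].
#' @param nPhasesOut target phase count.
#' @return A [CineVolume-class].
#' @export
resampleCineToGrid <- function(X, grid, nPhasesOut = nPhases(X)) {
    co <- gridWorldCoords(grid)
    nhIn <- nPhases(X)
    out <- array(0, c(grid@shape, nPhasesOut))
    for (h in seq_len(nPhasesOut)) {
        th <- 2 * pi * (h - 1) / nPhasesOut
        hf <- th / (2 * pi) * nhIn
        h0 <- floor(hf) %% nhIn; fr <- hf - floor(hf)
        h1 <- (h0 + 1) %% nhIn
        v <- (1 - fr) * sampleVolume(X@voxels[, , , h0 + 1], X@grid, co) +
            fr * sampleVolume(X@voxels[, , , h1 + 1], X@grid, co)
        out[, , , h] <- array(v, grid@shape)
    }
    CineVolume(out, grid, tRR = X@tRR)
}

#' Normalised RMS error between a reconstruction and ground truth
#'
#' The truth cine is resampled onto the reconstruction grid and phases; the
#' NRMSE is the RMS voxel difference divided by the RMS truth intensity over
#' the evaluation mask.
#'
#' @param recon reconstructed [CineVolume-class].
#' @param truth ground-truth [CineVolume-class] (any grid/phase count).
#' @param mask optional logical spatial mask on the reconstruction grid.
#' @return NRMSE (dimensionless).
#' @export
evaluateNrmse <- function(recon, truth, mask = NULL) {
    tr <- resampleCineToGrid(truth, recon@grid, nPhases(recon))
    if (is.null(mask)) {
        d <- recon@voxels - tr@voxels
        sqrt(mean(d^2)) / sqrt(mean(tr@voxels^2))
    } else {
        m <- as.logical(mask)
        nh <- nPhases(recon)
        num <- 0; den <- 0
        for (h in seq_len(nh)) {
            d <- recon@voxels[, , , h][m] - tr@voxels[, , , h][m]
            num <- num + sum(d^2)
            den <- den + sum(tr@voxels[, , , h][m]^2)
        }
        sqrt(num / den)
    }
}
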