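# Acquisition forward model: Gaussian spatial PSF, sinc temporal PSF,
# projection of a 4D cine into frame space, residuals, intensity matching.

FWHM2SD <- 1 / (2 * sqrt(2 * log(2)))

#' Spatial PSF weights of one frame against a volume grid
#'
#' Each frame pixel receives a 3D Gaussian footprint in volume space: the
#' in-plane full width at half maximum equals the in-plane pixel spacing and
#' the through-plane FWHM equals the slice thickness. Pixel centres are
#' mapped through the frame's rigid transform; the footprint is truncated
#' where the weight falls below `truncation` of its peak, and per-pixel
#' weights are normalised to sum to one.
#'
#' @param frame a [FrameImage-class].
#' @param volGrid target [VoxelGrid-class].
#' @param transform the frame's [RigidTransform-class] (frame to volume
#'   world).
#' @param truncation footprint cutoff relative to peak (default 0.01).
#' @return sparse `dgCMatrix` of size `n_pixels` x `n_voxels`; rows of
#'   pixels whose footprint misses the volume are zero.
#' @export
spatialPsfWeights <- function(frame, volGrid, transform = RigidTransform(),
                              truncation = 0.01) {
    if (any(volGrid@spacing <= 0) || any(volGrid@shape < 1))
        stop("degenerate volume grid")
    fg <- frame@grid
    P <- framePixelWorld(fg)
    Q <- transformPoints(transform, P)
    R <- rotationMatrix(transform@rotation)
    U <- R %*% fg@directions            # PSF axes in world after rotation
    sigma <- c(fg@spacing[1] * FWHM2SD, fg@spacing[2] * FWHM2SD,
               fg@spacing[3] * FWHM2SD)
    rad <- sigma * sqrt(2 * log(1 / truncation))
    # bounding half-width of the truncation ellipsoid along each volume axis
    proj <- abs(t(volGrid@directions) %*% U)   # |D_a . U_j|
    boxr <- as.integer(ceiling((proj %*% rad) / volGrid@spacing + 0.5))
    tri <- psf_triplets_cpp(Q, volGrid@origin, volGrid@spacing,
                            volGrid@directions, volGrid@shape, U, sigma,
                            truncation, boxr)
    npix <- nrow(P)
    nvox <- prod(volGrid@shape)
    W <- Matrix::sparseMatrix(i = tri$pixel, j = tri$voxel, x = tri$w,
                              dims = c(npix, nvox))
    rs <- Matrix::rowSums(W)
    rs[rs == 0] <- 1
    Matrix::Diagonal(x = 1 / rs) %*% W
}

#' Temporal PSF weight
#'
#' Sinc kernel in cyclic cardiac-phase distance, reflecting the band-limited
#' temporal response of the real-time acquisition. The kernel width is the
#' acquisition temporal resolution expressed as phase,
#' \eqn{\Delta\theta = 2\pi \cdot t_{acq} / t_{RR}}; the kernel is truncated
#' after two side lobes per side and distances wrap on \eqn{[0, 2\pi)}.
#'
#' @param thetaK frame cardiac phase(s), radians.
#' @param thetaH cine phase(s), radians.
#' @param temporalResolution acquisition temporal resolution, seconds
#'   (default 0.072).
#' @param tRR R-R interval, seconds.
#' @param nLobes side lobes retained per side (default 2).
#' @return numeric weight(s); 1 at zero distance, 0 at sinc nulls.
#' @export
temporalPsfWeight <- function(thetaK, thetaH, temporalResolution = 0.072,
                              tRR, nLobes = 2) {
    if (!is.finite(tRR) || tRR <= 0) stop("tRR must be positive")
    dtheta <- 2 * pi * temporalResolution / tRR
    d <- (thetaK - thetaH) %% (2 * pi)
    d <- ifelse(d > pi, d - 2 * pi, d)
    x <- d / dtheta
    w <- ifelse(abs(x) < 1e-12, 1, sin(pi * x) / (pi * x))
    w[abs(x) > (nLobes + 1)] <- 0
    w
}

#' Full PSF weights of one frame
#'
#' Combines the spatial Gaussian factor and the temporal sinc factor
#' (normalised so the temporal weights sum to 1) into a [PsfWeights-class].
#' With `nPhases = 1` the temporal factor is the scalar 1 (static
#' reconstruction).
#'
#' @inheritParams spatialPsfWeights
#' @param theta frame cardiac phase, radians.
#' @param nPhases number of cine phases.
#' @param temporalResolution acquisition temporal resolution, seconds.
#' @param tRR R-R interval, seconds (required when `nPhases > 1`).
#' @param temporalKernel `"sinc"` (full truncated sinc, for the
#'   super-resolution data term) or `"sincPos"` (non-negative main lobe,
#'   for PSF-weighted interpolation and volume weights).
#' @return A [PsfWeights-class].
#' @export
psfWeights <- function(frame, volGrid, transform = RigidTransform(),
                       theta = 0, nPhases = 1L, temporalResolution = 0.072,
                       tRR = NA_real_, truncation = 0.01,
                       temporalKernel = c("sinc", "sincPos")) {
    temporalKernel <- match.arg(temporalKernel)
    sp <- spatialPsfWeights(frame, volGrid, transform, truncation)
    if (nPhases <= 1L) {
        tw <- 1
    } else {
        ph <- 2 * pi * (seq_len(nPhases) - 1) / nPhases
        tw <- temporalPsfWeight(theta, ph, temporalResolution, tRR)
        if (temporalKernel == "sincPos") tw <- pmax(tw, 0)
        s <- sum(tw)
        if (abs(s) < 1e-9) {    # pathological: renormalise on nearest phase
            tw <- as.numeric(seq_len(nPhases) ==
                                 which.min(abs(circDist(ph, theta))))
        } else tw <- tw / s
    }
    methods::new("PsfWeights", spatial = sp, temporal = tw)
}

circDist <- function(a, b) {
    d <- (a - b) %% (2 * pi)
    ifelse(d > pi, d - 2 * pi, d)
}

#' Project a cine volume into frame space (acquisition model)
#'
#' Computes the model-predicted frame
#' \eqn{\hat y_k(j) = \sum_i \sum_h w_{ijhk} x_{ih}}.
#'
#' @param X a [CineVolume-class].
#' @param w a [PsfWeights-class] built against `X`'s grid and phase count.
#' @return numeric matrix of predicted pixel values (frame shaped).
#' @export
projectFrame <- function(X, w) {
    d <- dim(X@voxels)
    if (nrow(w@spatial) < 1 || ncol(w@spatial) != prod(d[1:3]) ||
        length(w@temporal) != d[4])
        stop("PSF weights do not match the cine grid")
    Xmat <- matrix(X@voxels, prod(d[1:3]), d[4])
    xk <- as.numeric(Xmat %*% w@temporal)
    as.numeric(w@spatial %*% xk)
}

# adjoint of projectFrame: spread per-pixel values r into a (nvox x nh) array
adjointFrame <- function(r, w, nvox, nh) {
    g <- as.numeric(Matrix::crossprod(w@spatial, as.numeric(r)))
    outer(g, w@temporal)
}

#' Residual between an acquired and a model-predicted frame
#'
#' @param yStar acquired (intensity-matched) pixel matrix or
#'   [FrameImage-class].
#' @param yHat predicted pixel matrix from [projectFrame()].
#' @return matrix of per-pixel residuals, acquired minus predicted.
#' @export
frameResidual <- function(yStar, yHat) {
    if (methods::is(yStar, "FrameImage")) yStar <- yStar@pixels
    if (is.matrix(yHat) && !all(dim(yHat) == dim(yStar)))
        stop("frame shape mismatch")
    if (!is.matrix(yHat)) {
        if (length(yHat) != length(yStar)) stop("frame shape mismatch")
        yHat <- matrix(yHat, nrow(yStar), ncol(yStar))
    }
    yStar - yHat
}

#' Per-frame intensity scales and per-slice bias fields
#'
#' Estimates a multiplicative scale per frame (robust ratio of the predicted
#' to the acquired in-mask medians) and a smooth multiplicative bias field
#' per slice (Gaussian-smoothed mean log-ratio of predicted to scaled
#' acquired intensities). Both are re-estimated at every reconstruction
#' iteration.
#'
#' @param frames list of [FrameImage-class].
#' @param predicted list of predicted pixel matrices, one per frame.
#' @param biasSigmaMm Gaussian smoothing width of the bias field, mm
#'   (default 8). `NA` disables bias estimation.
#' @param valid optional list of logical masks marking pixels whose model
#'   prediction is defined (inside the reconstruction volume); pixels
#'   outside are excluded from the fits.
#' @return list with `scales` (per frame), `bias` (per slice, named list of
#'   matrices) and `corrected` (list of corrected pixel matrices
#'   \eqn{y^*_{jk}}).
#' @export
intensityMatch <- function(frames, predicted, biasSigmaMm = 8,
                           valid = NULL) {
    n <- length(frames)
    vmask <- function(k) {
        m <- frames[[k]]@mask
        if (!is.null(valid))
            m <- m & matrix(as.logical(valid[[k]]), nrow(m), ncol(m))
        m
    }
    scales <- rep(1, n)
    for (k in seq_len(n)) {
        m <- vmask(k)
        if (!any(m)) next
        ya <- abs(frames[[k]]@pixels[m])
        yp <- abs(predicted[[k]][m])
        med <- median(ya)
        if (med <= 0) next                      # scale skipped
        scales[k] <- median(yp) / med
    }
    # the overall intensity scale of the reconstruction is a gauge: only
    # relative frame scaling is meaningful, so fix the (robust) geometric
    # median at 1 -- individual aberrant frames keep their relative scale
    pos <- scales > 0
    if (any(pos))
        scales[pos] <- scales[pos] / exp(median(log(scales[pos])))
    slices <- vapply(frames, function(f) f@slice, 0L)
    bias <- list()
    eps <- 1e-6 * max(abs(unlist(lapply(predicted, max))), 1e-12)
    for (l in unique(slices)) {
        ks <- which(slices == l)
        d <- dim(frames[[ks[1]]]@pixels)
        num <- matrix(0, d[1], d[2]); den <- matrix(0, d[1], d[2])
        for (k in ks) {
            m <- vmask(k)
            r <- log((abs(predicted[[k]]) + eps) /
                     (scales[k] * abs(frames[[k]]@pixels) + eps))
            num[m] <- num[m] + r[m]
            den[m] <- den[m] + 1
        }
        if (is.na(biasSigmaMm) || all(den == 0)) {
            bias[[as.character(l)]] <- matrix(1, d[1], d[2])
            next
        }
        sigmaPx <- biasSigmaMm / inPlaneSpacing(frames[[ks[1]]]@grid)
        smDen <- gaussSmooth2d(den, sigmaPx)
        logb <- gaussLocalLinear(num, den, sigmaPx)
        # only trust the field where the slice actually has coverage, and
        # bound it to a factor of 2 either way
        logb[smDen < 0.2 * max(smDen)] <- 0
        logb <- pmin(pmax(logb, -log(2)), log(2))
        bias[[as.character(l)]] <- exp(logb)
    }
    corrected <- lapply(seq_len(n), function(k) {
        out <- scales[k] * frames[[k]]@pixels * bias[[as.character(slices[k])]]
        out
    })
    list(scales = scales, bias = bias, corrected = corrected)
}

# Gaussian-weighted local linear fit of num/den (num = weighted values,
# den = weights): reproduces linear fields exactly, also at mask boundaries
gaussLocalLinear <- function(num, den, sigmaPx) {
    if (sigmaPx <= 0) return(num / pmax(den, 1e-9))
    sm <- function(x) gaussSmooth2d(x, sigmaPx)
    d <- dim(num)
    u <- matrix(seq_len(d[1]), d[1], d[2])
    v <- matrix(rep(seq_len(d[2]), each = d[1]), d[1], d[2])
    # weighted moment images (coordinates folded into the images, so one
    # Gaussian kernel serves all terms)
    M0 <- sm(den);      Mx <- sm(den * u);     My <- sm(den * v)
    Mxx <- sm(den * u * u); Mxy <- sm(den * u * v); Myy <- sm(den * v * v)
    C0 <- sm(num);      Cx <- sm(num * u);     Cy <- sm(num * v)
    # centre coordinates: solve the 3x3 weighted least squares per pixel for
    # the local value a0 + a1*(u-u0) + a2*(v-v0) evaluated at (u0, v0)
    mx <- Mx - M0 * u; my <- My - M0 * v
    sxx <- Mxx - 2 * u * Mx + u * u * M0
    syy <- Myy - 2 * v * My + v * v * M0
    sxy <- Mxy - u * My - v * Mx + u * v * M0
    c0 <- C0; cx <- Cx - u * C0; cy <- Cy - v * C0
    det <- M0 * (sxx * syy - sxy^2) - mx * (mx * syy - sxy * my) +
        my * (mx * sxy - sxx * my)
    a0 <- (c0 * (sxx * syy - sxy^2) - mx * (cx * syy - sxy * cy) +
               my * (cx * sxy - sxx * cy))
    out <- ifelse(abs(det) > 1e-9 * pmax(M0, 1e-12)^3 & M0 > 1e-9,
                  a0 / det, C0 / pmax(M0, 1e-9))
    matrix(out, d[1], d[2])
}

# 2D Gaussian smoothing (EBImage filter with zero-padded boundary)
gaussSmooth2d <- function(x, sigmaPx) {
    if (sigmaPx <= 0) return(x)
    size <- 2L * as.integer(ceiling(3 * sigmaPx)) + 1L
    size <- min(size, 2L * ((min(dim(x)) - 1L) %/% 2L) + 1L)
    if (size < 3L) return(x)
    kern <- EBImage::makeBrush(size, shape = "Gaussian", sigma = sigmaPx)
    as.matrix(EBImage::filter2(x, kern, boundary = 0))
}
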