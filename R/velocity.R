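# Proof-of-principle complex-valued (velocity-sensitive) reconstruction:
# background phase removal, phase-sign harmonization, separate real and
# imaginary reconstruction, and the linear phase-to-velocity mapping.

# quality-guided 2D phase unwrapping restricted to a mask: breadth-first
# growth from the highest-magnitude seed, adding 2*pi multiples so that
# neighbour differences stay below pi
unwrapPhase2d <- function(phase, mag, mask) {
    d <- dim(phase)
    out <- phase
    visited <- !mask
    if (!any(mask)) return(out)
    ord <- order(-as.numeric(mag) * as.numeric(mask))
    seed <- ord[1]
    qidx <- integer(sum(mask))
    qhead <- 1L; qtail <- 1L
    qidx[1] <- seed
    visited[seed] <- TRUE
    nb <- function(i) {
        r <- (i - 1L) %% d[1] + 1L
        c <- (i - 1L) %/% d[1] + 1L
        out <- integer(0)
        if (r > 1L) out <- c(out, i - 1L)
        if (r < d[1]) out <- c(out, i + 1L)
        if (c > 1L) out <- c(out, i - d[1])
        if (c < d[2]) out <- c(out, i + d[1])
        out
    }
    while (qhead <= qtail) {
        i <- qidx[qhead]; qhead <- qhead + 1L
        for (j in nb(i)) {
            if (visited[j]) next
            visited[j] <- TRUE
            dphi <- out[j] - out[i]
            out[j] <- out[j] - 2 * pi * round(dphi / (2 * pi))
            qtail <- qtail + 1L
            qidx[qtail] <- j
        }
    }
    out
}

# third-order 3D polynomial design matrix (20 monomials) on scaled coords
poly3Design <- function(xyz, centre, scale) {
    x <- (xyz[, 1] - centre[1]) / scale
    y <- (xyz[, 2] - centre[2]) / scale
    z <- (xyz[, 3] - centre[3]) / scale
    cbind(1, x, y, z, x^2, y^2, z^2, x * y, x * z, y * z,
          x^3, y^3, z^3, x^2 * y, x^2 * z, y^2 * x, y^2 * z, z^2 * x,
          z^2 * y, x * y * z)
}

#' Remove smooth background phase from complex frames
#'
#' Fits a third-order 3D polynomial (20 coefficients) to the unwrapped phase
#' of static-region voxels pooled across all frames of a stack, and
#' subtracts the fitted background phase from every frame. The residual
#' static-region phase has zero mean; applying the operation twice changes
#' the frames by less than 1e-9.
#'
#' @param frames list of complex-valued [FrameImage-class] from one stack.
#' @param staticMasks list of logical matrices marking static amniotic fluid
#'   and tissue, one per frame (recycled if length 1).
#' @return list of corrected [FrameImage-class].
#' @export
removeBackgroundPhase <- function(frames, staticMasks) {
    if (!is.list(staticMasks)) staticMasks <- list(staticMasks)
    if (length(staticMasks) == 1L)
        staticMasks <- rep(staticMasks, length(frames))
    pts <- list(); phs <- list()
    for (k in seq_along(frames)) {
        m <- staticMasks[[k]]
        if (!any(m)) next
        ph <- unwrapPhase2d(Arg(frames[[k]]@pixels), Mod(frames[[k]]@pixels),
                            m)
        P <- framePixelWorld(frames[[k]]@grid)
        keep <- as.numeric(m) > 0
        pts[[length(pts) + 1L]] <- P[keep, , drop = FALSE]
        phs[[length(phs) + 1L]] <- ph[m]
    }
    A <- do.call(rbind, pts)
    b <- unlist(phs)
    if (length(b) < 40) stop("fewer than 40 static voxels: underdetermined")
    centre <- colMeans(A)
    scale <- max(apply(A, 2, function(v) diff(range(v))) / 2, 1)
    X <- poly3Design(A, centre, scale)
    coef <- qr.coef(qr(X), b)
    coef[is.na(coef)] <- 0
    lapply(frames, function(f) {
        P <- framePixelWorld(f@grid)
        bg <- as.numeric(poly3Design(P, centre, scale) %*% coef)
        px <- f@pixels * exp(-1i * matrix(bg, nrow(f@pixels), ncol(f@pixels)))
        methods::initialize(f, pixels = px)
    })
}

#' Harmonize the velocity-encoding phase sign across stacks
#'
#' Chooses a global factor of +1 or -1 per stack so that the sign of the
#' (background-corrected) phase agrees with the target stack over their
#' spatially overlapping region. Each stack's phase is interpolated into a
#' common volume, and the sign maximising the correlation with the target is
#' applied; a stack with no overlap keeps +1 with a warning.
#'
#' @param framesByStack list (per stack) of lists of complex
#'   [FrameImage-class].
#' @param targetStack index of the target stack.
#' @param spacing working-grid spacing, mm.
#' @return list with `frames` (sign-corrected `framesByStack`) and `signs`.
#' @export
harmonizePhaseSign <- function(framesByStack, targetStack = 1L,
                               spacing = 3) {
    nS <- length(framesByStack)
    allFrames <- unlist(framesByStack, recursive = FALSE)
    grid <- framesBoundingGrid(allFrames, spacing)
    phVol <- function(frames) {
        ident <- lapply(frames, function(f) RigidTransform())
        mag <- initializeCine(frames, ident, volGrid = grid,
                              pixels = lapply(frames, function(f)
                                  Mod(f@pixels) * Arg(f@pixels)))
        wsum <- mag$weightSum[, 1]
        list(v = mag$cine@voxels[, , , 1], w = array(wsum, grid@shape))
    }
    tgt <- phVol(framesByStack[[targetStack]])
    signs <- rep(1, nS)
    for (s in seq_len(nS)) {
        if (s == targetStack) next
        cur <- phVol(framesByStack[[s]])
        both <- tgt$w > 1e-6 & cur$w > 1e-6
        if (sum(both) < 10) {
            warning("stack ", s, " has no overlap with the target stack; ",
                    "sign left at +1")
            next
        }
        cc <- suppressWarnings(stats::cor(tgt$v[both], cur$v[both]))
        if (is.finite(cc) && cc < 0) signs[s] <- -1
    }
    out <- lapply(seq_len(nS), function(s) {
        if (signs[s] > 0) return(framesByStack[[s]])
        lapply(framesByStack[[s]], function(f)
            methods::initialize(f, pixels = Conj(f@pixels)))
    })
    list(frames = out, signs = signs)
}

#' Complex-valued 4D cine reconstruction
#'
#' Reconstructs the real and imaginary channels separately with the
#' magnitude-pipeline machinery (reusing the robust weights estimated from
#' the magnitude pass rather than refitting them on complex residuals) and
#' combines them into a complex cine.
#'
#' @param frames list of complex [FrameImage-class] (background-corrected,
#'   sign-harmonized).
#' @param transforms per-frame [RigidTransform-class] from the magnitude
#'   pipeline.
#' @param theta per-frame cardiac phases.
#' @param volGrid reconstruction grid.
#' @param config a [ReconConfig-class].
#' @param tRR R-R interval, seconds.
#' @param weights optional [RobustWeights-class] from the magnitude
#'   reconstruction.
#' @return list with `cine` (complex-valued [CineVolume-class]) plus the
#'   per-channel diagnostics.
#' @export
reconstructComplex <- function(frames, transforms, theta, volGrid, config,
                               tRR, weights = NULL) {
    chanRecon <- function(part) {
        chan <- lapply(frames, function(f)
            methods::initialize(f, pixels = part(f@pixels) + 0i))
        reconstruct(chan, transforms, theta, volGrid, config,
                    tRR = tRR, mode = "cine", robust = FALSE,
                    bias = FALSE, intensity = FALSE, magnitude = FALSE,
                    fixedWeights = weights)
    }
    re <- chanRecon(Re)
    im <- chanRecon(Im)
    cine <- CineVolume(re$cine@voxels + 1i * im$cine@voxels,
                       volGrid, tRR = tRR)
    list(cine = cine, real = re, imaginary = im)
}

#' Map velocity-encoded phase to velocity
#'
#' Inverts the linear relation \eqn{\phi = \gamma (v \cdot M_1)} for the
#' single through-slice component: only `M1[3]` (the slice-direction first
#' moment of the velocity-encoding gradient waveform) may be non-zero;
#' decoding of multi-component first moments is not supported.
#'
#' @param phase phase map (radians), any numeric array.
#' @param M1 numeric triple of gradient first moments (readout,
#'   phase-encode, slice), in T s^2/m.
#' @param gamma gyromagnetic ratio, rad/s/T (default proton,
#'   2.675e8).
#' @return velocity array, m/s.
#' @export
phaseToVelocity <- function(phase, M1, gamma = 2.675e8) {
    if (length(M1) != 3L || all(M1 == 0)) stop("M1 must be non-zero")
    if (any(M1[1:2] != 0))
        stop("multi-component velocity decoding is not supported")
    phase / (gamma * M1[3])
}
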