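# Rigid-body geometry: transforms, SE(3) log/exp, Frechet mean, motion metrics.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

rotationMatrix <- function(anglesDeg) {
    a <- deg2rad(anglesDeg)
    ca <- cos(a); sa <- sin(a)
    Rx <- rbind(c(1, 0, 0), c(0, ca[1], -sa[1]), c(0, sa[1], ca[1]))
    Ry <- rbind(c(ca[2], 0, sa[2]), c(0, 1, 0), c(-sa[2], 0, ca[2]))
    Rz <- rbind(c(ca[3], -sa[3], 0), c(sa[3], ca[3], 0), c(0, 0, 1))
    Rz %*% Ry %*% Rx
}

anglesFromRotation <- function(R) {
    # inverse of Rz(rz) %*% Ry(ry) %*% Rx(rx)
    ry <- asin(max(-1, min(1, -R[3, 1])))
    if (abs(cos(ry)) > 1e-9) {
        rx <- atan2(R[3, 2], R[3, 3])
        rz <- atan2(R[2, 1], R[1, 1])
    } else {   # gimbal lock: fold rz into rx
        rx <- atan2(-R[2, 3], R[2, 2])
        rz <- 0
    }
    rad2deg(c(rx, ry, rz))
}

#' Homogeneous matrix of a rigid transform
#'
#' @param t a [RigidTransform-class].
#' @return 4x4 homogeneous matrix mapping world points, such that
#'   \eqn{A(x) = R (x - c) + c + t}.
#' @export
transformMatrix <- function(t) {
    R <- rotationMatrix(t@rotation)
    M <- diag(4)
    M[1:3, 1:3] <- R
    M[1:3, 4] <- t@centre + t@translation - R %*% t@centre
    M
}

#' Rigid transform from a homogeneous matrix
#'
#' @param M 4x4 rigid homogeneous matrix (rotation block determinant +1).
#' @param centre centre of rotation to use for the parameterisation.
#' @return A [RigidTransform-class] with `transformMatrix()` equal to `M`.
#' @export
transformFromMatrix <- function(M, centre = c(0, 0, 0)) {
    R <- M[1:3, 1:3]
    rot <- anglesFromRotation(R)
    trans <- M[1:3, 4] - centre + as.numeric(R %*% centre)
    RigidTransform(rotation = rot, translation = trans, centre = centre)
}

#' Apply a rigid transform to 3D points
#'
#' @param t a [RigidTransform-class].
#' @param pts numeric n x 3 matrix (or length-3 vector) of world points, mm.
#' @return n x 3 matrix of transformed points. Pairwise Euclidean distances
#'   are preserved to 1e-9 mm.
#' @examples
#' t <- RigidTransform(rotation = c(0, 0, 90))
#' transformPoints(t, c(1, 0, 0))
#' @export
transformPoints <- function(t, pts) {
    if (is.null(dim(pts))) pts <- matrix(pts, ncol = 3)
    if (any(!is.finite(pts))) stop("points must be finite")
    M <- transformMatrix(t)
    out <- pts %*% t(M[1:3, 1:3])
    out[, 1] <- out[, 1] + M[1, 4]
    out[, 2] <- out[, 2] + M[2, 4]
    out[, 3] <- out[, 3] + M[3, 4]
    out
}

#' Compose and invert rigid transforms
#'
#' `composeTransforms(a, b)` returns the transform applying `b` first and
#' then `a`; `invertTransform(a)` returns the inverse.
#'
#' @param a,b [RigidTransform-class] objects.
#' @param centre centre of rotation for the result's parameterisation
#'   (default: that of `a`).
#' @return A [RigidTransform-class].
#' @export
composeTransforms <- function(a, b, centre = a@centre) {
    transformFromMatrix(transformMatrix(a) %*% transformMatrix(b), centre)
}

#' @rdname composeTransforms
#' @export
invertTransform <- function(a, centre = a@centre) {
    M <- transformMatrix(a)
    Mi <- diag(4)
    Mi[1:3, 1:3] <- t(M[1:3, 1:3])
    Mi[1:3, 4] <- -t(M[1:3, 1:3]) %*% M[1:3, 4]
    transformFromMatrix(Mi, centre)
}

isIdentityTransform <- function(t, tol = 1e-12) {
    all(abs(t@rotation) < tol) && all(abs(t@translation) < tol)
}

skew <- function(w) rbind(c(0, -w[3], w[2]), c(w[3], 0, -w[1]),
                          c(-w[2], w[1], 0))

# se(3) logarithm: 4x4 rigid matrix -> 6-vector (omega, u), omega in radians
logSE3 <- function(M) {
    R <- M[1:3, 1:3]
    ct <- max(-1, min(1, (sum(diag(R)) - 1) / 2))
    theta <- acos(ct)
    if (theta < 1e-10) {
        w <- 0.5 * c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
    } else {
        w <- theta / (2 * sin(theta)) *
            c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
    }
    W <- skew(w)
    if (theta < 1e-10) {
        Vinv <- diag(3) - 0.5 * W
    } else {
        A <- sin(theta) / theta
        B <- (1 - cos(theta)) / theta^2
        Vinv <- diag(3) - 0.5 * W + (1 / theta^2) * (1 - A / (2 * B)) * (W %*% W)
    }
    u <- as.numeric(Vinv %*% M[1:3, 4])
    c(w, u)
}

# se(3) exponential: 6-vector (omega, u) -> 4x4 rigid matrix
expSE3 <- function(v) {
    w <- v[1:3]; u <- v[4:6]
    theta <- sqrt(sum(w^2))
    W <- skew(w)
    if (theta < 1e-10) {
        R <- diag(3) + W + 0.5 * (W %*% W)
        V <- diag(3) + 0.5 * W + (W %*% W) / 6
    } else {
        A <- sin(theta) / theta
        B <- (1 - cos(theta)) / theta^2
        C <- (theta - sin(theta)) / theta^3
        R <- diag(3) + A * W + B * (W %*% W)
        V <- diag(3) + B * W + C * (W %*% W)
    }
    M <- diag(4)
    M[1:3, 1:3] <- R
    M[1:3, 4] <- V %*% u
    M
}

#' Scale a rigid transform in the Lie algebra
#'
#' Multiplies the se(3) logarithm of the transform by `s` and maps back.
#' `s = 0` yields the identity; for small rotations displacement scales
#' linearly with `s`.
#'
#' @param t a [RigidTransform-class].
#' @param s non-negative scalar.
#' @return A [RigidTransform-class].
#' @export
scaleTransform <- function(t, s) {
    if (s < 0) stop("scale must be >= 0")
    transformFromMatrix(expSE3(s * logSE3(transformMatrix(t))), t@centre)
}

#' Weighted Frechet mean of rigid transforms
#'
#' Iterative geodesic averaging on the rigid-motion group in the
#' matrix-logarithm parameterisation: the estimate `M` is updated by the
#' weighted mean of \eqn{\log(M^{-1} A_k)} until the update norm falls below
#' `tol`. The result is invariant under permutation of the inputs, and
#' weights concentrated on one transform return that transform.
#'
#' @param transforms list of [RigidTransform-class].
#' @param weights non-negative per-transform weights, at least one positive.
#' @param centre centre of rotation for the result (default: centre of the
#'   first transform).
#' @param tol convergence tolerance on the se(3) update norm (default 1e-6).
#' @param maxIter maximum number of iterations (default 100).
#' @return A [RigidTransform-class].
#' @export
meanSliceTransform <- function(transforms, weights = NULL,
                               centre = transforms[[1]]@centre,
                               tol = 1e-6, maxIter = 100L) {
    n <- length(transforms)
    if (n == 0L) stop("no transforms given")
    if (is.null(weights)) weights <- rep(1, n)
    if (any(weights < 0) || all(weights == 0))
        stop("weights must be non-negative with at least one positive")
    w <- weights / sum(weights)
    mats <- lapply(transforms, transformMatrix)
    M <- mats[[which.max(w)]]
    for (it in seq_len(maxIter)) {
        Minv <- solve(M)
        v <- rep(0, 6)
        for (k in seq_len(n))
            if (w[k] > 0) v <- v + w[k] * logSE3(Minv %*% mats[[k]])
        M <- M %*% expSE3(v)
        if (sqrt(sum(v^2)) < tol) break
    }
    transformFromMatrix(M, centre)
}

# world coordinates (n x 3) of in-mask pixel centres of a frame
frameMaskWorld <- function(frame) {
    idx <- which(frame@mask, arr.ind = TRUE)
    if (nrow(idx) == 0L) stop("frame has no in-mask voxels")
    voxelToWorld(frame@grid, cbind(idx[, 1] - 1, idx[, 2] - 1, 0))
}

# frames kept for motion summary statistics: those contributing at least
# median(N_j)/10 in-mask voxels
motionSummaryKeep <- function(frames) {
    nj <- vapply(frames, function(f) sum(f@mask), 0)
    nj >= median(nj) / 10
}

#' Global displacement disp(A)
#'
#' Mean over frames and in-mask voxels of the distance between each voxel's
#' original and transformed world position. Frames contributing fewer than
#' `median(N_j)/10` in-mask voxels are excluded from the summary.
#'
#' @param transforms list of per-frame [RigidTransform-class].
#' @param frames list of [FrameImage-class].
#' @return Displacement in mm.
#' @export
globalDisplacement <- function(transforms, frames) {
    if (length(frames) == 0L) stop("empty frame set")
    if (length(transforms) != length(frames))
        stop("one transform per frame required")
    keep <- motionSummaryKeep(frames)
    tot <- 0; n <- 0
    for (k in which(keep)) {
        y <- frameMaskWorld(frames[[k]])
        d <- sqrt(rowSums((transformPoints(transforms[[k]], y) - y)^2))
        tot <- tot + sum(d); n <- n + length(d)
    }
    tot / n
}

#' Deviation from the per-slice mean transform
#'
#' For each slice the frame-weight-weighted Frechet mean transform is
#' computed; dev(A) is the mean over frames and in-mask voxels of the
#' distance between a voxel's position under the slice-mean transform and
#' under the frame transform. Per-slice values dev(A_l) restrict the sums to
#' one slice; slices whose frames have zero total weight get `NA`.
#'
#' @param transforms list of per-frame [RigidTransform-class].
#' @param frames list of [FrameImage-class] (slice membership from the
#'   `slice` slot).
#' @param frameWeights per-frame weights (e.g. frame inlier probabilities);
#'   default all 1.
#' @param truth optional list of ground-truth transforms; when given the TRE
#'   is included in the summary.
#' @return A [MotionSummary-class].
#' @export
deviationFromSliceMean <- function(transforms, frames, frameWeights = NULL,
                                   truth = NULL) {
    n <- length(frames)
    if (n == 0L) stop("empty frame set")
    if (is.null(frameWeights)) frameWeights <- rep(1, n)
    slices <- vapply(frames, function(f) f@slice, 0L)
    keep <- motionSummaryKeep(frames)
    tot <- 0; ntot <- 0
    perSlice <- setNames(rep(NA_real_, length(unique(slices))),
                         as.character(sort(unique(slices))))
    for (l in sort(unique(slices))) {
        ks <- which(slices == l)
        wl <- frameWeights[ks]
        if (sum(wl) <= 0) next
        Abar <- meanSliceTransform(transforms[ks], wl)
        stot <- 0; sn <- 0
        for (k in ks[keep[ks]]) {
            y <- frameMaskWorld(frames[[k]])
            d <- sqrt(rowSums((transformPoints(Abar, y) -
                               transformPoints(transforms[[k]], y))^2))
            stot <- stot + sum(d); sn <- sn + length(d)
        }
        if (sn > 0) perSlice[as.character(l)] <- stot / sn
        tot <- tot + stot; ntot <- ntot + sn
    }
    tre <- if (is.null(truth)) NA_real_ else
        targetRegistrationError(transforms, truth, frames)
    methods::new("MotionSummary",
                 disp = globalDisplacement(transforms, frames),
                 dev = tot / ntot, perSliceDev = perSlice, tre = tre)
}

#' Target registration error
#'
#' Mean over frames and in-mask voxels of the distance between voxel
#' positions under the estimated and ground-truth transforms.
#'
#' @param est,truth lists of per-frame [RigidTransform-class], same length.
#' @param frames list of [FrameImage-class].
#' @return TRE in mm.
#' @export
targetRegistrationError <- function(est, truth, frames) {
    if (length(est) != length(truth) || length(est) != length(frames))
        stop("est, truth and frames must have matching lengths")
    tot <- 0; n <- 0
    for (k in seq_along(frames)) {
        y <- frameMaskWorld(frames[[k]])
        d <- sqrt(rowSums((transformPoints(est[[k]], y) -
                           transformPoints(truth[[k]], y))^2))
        tot <- tot + sum(d); n <- n + length(d)
    }
    tot / n
}

#' Read and write rigid transforms as CSV
#'
#' One row per frame with columns `frame`, `rx`, `ry`, `rz` (degrees), `tx`,
#' `ty`, `tz`, `cx`, `cy`, `cz` (mm). Values are written with 17 significant
#' digits so that a write/read round trip is bit-exact.
#'
#' @param transforms list of [RigidTransform-class].
#' @param file path to the CSV file.
#' @param ids optional frame identifiers (default `seq_along(transforms)`).
#' @return `readTransforms` returns a named list of
#'   [RigidTransform-class] objects.
#' @export
writeTransforms <- function(transforms, file, ids = seq_along(transforms)) {
    p <- t(vapply(transforms, function(tr)
        c(tr@rotation, tr@translation, tr@centre), numeric(9)))
    df <- data.frame(frame = ids,
                     rx = p[, 1], ry = p[, 2], rz = p[, 3],
                     tx = p[, 4], ty = p[, 5], tz = p[, 6],
                     cx = p[, 7], cy = p[, 8], cz = p[, 9])
    num <- vapply(df, is.double, TRUE)
    df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
    write.csv(df, file, row.names = FALSE, quote = FALSE)
    invisible(file)
}

#' @rdname writeTransforms
#' @export
readTransforms <- function(file) {
    df <- read.csv(file)
    out <- lapply(seq_len(nrow(df)), function(i)
        RigidTransform(rotation = as.numeric(df[i, c("rx", "ry", "rz")]),
                       translation = as.numeric(df[i, c("tx", "ty", "tz")]),
                       centre = as.numeric(df[i, c("cx", "cy", "cz")])))
    names(out) <- df$frame
    out
}
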