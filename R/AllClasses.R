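#' @import methods
#' @importFrom stats dnorm fft mad median optimize optim quantile rnorm runif sd var approx setNames
#' @importFrom utils head read.csv tail write.csv
#' @useDynLib fetalcine4d, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

#' Regular 3D voxel grid in world (scanner) coordinates
#'
#' Describes the geometry of an image array: integer extent, voxel spacing in
#' mm, the world position of the centre of voxel (0,0,0) and an orthonormal
#' direction matrix whose columns are the world directions of the array axes.
#' Voxel indices are 0-based; the centre of voxel \eqn{(i,j,k)} maps to world
#' position \eqn{o + D (s \odot (i,j,k))}.
#'
#' @slot shape integer triple, array extent per axis.
#' @slot spacing numeric triple, mm per voxel along each axis (for a 2D frame
#'   the third component is the slice thickness).
#' @slot origin numeric triple, world position (mm) of the first voxel centre.
#' @slot directions orthonormal 3x3 matrix, columns are axis directions.
#' @export
setClass("VoxelGrid",
    representation(shape = "integer", spacing = "numeric",
                   origin = "numeric", directions = "matrix"),
    validity = function(object) {
        msg <- character()
        if (length(object@shape) != 3L || any(object@shape < 1L))
            msg <- c(msg, "shape must be 3 positive integers")
        if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
            any(object@spacing <= 0))
            msg <- c(msg, "spacing must be 3 strictly positive values")
        if (length(object@origin) != 3L || any(!is.finite(object@origin)))
            msg <- c(msg, "origin must be 3 finite values")
        D <- object@directions
        if (!all(dim(D) == c(3L, 3L)) ||
            max(abs(crossprod(D) - diag(3))) > 1e-9)
            msg <- c(msg, "directions must be orthonormal 3x3 to 1e-9")
        if (length(msg)) msg else TRUE
    })

#' Six-parameter rigid-body transform
#'
#' A rotation (three fixed-axis angles, degrees) about a centre point followed
#' by a translation (mm): \eqn{A(x) = R (x - c) + c + t}. The rotation matrix
#' is composed in the fixed order \eqn{R = R_z R_y R_x}.
#'
#' @slot rotation numeric triple, rotation angles in degrees about the world
#'   x, y and z axes.
#' @slot translation numeric triple, mm.
#' @slot centre numeric triple, world point (mm) about which rotation acts.
#' @export
setClass("RigidTransform",
    representation(rotation = "numeric", translation = "numeric",
                   centre = "numeric"),
    prototype(rotation = c(0, 0, 0), translation = c(0, 0, 0),
              centre = c(0, 0, 0)),
    validity = function(object) {
        if (length(object@rotation) != 3L || length(object@translation) != 3L ||
            length(object@centre) != 3L)
            return("rotation, translation and centre must each have length 3")
        if (any(!is.finite(c(object@rotation, object@translation, object@centre))))
            return("all parameters must be finite")
        TRUE
    })

#' One acquired or simulated 2D real-time image frame
#'
#' A single real-time frame with its slice geometry, acquisition time, slice
#' and stack membership and a heart-region mask. Pixels are magnitude
#' intensities (non-negative) or complex values for the velocity-sensitive
#' path.
#'
#' @slot pixels numeric or complex matrix of pixel values.
#' @slot grid a [VoxelGrid-class] with shape `c(nx, ny, 1)`; the third spacing
#'   component is the slice thickness.
#' @slot time acquisition time in seconds.
#' @slot slice integer slice identifier (unique across stacks).
#' @slot stack integer stack identifier.
#' @slot mask logical matrix, heart-region mask, same shape as `pixels`.
#' @export
setClass("FrameImage",
    representation(pixels = "ANY", grid = "VoxelGrid", time = "numeric",
                   slice = "integer", stack = "integer", mask = "matrix"),
    validity = function(object) {
        p <- object@pixels
        if (!(is.matrix(p) && (is.numeric(p) || is.complex(p))))
            return("pixels must be a numeric or complex matrix")
        if (is.numeric(p) && any(p < -1e-9, na.rm = TRUE))
            return("magnitude pixels must be non-negative")
        if (!identical(dim(object@mask), dim(p)))
            return("mask must have the same shape as pixels")
        if (!is.logical(object@mask)) return("mask must be logical")
        if (object@grid@shape[3] != 1L)
            return("frame grid must have shape (nx, ny, 1)")
        if (!all(dim(p) == object@grid@shape[1:2]))
            return("pixel array does not match grid shape")
        TRUE
    })

#' 4D cine volume (3 spatial dimensions + cyclic cardiac phase)
#'
#' @slot voxels 4D numeric (or complex) array, dimensions (x, y, z, phase).
#' @slot grid spatial [VoxelGrid-class].
#' @slot phases numeric vector of cardiac phases \eqn{\vartheta_h} on
#'   \eqn{[0, 2\pi)}, equally spaced starting at 0; length 1 denotes a static
#'   volume.
#' @slot tRR nominal R-R interval in seconds (NA if unknown).
#' @export
setClass("CineVolume",
    representation(voxels = "array", grid = "VoxelGrid", phases = "numeric",
                   tRR = "numeric"),
    validity = function(object) {
        d <- dim(object@voxels)
        if (length(d) != 4L) return("voxels must be a 4D array")
        if (!all(d[1:3] == object@grid@shape))
            return("spatial dimensions do not match grid shape")
        nh <- length(object@phases)
        if (nh < 1L || d[4] != nh)
            return("phase axis length must equal length(phases)")
        want <- 2 * pi * (seq_len(nh) - 1) / nh
        if (max(abs(object@phases - want)) > 1e-9)
            return("phases must be equally spaced on [0, 2*pi) starting at 0")
        TRUE
    })

#' Point-spread-function weights linking one frame to a cine volume
#'
#' The acquisition model couples frame pixel \eqn{j} of frame \eqn{k} to cine
#' voxel \eqn{i} and phase \eqn{h} through \eqn{w_{ijhk} = d_{hk} m_{ijk}}:
#' a spatial factor (sparse matrix, pixels x voxels, rows normalised to sum
#' to 1) and a temporal factor (one weight per cardiac phase, summing to 1).
#'
#' @slot spatial sparse `dgCMatrix`, `n_pixels` x `n_voxels`.
#' @slot temporal numeric vector, one weight per cine phase.
#' @export
setClass("PsfWeights",
    representation(spatial = "ANY", temporal = "numeric"),
    validity = function(object) {
        if (!methods::is(object@spatial, "sparseMatrix"))
            return("spatial must be a sparse Matrix")
        if (any(object@spatial@x < -1e-12))
            return("spatial coefficients must be non-negative")
        TRUE
    })

#' Per-frame cardiac timing
#'
#' @slot theta numeric vector, cardiac phase of each frame on \eqn{[0,2\pi)}.
#' @slot tRR named numeric, R-R interval (s) per slice.
#' @slot offsets named numeric, cyclic offset \eqn{\theta_l^{offset}} per
#'   slice on \eqn{[0, 2\pi)}.
#' @export
setClass("CardiacTiming",
    representation(theta = "numeric", tRR = "numeric", offsets = "numeric"),
    validity = function(object) {
        if (any(object@theta < -1e-9 | object@theta >= 2 * pi + 1e-9))
            return("theta must lie on [0, 2*pi)")
        TRUE
    })

#' Robust-statistics inlier probabilities
#'
#' Voxel-wise and frame-wise posterior probabilities of being an inlier,
#' together with the fitted mixture parameters.
#'
#' @slot pVoxel list of numeric matrices (one per frame) of voxel-wise inlier
#'   probabilities.
#' @slot pFrame numeric vector of frame-wise inlier probabilities.
#' @slot params list of mixture parameters (`sigma2`, `cInlier`,
#'   `outlierRange` at voxel level; `frameMix` at frame level).
#' @export
setClass("RobustWeights",
    representation(pVoxel = "list", pFrame = "numeric", params = "list"),
    validity = function(object) {
        pv <- unlist(object@pVoxel, use.names = FALSE)
        if (length(pv) && (min(pv) < -1e-9 || max(pv) > 1 + 1e-9))
            return("pVoxel must lie in [0,1]")
        if (length(object@pFrame) &&
            (min(object@pFrame) < -1e-9 || max(object@pFrame) > 1 + 1e-9))
            return("pFrame must lie in [0,1]")
        TRUE
    })

#' Summary of estimated motion
#'
#' Holds the global displacement disp(A), global deviation from the per-slice
#' mean transform dev(A), per-slice deviations dev(A_l) and, when ground-truth
#' transforms are available, the target registration error (all mm).
#'
#' @slot disp mean voxel displacement, mm.
#' @slot dev mean deviation from per-slice mean transforms, mm.
#' @slot perSliceDev named numeric, dev(A_l) per slice (NA where undefined).
#' @slot tre target registration error in mm, NA when no ground truth.
#' @export
setClass("MotionSummary",
    representation(disp = "numeric", dev = "numeric",
                   perSliceDev = "numeric", tre = "numeric"),
    prototype(tre = NA_real_),
    validity = function(object) {
        vals <- c(object@disp, object@dev, object@perSliceDev, object@tre)
        if (any(vals < -1e-12, na.rm = TRUE))
            return("motion summaries must be non-negative")
        TRUE
    })

#' Specification of the numerical beating-heart phantom
#'
#' An analytic ellipsoid phantom of the fetal heart in utero: ventricular and
#' atrial blood pools with a myocardial shell, embedded in fetal body tissue
#' and surrounded by amniotic fluid. Ventricular inner radii contract
#' cyclically with cardiac phase while the atria move in anti-phase.
#'
#' @slot grid high-resolution [VoxelGrid-class] on which the phantom cine is
#'   evaluated (default 0.44 mm isotropic).
#' @slot nPhases number of cardiac phases (default 25).
#' @slot heartRateBpm phantom heart rate, beats per minute (default 150).
#' @slot chambers list of chambers; each a list with `centre` (mm), `radii`
#'   (mm, ellipsoid semi-axes at end-diastole) and `role`
#'   (`"ventricle"` or `"atrium"`).
#' @slot wallThickness myocardial wall thickness, mm.
#' @slot contractionFrac peak fractional shortening of ventricular inner
#'   radii over the cycle (0 = static heart).
#' @slot signal named numeric signal levels (arbitrary units) for `blood`,
#'   `myocardium`, `fluid` (amniotic), `tissue`.
#' @slot bodyRadii semi-axes (mm) of the ellipsoidal fetal body cross-section
#'   surrounding the heart.
#' @export
setClass("PhantomSpec",
    representation(grid = "VoxelGrid", nPhases = "integer",
                   heartRateBpm = "numeric", chambers = "list",
                   wallThickness = "numeric", contractionFrac = "numeric",
                   signal = "numeric", bodyRadii = "numeric"),
    validity = function(object) {
        if (object@nPhases < 2L) return("nPhases must be >= 2")
        if (object@contractionFrac < 0 || object@contractionFrac >= 1)
            return("contractionFrac must be in [0, 1)")
        need <- c("blood", "myocardium", "fluid", "tissue")
        if (!all(need %in% names(object@signal)))
            return("signal must name blood, myocardium, fluid, tissue")
        if (any(object@signal < 0)) return("signal levels must be >= 0")
        TRUE
    })

#' Rigid motion trajectory with ground-truth bookkeeping
#'
#' @slot transforms list of per-frame [RigidTransform-class] (the ground
#'   truth A*).
#' @slot scale dimensionless displacement scale factor applied in the Lie
#'   algebra; 0 yields identity transforms.
#' @slot times frame acquisition times, seconds.
#' @export
setClass("MotionTrajectory",
    representation(transforms = "list", scale = "numeric", times = "numeric"),
    validity = function(object) {
        if (object@scale < 0) return("scale must be >= 0")
        if (!all(vapply(object@transforms, methods::is, TRUE,
                        class2 = "RigidTransform")))
            return("transforms must all be RigidTransform")
        TRUE
    })

#' Reconstruction configuration
#'
#' @slot spacing reconstruction voxel size, mm (default 1.25).
#' @slot nPhases number of reconstructed cardiac phases (default 25).
#' @slot lambda edge-preserving regularisation weight.
#' @slot delta edge definition parameter, relative to mean in-mask intensity.
#' @slot nSR number of super-resolution gradient-descent iterations
#'   (default 20).
#' @slot step gradient step size (relative; the step is preconditioned by the
#'   accumulated PSF weight per voxel).
#' @slot truncation spatial PSF footprint truncation, fraction of peak
#'   (default 0.01).
#' @slot biasSigmaMm Gaussian smoothing width of the per-slice bias field, mm.
#' @slot seed integer seed for any stochastic initialisation.
#' @export
setClass("ReconConfig",
    representation(spacing = "numeric", nPhases = "integer",
                   lambda = "numeric", delta = "numeric", nSR = "integer",
                   step = "numeric", truncation = "numeric",
                   biasSigmaMm = "numeric", seed = "integer"),
    validity = function(object) {
        if (object@lambda < 0) return("lambda must be >= 0")
        if (object@delta <= 0) return("delta must be > 0")
        if (object@nSR < 1L) return("nSR must be >= 1")
        if (object@truncation <= 0 || object@truncation >= 1)
            return("truncation must be in (0, 1)")
        TRUE
    })
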