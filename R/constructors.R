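#' Construct a VoxelGrid
#'
#' @param shape integer triple.
#' @param spacing numeric triple, mm (scalar recycled).
#' @param origin world position of first voxel centre, mm. By default the
#'   grid is centred on the world origin.
#' @param directions orthonormal 3x3 direction matrix (columns = axes).
#' @return A [VoxelGrid-class].
#' @examples
#' g <- VoxelGrid(c(32, 32, 32), 1.25)
#' @export
VoxelGrid <- function(shape, spacing, origin = NULL, directions = diag(3)) {
    shape <- as.integer(shape)
    spacing <- rep_len(as.numeric(spacing), 3L)
    if (is.null(origin))
        origin <- as.numeric(-directions %*% (spacing * (shape - 1) / 2))
    methods::new("VoxelGrid", shape = shape, spacing = spacing,
                 origin = as.numeric(origin), directions = directions)
}

#' Construct a RigidTransform
#'
#' @param rotation angles in degrees about the fixed world x, y, z axes
#'   (composed as \eqn{R_z R_y R_x}).
#' @param translation mm.
#' @param centre centre of rotation, mm.
#' @return A [RigidTransform-class].
#' @examples
#' RigidTransform(rotation = c(0, 0, 90), translation = c(1, 0, 0))
#' @export
RigidTransform <- function(rotation = c(0, 0, 0), translation = c(0, 0, 0),
                           centre = c(0, 0, 0)) {
    methods::new("RigidTransform", rotation = as.numeric(rotation),
                 translation = as.numeric(translation),
                 centre = as.numeric(centre))
}

#' Construct a FrameImage
#'
#' @param pixels numeric (magnitude) or complex matrix.
#' @param grid frame [VoxelGrid-class] with shape `c(nx, ny, 1)`.
#' @param time acquisition time, seconds.
#' @param slice,stack integer identifiers.
#' @param mask logical heart-region mask (default: all `TRUE`).
#' @return A [FrameImage-class].
#' @export
FrameImage <- function(pixels, grid, time = 0, slice = 1L, stack = 1L,
                       mask = NULL) {
    if (is.null(mask))
        mask <- matrix(TRUE, nrow(pixels), ncol(pixels))
    methods::new("FrameImage", pixels = pixels, grid = grid,
                 time = as.numeric(time), slice = as.integer(slice),
                 stack = as.integer(stack), mask = mask)
}

#' Construct a CineVolume
#'
#' @param voxels 4D array (x, y, z, phase); a 3D array is promoted to a
#'   single-phase static volume.
#' @param grid spatial [VoxelGrid-class].
#' @param tRR nominal R-R interval, seconds.
#' @return A [CineVolume-class].
#' @export
CineVolume <- function(voxels, grid, tRR = NA_real_) {
    if (length(dim(voxels)) == 3L) dim(voxels) <- c(dim(voxels), 1L)
    nh <- dim(voxels)[4]
    methods::new("CineVolume", voxels = voxels, grid = grid,
                 phases = 2 * pi * (seq_len(nh) - 1) / nh,
                 tRR = as.numeric(tRR))
}

#' Reconstruction configuration with package defaults
#'
#' Defaults mirror the study settings: 1.25 mm reconstruction grid, 25
#' cardiac phases, 20 super-resolution iterations, spatial PSF footprints
#' truncated at 1 percent of peak, and a per-slice bias field smoothed with
#' an 8 mm Gaussian. `lambda` and `delta` defaults were chosen by a grid
#' search on the packaged phantom (see `scripts/param_grid.R`).
#'
#' @param spacing,nPhases,lambda,delta,nSR,step,truncation,biasSigmaMm,seed
#'   see [ReconConfig-class].
#' @return A [ReconConfig-class].
#' @examples
#' cfg <- ReconConfig(spacing = 2, nPhases = 8, nSR = 5)
#' @export
ReconConfig <- function(spacing = 1.25, nPhases = 25L, lambda = 0.05,
                        delta = 0.25, nSR = 20L, step = 0.5, truncation = 0.01,
                        biasSigmaMm = 8, seed = 2019L) {
    methods::new("ReconConfig", spacing = as.numeric(spacing),
                 nPhases = as.integer(nPhases), lambda = as.numeric(lambda),
                 delta = as.numeric(delta), nSR = as.integer(nSR),
                 step = as.numeric(step), truncation = as.numeric(truncation),
                 biasSigmaMm = as.numeric(biasSigmaMm), seed = as.integer(seed))
}

setMethod("show", "VoxelGrid", function(object) {
    cat("VoxelGrid:", paste(object@shape, collapse = " x "),
        "voxels,", paste(signif(object@spacing, 4), collapse = " x "),
        "mm\n")
})

setMethod("show", "RigidTransform", function(object) {
    cat(sprintf(
        "RigidTransform: rot (%.3f, %.3f, %.3f) deg, trans (%.3f, %.3f, %.3f) mm\n",
        object@rotation[1], object@rotation[2], object@rotation[3],
        object@translation[1], object@translation[2], object@translation[3]))
})

setMethod("show", "FrameImage", function(object) {
    cat(sprintf("FrameImage: %d x %d px, slice %d, stack %d, t = %.3f s\n",
                nrow(object@pixels), ncol(object@pixels), object@slice,
                object@stack, object@time))
})

setMethod("show", "CineVolume", function(object) {
    d <- dim(object@voxels)
    cat(sprintf("CineVolume: %d x %d x %d voxels, %d phase(s), %s mm\n",
                d[1], d[2], d[3], d[4],
                paste(signif(object@grid@spacing, 4), collapse = " x ")))
})

setMethod("show", "MotionSummary", function(object) {
    cat(sprintf("MotionSummary: disp %.3f mm, dev %.3f mm%s\n",
                object@disp, object@dev,
                if (is.na(object@tre)) "" else
                    sprintf(", TRE %.3f mm", object@tre)))
})

#' Accessors for cine volumes and frames
#'
#' `cineArray` returns the raw 4D array, `cineGrid`/`frameGrid` the geometry,
#' `framePixels`/`frameMask` the pixel data and heart mask, `frameTime` the
#' acquisition time and `nPhases` the number of cardiac phases.
#'
#' @param x a [CineVolume-class] or [FrameImage-class].
#' @return The corresponding slot value.
#' @aliases cineArray cineGrid nPhases framePixels frameMask frameGrid
#'   frameTime
#' @name accessors
NULL

#' @rdname accessors
#' @export
cineArray <- function(x) x@voxels
#' @rdname accessors
#' @export
cineGrid <- function(x) x@grid
#' @rdname accessors
#' @export
nPhases <- function(x) length(x@phases)
#' @rdname accessors
#' @export
framePixels <- function(x) x@pixels
#' @rdname accessors
#' @export
frameMask <- function(x) x@mask
#' @rdname accessors
#' @export
frameGrid <- function(x) x@grid
#' @rdname accessors
#' @export
frameTime <- function(x) x@time
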