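# Grid coordinate mapping and volume sampling helpers.

#' Map voxel indices to world coordinates
#'
#' @param grid a [VoxelGrid-class].
#' @param ijk n x 3 matrix of 0-based voxel indices (may be fractional).
#' @return n x 3 matrix of world coordinates, mm.
#' @export
voxelToWorld <- function(grid, ijk) {
    if (is.null(dim(ijk))) ijk <- matrix(ijk, ncol = 3)
    out <- (ijk * rep(grid@spacing, each = nrow(ijk))) %*% t(grid@directions)
    out[, 1] <- out[, 1] + grid@origin[1]
    out[, 2] <- out[, 2] + grid@origin[2]
    out[, 3] <- out[, 3] + grid@origin[3]
    out
}

#' Map world coordinates to (fractional, 0-based) voxel indices
#'
#' @param grid a [VoxelGrid-class].
#' @param xyz n x 3 matrix of world coordinates, mm.
#' @return n x 3 matrix of continuous voxel indices.
#' @export
worldToVoxel <- function(grid, xyz) {
    if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3)
    xyz[, 1] <- xyz[, 1] - grid@origin[1]
    xyz[, 2] <- xyz[, 2] - grid@origin[2]
    xyz[, 3] <- xyz[, 3] - grid@origin[3]
    (xyz %*% grid@directions) / rep(grid@spacing, each = nrow(xyz))
}

# all voxel centres of a grid in world coordinates (n x 3, column-major order)
gridWorldCoords <- function(grid) {
    s <- grid@shape
    ijk <- cbind(rep(seq_len(s[1]) - 1, times = s[2] * s[3]),
                 rep(rep(seq_len(s[2]) - 1, each = s[1]), times = s[3]),
                 rep(seq_len(s[3]) - 1, each = s[1] * s[2]))
    voxelToWorld(grid, ijk)
}

# world coordinates of all pixel centres of a frame grid (column-major)
framePixelWorld <- function(grid) {
    s <- grid@shape
    ij <- cbind(rep(seq_len(s[1]) - 1, times = s[2]),
                rep(seq_len(s[2]) - 1, each = s[1]), 0)
    voxelToWorld(grid, ij)
}

#' Sample a 3D volume at world points by trilinear interpolation
#'
#' @param vol 3D numeric array laid out on `grid`.
#' @param grid a [VoxelGrid-class].
#' @param xyz n x 3 matrix of world coordinates, mm.
#' @param outside value returned for points outside the volume (default 0).
#' @return numeric vector of sampled values.
#' @export
sampleVolume <- function(vol, grid, xyz, outside = 0) {
    ijk <- worldToVoxel(grid, xyz)
    tri_interp_cpp(as.numeric(vol), dim(vol), ijk, outside)
}

# block-mean downsampling of a 3D array by integer factor (for pyramids)
downsampleVolume <- function(vol, factor) {
    if (factor <= 1L) return(vol)
    d <- dim(vol)
    nd <- pmax(1L, d %/% factor)
    out <- array(0, nd)
    cnt <- array(0, nd)
    idx <- lapply(1:3, function(a) pmin((seq_len(d[a]) - 1L) %/% factor + 1L,
                                        nd[a]))
    # accumulate via linear indices
    lin <- (rep(idx[[1]], times = d[2] * d[3])) +
        nd[1] * (rep(rep(idx[[2]], each = d[1]), times = d[3]) - 1L) +
        nd[1] * nd[2] * (rep(idx[[3]], each = d[1] * d[2]) - 1L)
    out <- array(bin_accum_cpp(lin, as.numeric(vol), prod(nd)), nd)
    cnt <- array(bin_accum_cpp(lin, rep(1, length(lin)), prod(nd)), nd)
    out / pmax(cnt, 1)
}

# downsampled copy of a grid matching downsampleVolume
downsampleGrid <- function(grid, factor) {
    if (factor <= 1L) return(grid)
    nd <- pmax(1L, grid@shape %/% as.integer(factor))
    sp <- grid@spacing * factor
    # origin moves to the centre of the first block
    off <- grid@directions %*% ((factor - 1) / 2 * grid@spacing)
    VoxelGrid(nd, sp, origin = grid@origin + as.numeric(off),
              directions = grid@directions)
}

# mean absolute in-plane spacing of a frame grid
inPlaneSpacing <- function(grid) mean(grid@spacing[1:2])

# nearest-neighbour fill of zero-weight voxels; returns list(filled, flag)
nnFillVolume <- function(vol, have) {
    d <- dim(vol)
    flag <- !have
    if (!any(flag)) return(list(vol = vol, filled = flag))
    if (!any(have)) stop("entirely empty volume")
    vol[!have] <- 0
    maxit <- sum(d)
    for (it in seq_len(maxit)) {
        if (all(have)) break
        num <- array(0, d); den <- array(0, d)
        for (ax in 1:3) for (s in c(-1L, 1L)) {
            sh <- shiftArray(vol * have, ax, s)
            cn <- shiftArray(array(as.numeric(have), d), ax, s)
            num <- num + sh
            den <- den + cn
        }
        new <- !have & den > 0
        vol[new] <- num[new] / den[new]
        have <- have | new
    }
    list(vol = vol, filled = flag)
}

# shift a 3D array by s along axis ax, zero-filling
shiftArray <- function(x, ax, s) {
    d <- dim(x)
    out <- array(0, d)
    n <- d[ax]
    if (abs(s) >= n) return(out)
    src <- if (s > 0) seq_len(n - s) else seq.int(1 - s, n)
    dst <- if (s > 0) seq.int(1 + s, n) else seq_len(n + s)
    ix <- function(a, i) if (a == ax) i else quote(expr = )
    if (ax == 1) out[dst, , ] <- x[src, , ]
    else if (ax == 2) out[, dst, ] <- x[, src, ]
    else out[, , dst] <- x[, , src]
    out
}
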