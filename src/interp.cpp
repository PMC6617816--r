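#include <Rcpp.h>
using namespace Rcpp;

// Trilinear interpolation of a 3D array (column-major, dims d) at continuous
// 0-based voxel coordinates. Points outside the array return `outside`.
// [[Rcpp::export]]
NumericVector tri_interp_cpp(NumericVector vol, IntegerVector dim,
                             NumericMatrix ijk, double outside) {
    const int d0 = dim[0], d1 = dim[1], d2 = dim[2];
    const int n = ijk.nrow();
    NumericVector out(n);
    const double *v = vol.begin();
    for (int r = 0; r < n; ++r) {
        double x = ijk(r, 0), y = ijk(r, 1), z = ijk(r, 2);
        if (x < 0 || y < 0 || z < 0 ||
            x > d0 - 1 || y > d1 - 1 || z > d2 - 1) {
            out[r] = outside;
            continue;
        }
        int x0 = (int)std::floor(x), y0 = (int)std::floor(y),
            z0 = (int)std::floor(z);
        if (x0 > d0 - 2) x0 = d0 > 1 ? d0 - 2 : 0;
        if (y0 > d1 - 2) y0 = d1 > 1 ? d1 - 2 : 0;
        if (z0 > d2 - 2) z0 = d2 > 1 ? d2 - 2 : 0;
        double fx = x - x0, fy = y - y0, fz = z - z0;
        int x1 = d0 > 1 ? x0 + 1 : x0;
        int y1 = d1 > 1 ? y0 + 1 : y0;
        int z1 = d2 > 1 ? z0 + 1 : z0;
        if (d0 == 1) fx = 0;
        if (d1 == 1) fy = 0;
        if (d2 == 1) fz = 0;
        #define V(i, j, k) v[(i) + d0 * ((j) + d1 * (k))]
        double c00 = V(x0, y0, z0) * (1 - fx) + V(x1, y0, z0) * fx;
        double c10 = V(x0, y1, z0) * (1 - fx) + V(x1, y1, z0) * fx;
        double c01 = V(x0, y0, z1) * (1 - fx) + V(x1, y0, z1) * fx;
        double c11 = V(x0, y1, z1) * (1 - fx) + V(x1, y1, z1) * fx;
        #undef V
        out[r] = ((c00 * (1 - fy) + c10 * fy) * (1 - fz) +
                  (c01 * (1 - fy) + c11 * fy) * fz);
    }
    return out;
}

// Build sparse Gaussian PSF triplets linking frame pixels to volume voxels.
// Q: pixel centres in world coordinates after rigid transformation (npix x 3).
// The volume grid is given by origin/spacing/direction (columns = axes) and
// shape; U holds the world directions of the frame PSF axes (columns:
// in-plane x, in-plane y, slice normal, after rotation), sigma the Gaussian
// SDs (mm) along those axes, trunc the weight cutoff relative to peak and
// boxr the half-width of the candidate voxel box per volume axis.
// [[Rcpp::export]]
List psf_triplets_cpp(NumericMatrix Q, NumericVector gOrigin,
                      NumericVector gSpacing, NumericMatrix gDir,
                      IntegerVector gShape, NumericMatrix U,
                      NumericVector sigma, double trunc, IntegerVector boxr) {
    const int npix = Q.nrow();
    const double e2max = 2.0 * std::log(1.0 / trunc);
    std::vector<int> pi_, vi_;
    std::vector<double> w_;
    pi_.reserve(npix * 8); vi_.reserve(npix * 8); w_.reserve(npix * 8);
    const int d0 = gShape[0], d1 = gShape[1], d2 = gShape[2];
    for (int p = 0; p < npix; ++p) {
        double qx = Q(p, 0), qy = Q(p, 1), qz = Q(p, 2);
        double rx = qx - gOrigin[0], ry = qy - gOrigin[1],
               rz = qz - gOrigin[2];
        // continuous voxel coordinates (0-based)
        double c0 = (gDir(0, 0) * rx + gDir(1, 0) * ry + gDir(2, 0) * rz) /
                    gSpacing[0];
        double c1 = (gDir(0, 1) * rx + gDir(1, 1) * ry + gDir(2, 1) * rz) /
                    gSpacing[1];
        double c2 = (gDir(0, 2) * rx + gDir(1, 2) * ry + gDir(2, 2) * rz) /
                    gSpacing[2];
        int b0 = (int)std::lround(c0), b1 = (int)std::lround(c1),
            b2 = (int)std::lround(c2);
        for (int o2 = -boxr[2]; o2 <= boxr[2]; ++o2) {
            int v2 = b2 + o2;
            if (v2 < 0 || v2 >= d2) continue;
            for (int o1 = -boxr[1]; o1 <= boxr[1]; ++o1) {
                int v1 = b1 + o1;
                if (v1 < 0 || v1 >= d1) continue;
                for (int o0 = -boxr[0]; o0 <= boxr[0]; ++o0) {
                    int v0 = b0 + o0;
                    if (v0 < 0 || v0 >= d0) continue;
                    // world offset voxel centre - transformed pixel centre
                    double s0 = gSpacing[0] * v0, s1 = gSpacing[1] * v1,
                           s2 = gSpacing[2] * v2;
                    double wx = gOrigin[0] + gDir(0, 0) * s0 +
                                gDir(0, 1) * s1 + gDir(0, 2) * s2 - qx;
                    double wy = gOrigin[1] + gDir(1, 0) * s0 +
                                gDir(1, 1) * s1 + gDir(1, 2) * s2 - qy;
                    double wz = gOrigin[2] + gDir(2, 0) * s0 +
                                gDir(2, 1) * s1 + gDir(2, 2) * s2 - qz;
                    // local PSF coordinates
                    double l0 = (U(0, 0) * wx + U(1, 0) * wy + U(2, 0) * wz) /
                                sigma[0];
                    double l1 = (U(0, 1) * wx + U(1, 1) * wy + U(2, 1) * wz) /
                                sigma[1];
                    double l2 = (U(0, 2) * wx + U(1, 2) * wy + U(2, 2) * wz) /
                                sigma[2];
                    double e2 = l0 * l0 + l1 * l1 + l2 * l2;
                    if (e2 > e2max) continue;
                    pi_.push_back(p + 1);
                    vi_.push_back(1 + v0 + d0 * (v1 + d1 * v2));
                    w_.push_back(std::exp(-0.5 * e2));
                }
            }
        }
    }
    return List::create(_["pixel"] = wrap(pi_), _["voxel"] = wrap(vi_),
                        _["w"] = wrap(w_));
}

// Accumulate values into bins: out[idx[r]] += val[r] (idx 1-based).
// [[Rcpp::export]]
NumericVector bin_accum_cpp(IntegerVector idx, NumericVector val, int n) {
    NumericVector out(n);
    for (int r = 0; r < idx.size(); ++r) out[idx[r] - 1] += val[r];
    return out;
}
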