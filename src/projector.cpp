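#include <Rcpp.h>
#include <cmath>
#include <cstddef>
#include <vector>
using namespace Rcpp;

// Rotation-based SPECT projector primitives.
//
// Conventions shared with the R layer:
//  * volumes are nx x ny x nz arrays in R's column-major order
//    (x fastest), world axes (x, y, z), rotation about the z axis
//    through the grid centre;
//  * the camera of a view looks along +y after the volume has been
//    rotated into the camera frame; the detector plane spans (x, z)
//    and every constant-y plane sits at a fixed source-to-collimator
//    distance;
//  * the collimator-detector response of a plane factorizes as
//    K_d = G_d * M, a distance-dependent separable Gaussian convolved
//    with a distance-independent centrosymmetric mixing kernel M
//    (identity centre weight plus the septal-penetration star), so a
//    view needs one cheap separable blur per distance group and a
//    single sparse star application;
//  * forward rotation is the scatter (adjoint) form of bilinear
//    resampling, which conserves counts exactly for interior voxels;
//    backprojection uses the matching gather form.
//
// Forward and backprojection below are exact linear adjoints, which is
// what makes MLEM converge and what the adjointness tests verify.

// [[Rcpp::export(name = ".cpp_rotate_z")]]
NumericVector cpp_rotate_z(NumericVector vol, IntegerVector dim,
                           double angle, bool adjoint) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int nxy = nx * ny;
  NumericVector out(vol.size());
  const double cx = (nx - 1) / 2.0, cy = (ny - 1) / 2.0;
  const double ca = std::cos(angle), sa = std::sin(angle);
  // Precompute the four bilinear taps for every (x, y) position.
  std::vector<int> sidx((size_t)nxy * 4, 0);
  std::vector<double> sw((size_t)nxy * 4, 0.0);
  for (int iy = 0; iy < ny; ++iy) {
    for (int ix = 0; ix < nx; ++ix) {
      const double dx = ix - cx, dy = iy - cy;
      const double sx = ca * dx + sa * dy + cx;
      const double sy = -sa * dx + ca * dy + cy;
      const int x0 = (int)std::floor(sx), y0 = (int)std::floor(sy);
      const double fx = sx - x0, fy = sy - y0;
      const double wts[4] = { (1 - fx) * (1 - fy), fx * (1 - fy),
                              (1 - fx) * fy,       fx * fy };
      const int xs[4] = { x0, x0 + 1, x0,     x0 + 1 };
      const int ys[4] = { y0, y0,     y0 + 1, y0 + 1 };
      const size_t p4 = ((size_t)iy * nx + ix) * 4;
      for (int k = 0; k < 4; ++k) {
        if (wts[k] > 0.0 && xs[k] >= 0 && xs[k] < nx &&
            ys[k] >= 0 && ys[k] < ny) {
          sidx[p4 + k] = xs[k] + nx * ys[k];
          sw[p4 + k] = wts[k];
        }
      }
    }
  }
  const double *in = vol.begin();
  double *o = out.begin();
  for (int iz = 0; iz < nz; ++iz) {
    const double *slin = in + (size_t)iz * nxy;
    double *slout = o + (size_t)iz * nxy;
    if (adjoint) {
      // scatter form: source voxel p deposits at its rotated taps
      for (int p = 0; p < nxy; ++p) {
        const double v = slin[p];
        if (v == 0.0) continue;
        const size_t p4 = (size_t)p * 4;
        slout[sidx[p4]] += sw[p4] * v;
        slout[sidx[p4 + 1]] += sw[p4 + 1] * v;
        slout[sidx[p4 + 2]] += sw[p4 + 2] * v;
        slout[sidx[p4 + 3]] += sw[p4 + 3] * v;
      }
    } else {
      for (int p = 0; p < nxy; ++p) {
        const size_t p4 = (size_t)p * 4;
        slout[p] = sw[p4] * slin[sidx[p4]] +
                   sw[p4 + 1] * slin[sidx[p4 + 1]] +
                   sw[p4 + 2] * slin[sidx[p4 + 2]] +
                   sw[p4 + 3] * slin[sidx[p4 + 3]];
      }
    }
  }
  return out;
}

// Separable 1-D convolutions on an nx x nz plane, zero padded,
// symmetric taps (hence exactly self-adjoint).
static void conv1x(const std::vector<double> &in, std::vector<double> &out,
                   int nx, int nz, const NumericVector &g) {
  const int h = (g.size() - 1) / 2;
  std::fill(out.begin(), out.end(), 0.0);
  for (int a = -h; a <= h; ++a) {
    const double w = g[a + h];
    if (w == 0.0) continue;
    const int x0 = std::max(0, a), x1 = std::min(nx, nx + a);
    for (int iz = 0; iz < nz; ++iz) {
      const double *src = in.data() + (std::ptrdiff_t)nx * iz - a;
      double *dst = out.data() + (std::ptrdiff_t)nx * iz;
      for (int ix = x0; ix < x1; ++ix) dst[ix] += w * src[ix];
    }
  }
}

static void conv1z(const std::vector<double> &in, std::vector<double> &out,
                   int nx, int nz, const NumericVector &g) {
  const int h = (g.size() - 1) / 2;
  std::fill(out.begin(), out.end(), 0.0);
  for (int a = -h; a <= h; ++a) {
    const double w = g[a + h];
    if (w == 0.0) continue;
    const int z0 = std::max(0, a), z1 = std::min(nz, nz + a);
    for (int iz = z0; iz < z1; ++iz) {
      const double *src = in.data() + (std::ptrdiff_t)nx * (iz - a);
      double *dst = out.data() + (std::ptrdiff_t)nx * iz;
      for (int ix = 0; ix < nx; ++ix) dst[ix] += w * src[ix];
    }
  }
}

// Sparse centrosymmetric mixing kernel M: out[u] += sum_k w_k in[u - d_k].
static void apply_star(const std::vector<double> &in,
                       std::vector<double> &out, int nx, int nz,
                       const NumericMatrix &M) {
  std::fill(out.begin(), out.end(), 0.0);
  for (int k = 0; k < M.nrow(); ++k) {
    const int dx = (int)M(k, 0), dz = (int)M(k, 1);
    const double w = M(k, 2);
    const int x0 = std::max(0, dx), x1 = std::min(nx, nx + dx);
    const int z0 = std::max(0, dz), z1 = std::min(nz, nz + dz);
    for (int iz = z0; iz < z1; ++iz) {
      const double *src = in.data() + (std::ptrdiff_t)nx * (iz - dz) - dx;
      double *dst = out.data() + (std::ptrdiff_t)nx * iz;
      for (int ix = x0; ix < x1; ++ix) dst[ix] += w * src[ix];
    }
  }
}

// Forward projection of one rotated, attenuation-weighted volume:
// per-group plane sums -> per-group separable Gaussian -> summed ->
// one star application. group maps each y plane to a Gaussian (1-based
// into glist).
// [[Rcpp::export(name = ".cpp_project_view")]]
NumericMatrix cpp_project_view(NumericVector actw, IntegerVector dim,
                               IntegerVector group, List glist,
                               NumericMatrix star) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int ng = glist.size();
  const size_t sxz = (size_t)nx * nz;
  std::vector< std::vector<double> > gs(ng, std::vector<double>(sxz, 0.0));
  for (int iy = 0; iy < ny; ++iy) {
    std::vector<double> &dst = gs[group[iy] - 1];
    const double *src = actw.begin() + (size_t)nx * iy;
    for (int iz = 0; iz < nz; ++iz) {
      const double *s = src + (size_t)nx * ny * iz;
      double *d = &dst[(size_t)nx * iz];
      for (int ix = 0; ix < nx; ++ix) d[ix] += s[ix];
    }
  }
  std::vector<double> tmp(sxz), acc(sxz, 0.0), res(sxz);
  for (int g = 0; g < ng; ++g) {
    NumericVector taps = glist[g];
    conv1x(gs[g], tmp, nx, nz, taps);
    conv1z(tmp, res, nx, nz, taps);
    for (size_t i = 0; i < sxz; ++i) acc[i] += res[i];
  }
  apply_star(acc, res, nx, nz, star);
  NumericMatrix out(nx, nz);
  std::copy(res.begin(), res.end(), out.begin());
  return out;
}

// Adjoint of cpp_project_view up to the per-plane attenuation
// weighting and plane broadcast, which the R layer applies: returns
// one back-blurred detector image per Gaussian group (nx x nz x ng).
// Order is exactly reversed: star first, then the per-group Gaussians.
// [[Rcpp::export(name = ".cpp_backproject_view")]]
NumericVector cpp_backproject_view(NumericMatrix proj, IntegerVector dim,
                                   List glist, NumericMatrix star) {
  const int nx = dim[0], nz = dim[2];
  const int ng = glist.size();
  const size_t sxz = (size_t)nx * nz;
  std::vector<double> pin(proj.begin(), proj.end());
  std::vector<double> st(sxz), tmp(sxz), res(sxz);
  apply_star(pin, st, nx, nz, star);
  NumericVector out(sxz * ng);
  for (int g = 0; g < ng; ++g) {
    NumericVector taps = glist[g];
    conv1z(st, tmp, nx, nz, taps);
    conv1x(tmp, res, nx, nz, taps);
    std::copy(res.begin(), res.end(), out.begin() + sxz * g);
  }
  out.attr("dim") = IntegerVector::create(nx, nz, ng);
  return out;
}
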