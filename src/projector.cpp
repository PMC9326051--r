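// Rotate-based attenuated parallel-hole projector with depth-dependent
// Gaussian detector response, plus its exactly matched adjoint and a fused
// coefficient-space MLEM iteration.
//
// Geometry: volume (nx, ny, nz) of isotropic voxels (vx mm), centred at the
// origin; the rotation axis is z. For head angle theta (deg) the detector
// face is orthogonal to d = (-sin a, cos a); the transaxial detector axis is
// t = (cos a, sin a); the axial detector axis is z. Detector bins share the
// voxel pitch (bin size == voxel size), with the volume z-range centred in
// the nv axial bins.
//
// The volume is resampled (bilinear, per z-slice) onto a detector-aligned
// grid (nu transaxial x nd depth x nz axial), multiplied by precomputed
// attenuation survival factors and the voxel path length, and accumulated
// from the far side towards the detector through an incremental Gaussian
// cascade: before slice k is added, the accumulator is convolved with the
// variance increment between depth k-1 and k, so that slice k ends up
// carrying the total response variance sig2[k] (intrinsic + geometric).
// The adjoint runs the same linear steps in reverse; because each step is
// either symmetric (blur), diagonal (attenuation) or a transposed bilinear
// splat, <Px, y> == <x, P'y> holds to floating-point precision.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct RotGrid {
  std::vector<int> i0, j0;
  std::vector<double> fx, fy;
};

RotGrid make_grid(double theta_deg, int nx, int ny, int nu, int nd, double vx) {
  RotGrid g;
  g.i0.resize((size_t)nu * nd);
  g.j0.resize((size_t)nu * nd);
  g.fx.resize((size_t)nu * nd);
  g.fy.resize((size_t)nu * nd);
  const double a = theta_deg * M_PI / 180.0;
  const double tx = std::cos(a), ty = std::sin(a);
  const double dx = -std::sin(a), dy = std::cos(a);
  const double cu = 0.5 * (nu - 1), cd = 0.5 * (nd - 1);
  const double cx = 0.5 * (nx - 1), cy = 0.5 * (ny - 1);
  for (int k = 0; k < nd; ++k) {
    const double kc = (k - cd) * vx;
    for (int u = 0; u < nu; ++u) {
      const double uc = (u - cu) * vx;
      const double x = uc * tx + kc * dx;
      const double y = uc * ty + kc * dy;
      const double gx = x / vx + cx, gy = y / vx + cy;
      const int ii = (int)std::floor(gx), jj = (int)std::floor(gy);
      const size_t idx = (size_t)k * nu + u;
      if (ii < 0 || ii >= nx - 1 || jj < 0 || jj >= ny - 1) {
        g.i0[idx] = -1; g.j0[idx] = 0; g.fx[idx] = 0.0; g.fy[idx] = 0.0;
      } else {
        g.i0[idx] = ii; g.j0[idx] = jj;
        g.fx[idx] = gx - ii; g.fy[idx] = gy - jj;
      }
    }
  }
  return g;
}

// 3-tap [a, 1-2a, a] passes along both detector axes realising a given
// blur variance (bin^2, per axis); zero boundary. Skips the axial pass in
// 2D mode (nv == 1). Symmetric, hence self-adjoint.
void blur_var(double* m, int nu, int nv, double var, double* tmp) {
  if (var <= 1e-12) return;
  int npass = (int)std::ceil(var / 0.45);
  if (npass < 1) npass = 1;
  const double aa = var / npass / 2.0;
  for (int p = 0; p < npass; ++p) {
    for (int v = 0; v < nv; ++v) {            // along u
      double* col = m + (size_t)v * nu;
      for (int u = 0; u < nu; ++u) {
        double c = col[u] * (1.0 - 2.0 * aa);
        if (u > 0) c += aa * col[u - 1];
        if (u < nu - 1) c += aa * col[u + 1];
        tmp[u] = c;
      }
      for (int u = 0; u < nu; ++u) col[u] = tmp[u];
    }
    if (nv > 1) {
      for (int u = 0; u < nu; ++u) {          // along v
        for (int v = 0; v < nv; ++v) {
          double c = m[(size_t)v * nu + u] * (1.0 - 2.0 * aa);
          if (v > 0) c += aa * m[(size_t)(v - 1) * nu + u];
          if (v < nv - 1) c += aa * m[(size_t)(v + 1) * nu + u];
          tmp[v] = c;
        }
        for (int v = 0; v < nv; ++v) m[(size_t)v * nu + u] = tmp[v];
      }
    }
  }
}

void fwd_core(const double* V, int nx, int ny, int nz,
              const double* A, const RotGrid& g,
              int nu, int nv, int nd, double vx,
              const double* sig2, bool use_psf, double* acc, double* tmp) {
  const int zoff = (nv - nz) / 2;
  std::fill(acc, acc + (size_t)nu * nv, 0.0);
  bool seen = false;
  for (int k = 0; k < nd; ++k) {
    if (use_psf && k > 0 && seen) blur_var(acc, nu, nv, sig2[k - 1] - sig2[k], tmp);
    for (int z = 0; z < nz; ++z) {
      const int v = z + zoff;
      if (v < 0 || v >= nv) continue;
      double* arow = acc + (size_t)v * nu;
      const double* slab = V + (size_t)nx * ny * z;
      const double* af = A + (size_t)nu * ((size_t)nd * z + k);
      for (int u = 0; u < nu; ++u) {
        const size_t idx = (size_t)k * nu + u;
        const int ii = g.i0[idx];
        if (ii < 0) continue;
        const int jj = g.j0[idx];
        const double fx = g.fx[idx], fy = g.fy[idx];
        const double* s0 = slab + ii + (size_t)nx * jj;
        const double val = (1 - fx) * (1 - fy) * s0[0] + fx * (1 - fy) * s0[1]
                         + (1 - fx) * fy * s0[nx] + fx * fy * s0[nx + 1];
        if (val != 0.0) { arow[u] += val * af[u] * vx; seen = true; }
      }
    }
  }
  if (use_psf) blur_var(acc, nu, nv, sig2[nd - 1], tmp);
}

// Adjoint; accumulates w * (P' proj) into outvol. gbuf/tmp are work arrays.
void adj_core(const double* proj, int nx, int ny, int nz,
              const double* A, const RotGrid& g,
              int nu, int nv, int nd, double vx,
              const double* sig2, bool use_psf,
              double* outvol, double w, double* gbuf, double* tmp) {
  const int zoff = (nv - nz) / 2;
  std::copy(proj, proj + (size_t)nu * nv, gbuf);
  if (use_psf) blur_var(gbuf, nu, nv, sig2[nd - 1], tmp);
  for (int k = nd - 1; k >= 0; --k) {
    for (int z = 0; z < nz; ++z) {
      const int v = z + zoff;
      if (v < 0 || v >= nv) continue;
      const double* grow = gbuf + (size_t)v * nu;
      double* oslab = outvol + (size_t)nx * ny * z;
      const double* af = A + (size_t)nu * ((size_t)nd * z + k);
      for (int u = 0; u < nu; ++u) {
        const size_t idx = (size_t)k * nu + u;
        const int ii = g.i0[idx];
        if (ii < 0) continue;
        const int jj = g.j0[idx];
        const double fx = g.fx[idx], fy = g.fy[idx];
        const double val = w * grow[u] * af[u] * vx;
        if (val == 0.0) continue;
        double* o0 = oslab + ii + (size_t)nx * jj;
        o0[0]      += (1 - fx) * (1 - fy) * val;
        o0[1]      += fx * (1 - fy) * val;
        o0[nx]     += (1 - fx) * fy * val;
        o0[nx + 1] += fx * fy * val;
      }
    }
    if (use_psf && k > 0) blur_var(gbuf, nu, nv, sig2[k - 1] - sig2[k], tmp);
  }
}

inline int fold_idx(int i, int n) {
  if (i < 0) i = -i - 1;
  if (i >= n) i = 2 * n - 1 - i;
  return i;
}

}  // namespace

// Attenuation survival factor exp(-integral of mu from the voxel to the
// collimator face) sampled on the detector-aligned grid (nu, nd, nz).
// mu is in 1/cm; voxel pitch vx in mm. Depth index k increases towards the
// detector; the factor at k includes half of slice k's own attenuation.
// [[Rcpp::export]]
NumericVector cpp_att_factors(NumericVector mu, IntegerVector dims,
                              double theta_deg, int nu, int nd, double vx) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  RotGrid g = make_grid(theta_deg, nx, ny, nu, nd, vx);
  NumericVector out((R_xlen_t)nu * nd * nz);
  const double vxcm = vx / 10.0;
  const double* M = mu.begin();
  for (int z = 0; z < nz; ++z) {
    const double* slab = M + (size_t)nx * ny * z;
    for (int u = 0; u < nu; ++u) {
      double running = 0.0;
      for (int k = nd - 1; k >= 0; --k) {
        const size_t idx = (size_t)k * nu + u;
        double m = 0.0;
        const int ii = g.i0[idx];
        if (ii >= 0) {
          const int jj = g.j0[idx];
          const double fx = g.fx[idx], fy = g.fy[idx];
          const double* s0 = slab + ii + (size_t)nx * jj;
          m = (1 - fx) * (1 - fy) * s0[0] + fx * (1 - fy) * s0[1]
            + (1 - fx) * fy * s0[nx] + fx * fy * s0[nx + 1];
        }
        out[(size_t)nu * ((size_t)nd * z + k) + u] =
            std::exp(-vxcm * (running + 0.5 * m));
        running += m;
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_forward(NumericVector vol, IntegerVector dims,
                          NumericVector attf, double theta_deg,
                          int nu, int nv, int nd, double vx,
                          NumericVector sig2, bool use_psf) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  RotGrid g = make_grid(theta_deg, nx, ny, nu, nd, vx);
  NumericMatrix out(nu, nv);
  std::vector<double> tmp(std::max(nu, nv));
  fwd_core(vol.begin(), nx, ny, nz, attf.begin(), g, nu, nv, nd, vx,
           sig2.begin(), use_psf, out.begin(), tmp.data());
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_adjoint(NumericMatrix proj, IntegerVector dims,
                          NumericVector attf, double theta_deg,
                          int nu, int nv, int nd, double vx,
                          NumericVector sig2, bool use_psf) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  RotGrid g = make_grid(theta_deg, nx, ny, nu, nd, vx);
  NumericVector out((R_xlen_t)nx * ny * nz);
  std::vector<double> gbuf((size_t)nu * nv), tmp(std::max(nu, nv));
  adj_core(proj.begin(), nx, ny, nz, attf.begin(), g, nu, nv, nd, vx,
           sig2.begin(), use_psf, out.begin(), 1.0, gbuf.data(), tmp.data());
  return out;
}

// One fused EM pass over a gate's frames: accumulates the per-basis
// numerator sum_j V_nj P'_j(y_j / ybar_j) into `num` (zeroed here) and
// returns the Poisson log-likelihood sum_j sum_i (y log ybar - ybar).
// a_coef: nvox x nb; y: (nu*nv) x nj; Vmat: nj x nb; ai: 1-based index of
// each frame's angle into attfs/angles; scale multiplies the projector
// (sensitivity_scale * dt).
// [[Rcpp::export]]
double cpp_mlem_pass(NumericMatrix a_coef, NumericMatrix num,
                     NumericMatrix y, NumericMatrix Vmat,
                     IntegerVector ai, List attfs, NumericVector angles,
                     IntegerVector dims, int nu, int nv, int nd, double vx,
                     NumericVector sig2, bool use_psf, double scale,
                     double eps) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  const int nb = a_coef.ncol();
  const int nj = Vmat.nrow();
  const size_t nbin = (size_t)nu * nv;

  const int na = angles.size();
  std::vector<RotGrid> grids(na);
  for (int a = 0; a < na; ++a) {
    grids[a] = make_grid(angles[a], nx, ny, nu, nd, vx);
  }
  std::vector<const double*> afp(na);
  for (int a = 0; a < na; ++a) {
    afp[a] = NumericVector(attfs[a]).begin();  // no copy: SEXP-backed
  }

  std::fill(num.begin(), num.end(), 0.0);
  std::vector<double> xj(nvox), proj(nbin), gbuf(nbin), ratio(nbin),
      tmp(std::max(nu, nv)), bp(nvox);
  double ll = 0.0;

  for (int j = 0; j < nj; ++j) {
    // xj = sum_n V_jn a_.n (only the non-zero bases matter)
    std::fill(xj.begin(), xj.end(), 0.0);
    for (int n = 0; n < nb; ++n) {
      const double w = Vmat(j, n);
      if (w == 0.0) continue;
      const double* col = &a_coef(0, n);
      for (R_xlen_t i = 0; i < nvox; ++i) xj[i] += w * col[i];
    }
    const int a = ai[j] - 1;
    fwd_core(xj.data(), nx, ny, nz, afp[a], grids[a], nu, nv, nd, vx,
             sig2.begin(), use_psf, proj.data(), tmp.data());
    const double* yj = &y(0, j);
    for (size_t i = 0; i < nbin; ++i) {
      const double yb = proj[i] * scale;
      ll += yj[i] * std::log(yb + eps) - yb;
      ratio[i] = yj[i] / (yb + eps);
    }
    std::fill(bp.begin(), bp.end(), 0.0);
    adj_core(ratio.data(), nx, ny, nz, afp[a], grids[a], nu, nv, nd, vx,
             sig2.begin(), use_psf, bp.data(), scale, gbuf.data(),
             tmp.data());
    for (int n = 0; n < nb; ++n) {
      const double w = Vmat(j, n);
      if (w == 0.0) continue;
      double* col = &num(0, n);
      for (R_xlen_t i = 0; i < nvox; ++i) col[i] += w * bp[i];
    }
  }
  return ll;
}

// Mass-conserving separable Gaussian blur (scatter form: each source bin
// distributes a normalised kernel, with out-of-range taps folded back by
// mirror reflection, so column sums are exactly 1).
// [[Rcpp::export]]
NumericMatrix cpp_blur2d(NumericMatrix m, NumericVector kern) {
  const int n1 = m.nrow(), n2 = m.ncol(), kl = kern.size(), h = kl / 2;
  NumericMatrix t1(n1, n2);
  for (int j = 0; j < n2; ++j)
    for (int i = 0; i < n1; ++i) {
      const double s = m(i, j);
      if (s == 0.0) continue;
      for (int t = 0; t < kl; ++t) t1(fold_idx(i + t - h, n1), j) += kern[t] * s;
    }
  NumericMatrix t2(n1, n2);
  for (int j = 0; j < n2; ++j)
    for (int i = 0; i < n1; ++i) {
      const double s = t1(i, j);
      if (s == 0.0) continue;
      for (int t = 0; t < kl; ++t) t2(i, fold_idx(j + t - h, n2)) += kern[t] * s;
    }
  return t2;
}

// Same, for a 3D volume along all three axes.
// [[Rcpp::export]]
NumericVector cpp_blur3d(NumericVector vol, IntegerVector dims,
                         NumericVector kern) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int kl = kern.size(), h = kl / 2;
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<double> a(vol.begin(), vol.end()), b(n, 0.0);
  // x axis
  for (R_xlen_t p = 0; p < n; ++p) {
    const double s = a[p];
    if (s == 0.0) continue;
    const int i = p % nx;
    const R_xlen_t base = p - i;
    for (int t = 0; t < kl; ++t) b[base + fold_idx(i + t - h, nx)] += kern[t] * s;
  }
  std::fill(a.begin(), a.end(), 0.0);
  // y axis
  for (R_xlen_t p = 0; p < n; ++p) {
    const double s = b[p];
    if (s == 0.0) continue;
    const int j = (p / nx) % ny;
    const R_xlen_t base = p - (R_xlen_t)j * nx;
    for (int t = 0; t < kl; ++t) a[base + (R_xlen_t)fold_idx(j + t - h, ny) * nx] += kern[t] * s;
  }
  std::fill(b.begin(), b.end(), 0.0);
  // z axis
  const R_xlen_t sz = (R_xlen_t)nx * ny;
  for (R_xlen_t p = 0; p < n; ++p) {
    const double s = a[p];
    if (s == 0.0) continue;
    const int kz = p / sz;
    const R_xlen_t base = p - (R_xlen_t)kz * sz;
    for (int t = 0; t < kl; ++t) b[base + (R_xlen_t)fold_idx(kz + t - h, nz) * sz] += kern[t] * s;
  }
  NumericVector out(n);
  std::copy(b.begin(), b.end(), out.begin());
  return out;
}

// Dense in-place column update used for the EM denominator.
// [[Rcpp::export]]
void cpp_axpy_cols(NumericMatrix num, NumericVector bp, IntegerVector cols,
                   NumericVector w) {
  const R_xlen_t nr = num.nrow();
  for (int j = 0; j < cols.size(); ++j) {
    double* col = &num(0, cols[j] - 1);
    const double wj = w[j];
    if (wj == 0.0) continue;
    for (R_xlen_t i = 0; i < nr; ++i) col[i] += wj * bp[i];
  }
}
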