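#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Siddon-style exact intersection-length traversal of one ray through an
// n x n pixel grid of pitch `px` (mm), centred on the isocenter.
// Image layout matches an R matrix: element (r, c) at index (c * n + r),
// world coords x = (c + 0.5 - n/2) * px, y = (r + 0.5 - n/2) * px.
// forward: accumulate sum(img * length); adjoint: scatter val * length.
static double trace_ray(double* img, int n, double px,
                        double sx, double sy, double ex, double ey,
                        bool forward, double val) {
  const double x0 = -0.5 * n * px;
  const double y0 = -0.5 * n * px;
  const double dx = ex - sx, dy = ey - sy;
  const double L = std::sqrt(dx * dx + dy * dy);
  if (L <= 0.0) return 0.0;

  double amin = 0.0, amax = 1.0;
  if (std::fabs(dx) < 1e-12) {
    if (sx <= x0 || sx >= x0 + n * px) return 0.0;
  } else {
    double a1 = (x0 - sx) / dx, a2 = (x0 + n * px - sx) / dx;
    amin = std::max(amin, std::min(a1, a2));
    amax = std::min(amax, std::max(a1, a2));
  }
  if (std::fabs(dy) < 1e-12) {
    if (sy <= y0 || sy >= y0 + n * px) return 0.0;
  } else {
    double a1 = (y0 - sy) / dy, a2 = (y0 + n * px - sy) / dy;
    amin = std::max(amin, std::min(a1, a2));
    amax = std::min(amax, std::max(a1, a2));
  }
  if (amin >= amax) return 0.0;

  // incremental traversal: entry cell, per-axis crossing alphas and steps
  const double nudge = (amax - amin) * 1e-9;
  int ic = (int)std::floor((sx + (amin + nudge) * dx - x0) / px);
  int ir = (int)std::floor((sy + (amin + nudge) * dy - y0) / px);
  double ax = R_PosInf, ay = R_PosInf, dax = R_PosInf, day = R_PosInf;
  int stepc = 0, stepr = 0;
  if (std::fabs(dx) > 1e-12) {
    dax = px / std::fabs(dx);
    stepc = dx > 0 ? 1 : -1;
    const int plane = dx > 0 ? ic + 1 : ic;
    ax = (x0 + plane * px - sx) / dx;
  }
  if (std::fabs(dy) > 1e-12) {
    day = px / std::fabs(dy);
    stepr = dy > 0 ? 1 : -1;
    const int plane = dy > 0 ? ir + 1 : ir;
    ay = (y0 + plane * px - sy) / dy;
  }
  double acc = 0.0;
  double acur = amin;
  int guard = 0;
  const int guard_max = 4 * n + 8;
  while (acur < amax - 1e-12 && guard++ < guard_max) {
    const double anext = std::min(std::min(ax, ay), amax);
    if (anext > acur && ic >= 0 && ic < n && ir >= 0 && ir < n) {
      const double len = (anext - acur) * L;
      if (forward) acc += img[(size_t)ic * n + ir] * len;
      else img[(size_t)ic * n + ir] += val * len;
    }
    if (anext >= amax) break;
    if (ax <= anext + 1e-14) { ic += stepc; ax += dax; }
    if (ay <= anext + 1e-14) { ir += stepr; ay += day; }
    acur = anext;
  }
  return acc;
}

// endpoints of the ray for view angle `beta` (radians) and detector index k
static inline void ray_endpoints(bool fan, double beta, int k, int ndet,
                                 double pitch, double sad, double sdd,
                                 double halfspan,
                                 double& sx, double& sy, double& ex, double& ey) {
  const double cb = std::cos(beta), sb = std::sin(beta);
  const double u = (k - 0.5 * (ndet - 1)) * pitch;
  if (fan) {
    sx = sad * cb;            sy = sad * sb;
    const double ddx = -(sdd - sad) * cb, ddy = -(sdd - sad) * sb;
    ex = ddx - u * sb;        ey = ddy + u * cb;
  } else {
    // parallel ray through u * e_u, direction -(cos b, sin b); pitch at isocenter
    const double pxu = -u * sb, pyu = u * cb;
    sx = pxu + halfspan * cb; sy = pyu + halfspan * sb;
    ex = pxu - halfspan * cb; ey = pyu - halfspan * sb;
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_forward_project(NumericMatrix img, NumericVector angles_deg,
                                  int ndet, double pitch, double px,
                                  double sad, double sdd, bool fan) {
  const int n = img.nrow();
  if (img.ncol() != n) stop("image slice must be square");
  const int na = angles_deg.size();
  NumericMatrix out(na, ndet);
  const double halfspan = 1.5 * n * px;
  for (int a = 0; a < na; ++a) {
    const double beta = angles_deg[a] * M_PI / 180.0;
    for (int k = 0; k < ndet; ++k) {
      double sx, sy, ex, ey;
      ray_endpoints(fan, beta, k, ndet, pitch, sad, sdd, halfspan, sx, sy, ex, ey);
      out(a, k) = trace_ray(REAL(img), n, px, sx, sy, ex, ey, true, 0.0);
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_back_project(NumericMatrix sino, NumericVector angles_deg,
                               int n, double pitch, double px,
                               double sad, double sdd, bool fan) {
  const int na = angles_deg.size();
  const int ndet = sino.ncol();
  if (sino.nrow() != na) stop("sinogram rows must match angle count");
  NumericMatrix out(n, n);
  const double halfspan = 1.5 * n * px;
  for (int a = 0; a < na; ++a) {
    const double beta = angles_deg[a] * M_PI / 180.0;
    for (int k = 0; k < ndet; ++k) {
      const double v = sino(a, k);
      if (v == 0.0) continue;
      double sx, sy, ex, ey;
      ray_endpoints(fan, beta, k, ndet, pitch, sad, sdd, halfspan, sx, sy, ex, ey);
      trace_ray(REAL(out), n, px, sx, sy, ex, ey, false, v);
    }
  }
  return out;
}

// distance-weighted fan-beam backprojection of ramp-filtered data onto the
// n x n grid; `filt` is (n_angles x ndet) on the virtual detector at the
// isocenter with sample spacing `du` (mm).  Linear interpolation in u.
// [[Rcpp::export]]
NumericMatrix cpp_fbp_backproject(NumericMatrix filt, NumericVector angles_deg,
                                  int n, double du, double px,
                                  double sad, bool fan) {
  const int na = angles_deg.size();
  const int ndet = filt.ncol();
  NumericMatrix out(n, n);
  const double uc = 0.5 * (ndet - 1);
  for (int a = 0; a < na; ++a) {
    const double beta = angles_deg[a] * M_PI / 180.0;
    const double cb = std::cos(beta), sb = std::sin(beta);
    for (int c = 0; c < n; ++c) {
      const double x = (c + 0.5 - 0.5 * n) * px;
      for (int r = 0; r < n; ++r) {
        const double y = (r + 0.5 - 0.5 * n) * px;
        double u, w;
        if (fan) {
          const double d = sad - (x * cb + y * sb);   // source distance along axis
          if (d <= 1e-6) continue;
          u = sad * (-x * sb + y * cb) / d;
          const double U = d / sad;
          w = 1.0 / (U * U);
        } else {
          u = -x * sb + y * cb;
          w = 1.0;
        }
        const double fu = u / du + uc;
        const int k0 = (int)std::floor(fu);
        if (k0 < 0 || k0 >= ndet - 1) continue;
        const double frac = fu - k0;
        const double val = (1.0 - frac) * filt(a, k0) + frac * filt(a, k0 + 1);
        out(r, c) += w * val;
      }
    }
  }
  return out;
}
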