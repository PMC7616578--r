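// Slice acquisition forward model and its adjoint.
//
// A slice sample is a Gaussian-PSF-weighted average of the volume, evaluated
// at quadrature points around the (rigidly transformed) sample position.
// All coordinates arriving here are 0-based voxel coordinates of the volume;
// the R side composes world-space rigid transforms, PSF axes and quadrature
// into per-slice affine maps (base + i*step1 + j*step2) and per-slice
// quadrature offsets, so the inner loop is pure trilinear gather/scatter.

#include <Rcpp.h>
using namespace Rcpp;

static inline bool corners(const int* d, double x, double y, double z,
                           int& x0, int& y0, int& z0,
                           double& fx, double& fy, double& fz) {
  if (!(x >= 0.0 && y >= 0.0 && z >= 0.0 &&
        x <= d[0] - 1.0 && y <= d[1] - 1.0 && z <= d[2] - 1.0))
    return false;
  x0 = (int)std::floor(x); y0 = (int)std::floor(y); z0 = (int)std::floor(z);
  if (x0 > d[0] - 2) x0 = d[0] >= 2 ? d[0] - 2 : 0;
  if (y0 > d[1] - 2) y0 = d[1] >= 2 ? d[1] - 2 : 0;
  if (z0 > d[2] - 2) z0 = d[2] >= 2 ? d[2] - 2 : 0;
  fx = x - x0; fy = y - y0; fz = z - z0;
  if (d[0] == 1) fx = 0.0;
  if (d[1] == 1) fy = 0.0;
  if (d[2] == 1) fz = 0.0;
  return true;
}

static inline double gather(const double* v, const int* d,
                            double x, double y, double z, bool& ok) {
  int x0, y0, z0; double fx, fy, fz;
  ok = corners(d, x, y, z, x0, y0, z0, fx, fy, fz);
  if (!ok) return 0.0;
  const int sx = 1, sy = d[0], sz = d[0] * d[1];
  const double* p = v + x0 * sx + y0 * sy + z0 * sz;
  const int dx = d[0] >= 2 ? sx : 0;
  const int dy = d[1] >= 2 ? sy : 0;
  const int dz = d[2] >= 2 ? sz : 0;
  double c00 = p[0] * (1 - fx) + p[dx] * fx;
  double c10 = p[dy] * (1 - fx) + p[dx + dy] * fx;
  double c01 = p[dz] * (1 - fx) + p[dx + dz] * fx;
  double c11 = p[dy + dz] * (1 - fx) + p[dx + dy + dz] * fx;
  double c0 = c00 * (1 - fy) + c10 * fy;
  double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

static inline void scatter(double* v, const int* d,
                           double x, double y, double z, double w, bool& ok) {
  int x0, y0, z0; double fx, fy, fz;
  ok = corners(d, x, y, z, x0, y0, z0, fx, fy, fz);
  if (!ok) return;
  const int sy = d[0], sz = d[0] * d[1];
  double* p = v + x0 + y0 * sy + z0 * sz;
  const int dx = d[0] >= 2 ? 1 : 0;
  const int dy = d[1] >= 2 ? sy : 0;
  const int dz = d[2] >= 2 ? sz : 0;
  p[0]            += w * (1 - fx) * (1 - fy) * (1 - fz);
  p[dx]           += w * fx       * (1 - fy) * (1 - fz);
  p[dy]           += w * (1 - fx) * fy       * (1 - fz);
  p[dx + dy]      += w * fx       * fy       * (1 - fz);
  p[dz]           += w * (1 - fx) * (1 - fy) * fz;
  p[dx + dz]      += w * fx       * (1 - fy) * fz;
  p[dy + dz]      += w * (1 - fx) * fy       * fz;
  p[dx + dy + dz] += w * fx       * fy       * fz;
}

// Simulate all slices of a set: out(s, p) with p = j*nx + i.
// base/step1/step2: S x 3 voxel-space affine pieces per slice.
// quadvox: S x (3*Q), quadrature offsets in voxel space per slice.
// qw: Q quadrature weights summing to 1.
// defvox: optional (S*nx*ny) x 3 per-sample voxel-space offsets.
// Samples with less than half the quadrature mass in-support are NA.
// [[Rcpp::export]]
NumericMatrix cpp_psf_forward(NumericVector vol, IntegerVector dim,
                              NumericMatrix base, NumericMatrix step1,
                              NumericMatrix step2, NumericMatrix quadvox,
                              NumericVector qw, int nx, int ny,
                              Nullable<NumericMatrix> defvox) {
  const int S = base.nrow(), Q = qw.size(), P = nx * ny;
  const double* v = REAL(vol);
  const int d[3] = { dim[0], dim[1], dim[2] };
  NumericMatrix out(S, P);
  const bool hasdef = defvox.isNotNull();
  NumericMatrix dv = hasdef ? NumericMatrix(defvox) : NumericMatrix(0, 0);
  for (int s = 0; s < S; ++s) {
    const double bx = base(s, 0), by = base(s, 1), bz = base(s, 2);
    const double s1x = step1(s, 0), s1y = step1(s, 1), s1z = step1(s, 2);
    const double s2x = step2(s, 0), s2y = step2(s, 1), s2z = step2(s, 2);
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) {
        const int p = j * nx + i;
        double cx = bx + i * s1x + j * s2x;
        double cy = by + i * s1y + j * s2y;
        double cz = bz + i * s1z + j * s2z;
        if (hasdef) {
          const int r = s * P + p;
          cx += dv(r, 0); cy += dv(r, 1); cz += dv(r, 2);
        }
        double acc = 0.0, wsum = 0.0;
        for (int q = 0; q < Q; ++q) {
          bool ok;
          double val = gather(v, d, cx + quadvox(s, 3 * q),
                              cy + quadvox(s, 3 * q + 1),
                              cz + quadvox(s, 3 * q + 2), ok);
          if (ok) { acc += qw[q] * val; wsum += qw[q]; }
        }
        out(s, p) = (wsum >= 0.5) ? acc / wsum : NA_REAL;
      }
    }
  }
  return out;
}

// Adjoint of cpp_psf_forward (with optional per-sample weights):
// num = A' W val, den = A' W 1. NA values or zero weights are skipped.
// [[Rcpp::export]]
List cpp_psf_adjoint(NumericMatrix val, Nullable<NumericMatrix> wt,
                     IntegerVector dim, NumericMatrix base,
                     NumericMatrix step1, NumericMatrix step2,
                     NumericMatrix quadvox, NumericVector qw,
                     int nx, int ny, Nullable<NumericMatrix> defvox,
                     bool want_den) {
  const int S = base.nrow(), Q = qw.size(), P = nx * ny;
  const int d[3] = { dim[0], dim[1], dim[2] };
  const int nvox = d[0] * d[1] * d[2];
  NumericVector num(nvox), den(nvox);
  const bool hasw = wt.isNotNull();
  NumericMatrix wm = hasw ? NumericMatrix(wt) : NumericMatrix(0, 0);
  const bool hasdef = defvox.isNotNull();
  NumericMatrix dv = hasdef ? NumericMatrix(defvox) : NumericMatrix(0, 0);
  std::vector<double> qx(Q), qy(Q), qz(Q);
  for (int s = 0; s < S; ++s) {
    for (int q = 0; q < Q; ++q) {
      qx[q] = quadvox(s, 3 * q);
      qy[q] = quadvox(s, 3 * q + 1);
      qz[q] = quadvox(s, 3 * q + 2);
    }
    const double bx = base(s, 0), by = base(s, 1), bz = base(s, 2);
    const double s1x = step1(s, 0), s1y = step1(s, 1), s1z = step1(s, 2);
    const double s2x = step2(s, 0), s2y = step2(s, 1), s2z = step2(s, 2);
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) {
        const int p = j * nx + i;
        const double x = val(s, p);
        if (ISNAN(x)) continue;
        const double w0 = hasw ? wm(s, p) : 1.0;
        if (!(w0 > 0.0)) continue;
        double cx = bx + i * s1x + j * s2x;
        double cy = by + i * s1y + j * s2y;
        double cz = bz + i * s1z + j * s2z;
        if (hasdef) {
          const int r = s * P + p;
          cx += dv(r, 0); cy += dv(r, 1); cz += dv(r, 2);
        }
        // pass 1: in-support quadrature mass (must match forward)
        double wsum = 0.0;
        for (int q = 0; q < Q; ++q) {
          int x0, y0, z0; double fx, fy, fz;
          if (corners(d, cx + qx[q], cy + qy[q], cz + qz[q],
                      x0, y0, z0, fx, fy, fz))
            wsum += qw[q];
        }
        if (wsum < 0.5) continue;
        for (int q = 0; q < Q; ++q) {
          bool ok;
          const double w = w0 * qw[q] / wsum;
          scatter(REAL(num), d, cx + qx[q], cy + qy[q], cz + qz[q], w * x, ok);
          if (ok && want_den)
            scatter(REAL(den), d, cx + qx[q], cy + qy[q], cz + qz[q], w, ok);
        }
      }
    }
  }
  IntegerVector dd = IntegerVector::create(d[0], d[1], d[2]);
  num.attr("dim") = dd;
  den.attr("dim") = dd;
  return List::create(Named("num") = num, Named("den") = den);
}

// Generic interpolation of a volume at arbitrary voxel coordinates.
// pts: N x 3 0-based voxel coordinates; NA outside the support.
// [[Rcpp::export]]
NumericVector cpp_gather(NumericVector vol, IntegerVector dim,
                         NumericMatrix pts, bool nearest) {
  const int N = pts.nrow();
  const int d[3] = { dim[0], dim[1], dim[2] };
  const double* v = REAL(vol);
  NumericVector out(N);
  for (int n = 0; n < N; ++n) {
    const double x = pts(n, 0), y = pts(n, 1), z = pts(n, 2);
    if (nearest) {
      const double xr = std::round(x), yr = std::round(y), zr = std::round(z);
      if (xr < 0 || yr < 0 || zr < 0 ||
          xr > d[0] - 1 || yr > d[1] - 1 || zr > d[2] - 1) {
        out[n] = NA_REAL;
      } else {
        out[n] = v[(int)xr + (int)yr * d[0] + (int)zr * d[0] * d[1]];
      }
    } else {
      bool ok;
      const double val = gather(v, d, x, y, z, ok);
      out[n] = ok ? val : NA_REAL;
    }
  }
  return out;
}
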