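// Low-level image filtering: separable 1D convolution along a stack axis and
// per-voxel symmetric 3x3 Hessian eigen-decomposition (analytic, with LAPACK
// fallback for degenerate voxels).

#include <RcppArmadillo.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// correlation of one contiguous line with an odd-length kernel, replicate
// boundary; interior handled without clamping so the loop vectorizes
static void conv_line_contig(const double* in, double* out, int len,
                             const double* ker, int half) {
  const int lo = half < len ? half : len;
  const int hi = len - half > lo ? len - half : lo;
  for (int t = 0; t < lo; ++t) {
    double acc = 0.0;
    for (int s = -half; s <= half; ++s)
      acc += ker[s + half] * in[clampi(t + s, 0, len - 1)];
    out[t] = acc;
  }
  for (int t = lo; t < hi; ++t) {
    double acc = 0.0;
    const double* p = in + t - half;
    for (int s = 0; s < 2 * half + 1; ++s) acc += ker[s] * p[s];
    out[t] = acc;
  }
  for (int t = hi; t < len; ++t) {
    double acc = 0.0;
    for (int s = -half; s <= half; ++s)
      acc += ker[s + half] * in[clampi(t + s, 0, len - 1)];
    out[t] = acc;
  }
}

// [[Rcpp::export]]
NumericVector conv_axis_cpp(NumericVector arr, IntegerVector dims,
                            NumericVector kernel, int axis) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int nk = kernel.size();
  if (nk % 2 == 0) stop("kernel length must be odd");
  const int half = nk / 2;
  std::vector<double> ker(kernel.begin(), kernel.end());
  NumericVector out(arr.size());
  out.attr("dim") = dims;
  const double* pin = arr.begin();
  double* pout = out.begin();
  const size_t plane = (size_t)nx * ny;

  if (axis == 1) {
    const size_t nlines = (size_t)ny * nz;
    for (size_t l = 0; l < nlines; ++l)
      conv_line_contig(pin + l * nx, pout + l * nx, nx, ker.data(), half);
  } else if (axis == 2) {
    // accumulate whole x rows: contiguous in both source and destination
    for (int k = 0; k < nz; ++k) {
      const double* slab = pin + (size_t)k * plane;
      double* oslab = pout + (size_t)k * plane;
      for (int j = 0; j < ny; ++j) {
        double* orow = oslab + (size_t)j * nx;
        for (int s = -half; s <= half; ++s) {
          const double w = ker[s + half];
          const double* irow = slab + (size_t)clampi(j + s, 0, ny - 1) * nx;
          if (s == -half) for (int i = 0; i < nx; ++i) orow[i] = w * irow[i];
          else            for (int i = 0; i < nx; ++i) orow[i] += w * irow[i];
        }
      }
    }
  } else if (axis == 3) {
    // accumulate whole xy planes
    for (int k = 0; k < nz; ++k) {
      double* oplane = pout + (size_t)k * plane;
      for (int s = -half; s <= half; ++s) {
        const double w = ker[s + half];
        const double* iplane = pin + (size_t)clampi(k + s, 0, nz - 1) * plane;
        if (s == -half) for (size_t i = 0; i < plane; ++i) oplane[i] = w * iplane[i];
        else            for (size_t i = 0; i < plane; ++i) oplane[i] += w * iplane[i];
      }
    }
  } else stop("axis must be 1, 2 or 3");
  return out;
}

// analytic eigenvalues of a symmetric 3x3 matrix (trigonometric method)
static inline void eig3_values(double a11, double a22, double a33,
                               double a12, double a13, double a23,
                               double* ev) {
  double p1 = a12 * a12 + a13 * a13 + a23 * a23;
  if (p1 == 0.0) { ev[0] = a11; ev[1] = a22; ev[2] = a33; return; }
  double q = (a11 + a22 + a33) / 3.0;
  double b11 = a11 - q, b22 = a22 - q, b33 = a33 - q;
  double p2 = b11 * b11 + b22 * b22 + b33 * b33 + 2.0 * p1;
  double p = std::sqrt(p2 / 6.0);
  // det(B)/2 with B = (A - qI)/p
  double c11 = b11 / p, c22 = b22 / p, c33 = b33 / p;
  double c12 = a12 / p, c13 = a13 / p, c23 = a23 / p;
  double detB = c11 * (c22 * c33 - c23 * c23)
              - c12 * (c12 * c33 - c23 * c13)
              + c13 * (c12 * c23 - c22 * c13);
  double r = detB / 2.0;
  if (r < -1.0) r = -1.0; else if (r > 1.0) r = 1.0;
  double phi = std::acos(r) / 3.0;
  double e1 = q + 2.0 * p * std::cos(phi);
  double e3 = q + 2.0 * p * std::cos(phi + 2.0 * M_PI / 3.0);
  ev[0] = e1; ev[1] = 3.0 * q - e1 - e3; ev[2] = e3;
}

static inline void cross3(const double* a, const double* b, double* c) {
  c[0] = a[1] * b[2] - a[2] * b[1];
  c[1] = a[2] * b[0] - a[0] * b[2];
  c[2] = a[0] * b[1] - a[1] * b[0];
}

// eigenvector of symmetric A for eigenvalue lam via cross products of rows
// of (A - lam I); returns false when degenerate
static bool eig3_vector(double a11, double a22, double a33,
                        double a12, double a13, double a23,
                        double lam, double* v) {
  double r1[3] = {a11 - lam, a12, a13};
  double r2[3] = {a12, a22 - lam, a23};
  double r3[3] = {a13, a23, a33 - lam};
  double c1[3], c2[3], c3[3];
  cross3(r1, r2, c1); cross3(r1, r3, c2); cross3(r2, r3, c3);
  double n1 = c1[0]*c1[0]+c1[1]*c1[1]+c1[2]*c1[2];
  double n2 = c2[0]*c2[0]+c2[1]*c2[1]+c2[2]*c2[2];
  double n3 = c3[0]*c3[0]+c3[1]*c3[1]+c3[2]*c3[2];
  double* best = c1; double nb = n1;
  if (n2 > nb) { best = c2; nb = n2; }
  if (n3 > nb) { best = c3; nb = n3; }
  double scale = a11*a11 + a22*a22 + a33*a33 +
                 2.0*(a12*a12 + a13*a13 + a23*a23) + 1e-300;
  if (nb <= 1e-24 * scale * scale) return false;
  double inv = 1.0 / std::sqrt(nb);
  v[0] = best[0] * inv; v[1] = best[1] * inv; v[2] = best[2] * inv;
  return true;
}

static inline void fix_sign(double* v) {
  for (int c = 0; c < 3; ++c) {
    if (std::fabs(v[c]) > 1e-12) {
      if (v[c] < 0) { v[0] = -v[0]; v[1] = -v[1]; v[2] = -v[2]; }
      return;
    }
  }
}

// Per-voxel eigen-decomposition of the Hessian field. Returns eigenvalues
// sorted by increasing |lambda| and the eigenvector of the smallest-|lambda|
// eigenvalue (the local elongation direction), sign-fixed so the first
// non-zero component is positive.
// [[Rcpp::export]]
List hessian_eigen_cpp(NumericVector hxx, NumericVector hyy, NumericVector hzz,
                       NumericVector hxy, NumericVector hxz, NumericVector hyz) {
  const R_xlen_t n = hxx.size();
  NumericVector l1(n), l2(n), l3(n), ex(n), ey(n), ez(n);
  arma::mat33 A; arma::vec3 eval_a; arma::mat33 evec_a;
  for (R_xlen_t t = 0; t < n; ++t) {
    double a11 = hxx[t], a22 = hyy[t], a33 = hzz[t];
    double a12 = hxy[t], a13 = hxz[t], a23 = hyz[t];
    double ev[3];
    eig3_values(a11, a22, a33, a12, a13, a23, ev);
    // order by |lambda| ascending
    int ord[3] = {0, 1, 2};
    for (int a = 0; a < 2; ++a)
      for (int b = a + 1; b < 3; ++b)
        if (std::fabs(ev[ord[b]]) < std::fabs(ev[ord[a]]))
          std::swap(ord[a], ord[b]);
    double s1 = ev[ord[0]], s2 = ev[ord[1]], s3 = ev[ord[2]];
    double v[3];
    if (!eig3_vector(a11, a22, a33, a12, a13, a23, s1, v)) {
      // (near-)degenerate: fall back to LAPACK for a well-defined basis
      A(0,0)=a11; A(1,1)=a22; A(2,2)=a33;
      A(0,1)=A(1,0)=a12; A(0,2)=A(2,0)=a13; A(1,2)=A(2,1)=a23;
      if (arma::eig_sym(eval_a, evec_a, A)) {
        int bi = 0; double bv = std::fabs(eval_a(0));
        for (int c = 1; c < 3; ++c)
          if (std::fabs(eval_a(c)) < bv) { bv = std::fabs(eval_a(c)); bi = c; }
        v[0] = evec_a(0, bi); v[1] = evec_a(1, bi); v[2] = evec_a(2, bi);
      } else { v[0] = 1; v[1] = 0; v[2] = 0; }
    }
    fix_sign(v);
    l1[t] = s1; l2[t] = s2; l3[t] = s3;
    ex[t] = v[0]; ey[t] = v[1]; ez[t] = v[2];
  }
  return List::create(_["l1"] = l1, _["l2"] = l2, _["l3"] = l3,
                      _["ex"] = ex, _["ey"] = ey, _["ez"] = ez);
}
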