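#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Column-major linear index for a 0-based voxel (i,j,k).
static inline R_xlen_t lin(int i, int j, int k, int d0, int d1) {
  return (R_xlen_t)i + (R_xlen_t)j * d0 + (R_xlen_t)k * d0 * (R_xlen_t)d1;
}

// Sample a 3-D volume at continuous 0-based voxel coordinates.
// mode 0: trilinear, mode 1: nearest neighbour. Points outside the grid
// (beyond the outermost voxel centres) return `fill`.
// [[Rcpp::export]]
NumericVector c_interp3(NumericVector vol, IntegerVector dim,
                        NumericVector px, NumericVector py, NumericVector pz,
                        double fill, int mode) {
  const int d0 = dim[0], d1 = dim[1], d2 = dim[2];
  const R_xlen_t n = px.size();
  NumericVector out(n);
  const double *v = vol.begin();
  for (R_xlen_t t = 0; t < n; ++t) {
    double x = px[t], y = py[t], z = pz[t];
    if (!R_finite(x) || !R_finite(y) || !R_finite(z)) { out[t] = fill; continue; }
    if (mode == 1) {
      int i = (int)std::lround(x), j = (int)std::lround(y), k = (int)std::lround(z);
      if (i < 0 || i >= d0 || j < 0 || j >= d1 || k < 0 || k >= d2) out[t] = fill;
      else out[t] = v[lin(i, j, k, d0, d1)];
      continue;
    }
    if (x < 0 || x > d0 - 1 || y < 0 || y > d1 - 1 || z < 0 || z > d2 - 1) {
      out[t] = fill; continue;
    }
    int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
    if (i0 == d0 - 1) --i0;
    if (j0 == d1 - 1) --j0;
    if (k0 == d2 - 1) --k0;
    if (d0 == 1) i0 = 0;
    if (d1 == 1) j0 = 0;
    if (d2 == 1) k0 = 0;
    double fx = x - i0, fy = y - j0, fz = z - k0;
    int i1 = std::min(i0 + 1, d0 - 1), j1 = std::min(j0 + 1, d1 - 1),
        k1 = std::min(k0 + 1, d2 - 1);
    double c000 = v[lin(i0, j0, k0, d0, d1)], c100 = v[lin(i1, j0, k0, d0, d1)];
    double c010 = v[lin(i0, j1, k0, d0, d1)], c110 = v[lin(i1, j1, k0, d0, d1)];
    double c001 = v[lin(i0, j0, k1, d0, d1)], c101 = v[lin(i1, j0, k1, d0, d1)];
    double c011 = v[lin(i0, j1, k1, d0, d1)], c111 = v[lin(i1, j1, k1, d0, d1)];
    double c00 = c000 * (1 - fx) + c100 * fx;
    double c10 = c010 * (1 - fx) + c110 * fx;
    double c01 = c001 * (1 - fx) + c101 * fx;
    double c11 = c011 * (1 - fx) + c111 * fx;
    double c0 = c00 * (1 - fy) + c10 * fy;
    double c1 = c01 * (1 - fy) + c11 * fy;
    out[t] = c0 * (1 - fz) + c1 * fz;
  }
  return out;
}

static const double DT_INF = 1e30;

// 1-D squared distance transform (lower envelope of parabolas),
// Felzenszwalb & Huttenlocher. f: input costs, d: output, w2: squared step.
static void dt1d(const double *f, double *d, int n, double w2,
                 int *v, double *z) {
  int k = 0;
  v[0] = 0;
  z[0] = -DT_INF;
  z[1] = DT_INF;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      int p = v[k];
      s = ((f[q] + w2 * q * q) - (f[p] + w2 * p * p)) / (2.0 * w2 * (q - p));
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = DT_INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    int p = v[k];
    d[q] = w2 * (q - p) * (q - p) + f[p];
  }
}

// Squared Euclidean distance (mm^2) from every voxel to the nearest TRUE
// voxel of a 3-D mask, with anisotropic spacing. Empty mask -> all DT_INF.
// [[Rcpp::export]]
NumericVector c_edt3_sq(LogicalVector mask, IntegerVector dim,
                        NumericVector spacing) {
  const int d0 = dim[0], d1 = dim[1], d2 = dim[2];
  R_xlen_t n = (R_xlen_t)d0 * d1 * d2;
  NumericVector D(n);
  for (R_xlen_t t = 0; t < n; ++t) D[t] = mask[t] ? 0.0 : DT_INF;
  int nmax = std::max(d0, std::max(d1, d2));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);
  // axis 0
  double w2 = spacing[0] * spacing[0];
  for (int k = 0; k < d2; ++k)
    for (int j = 0; j < d1; ++j) {
      double *col = &D[lin(0, j, k, d0, d1)];
      dt1d(col, d.data(), d0, w2, v.data(), z.data());
      std::copy(d.begin(), d.begin() + d0, col);
    }
  // axis 1
  w2 = spacing[1] * spacing[1];
  for (int k = 0; k < d2; ++k)
    for (int i = 0; i < d0; ++i) {
      for (int j = 0; j < d1; ++j) f[j] = D[lin(i, j, k, d0, d1)];
      dt1d(f.data(), d.data(), d1, w2, v.data(), z.data());
      for (int j = 0; j < d1; ++j) D[lin(i, j, k, d0, d1)] = d[j];
    }
  // axis 2
  w2 = spacing[2] * spacing[2];
  for (int j = 0; j < d1; ++j)
    for (int i = 0; i < d0; ++i) {
      for (int k = 0; k < d2; ++k) f[k] = D[lin(i, j, k, d0, d1)];
      dt1d(f.data(), d.data(), d2, w2, v.data(), z.data());
      for (int k = 0; k < d2; ++k) D[lin(i, j, k, d0, d1)] = d[k];
    }
  return D;
}

// Separable Gaussian smoothing with per-axis sigma in voxel units.
// Kernels are truncated at 3 sigma and renormalised at the borders
// (equivalent to dividing by the smoothed indicator of the domain).
// [[Rcpp::export]]
NumericVector c_gauss3(NumericVector vol, IntegerVector dim,
                       NumericVector sigma) {
  const int d0 = dim[0], d1 = dim[1], d2 = dim[2];
  R_xlen_t n = (R_xlen_t)d0 * d1 * d2;
  NumericVector cur = clone(vol);
  for (int axis = 0; axis < 3; ++axis) {
    double s = sigma[axis];
    if (s <= 0) continue;
    int h = std::max(1, (int)std::ceil(3.0 * s));
    std::vector<double> w(2 * h + 1);
    for (int t = -h; t <= h; ++t) w[t + h] = std::exp(-0.5 * t * t / (s * s));
    NumericVector nxt(n);
    int dlen = (axis == 0) ? d0 : (axis == 1 ? d1 : d2);
    for (int k = 0; k < ((axis == 2) ? 1 : d2); ++k)
      for (int j = 0; j < ((axis == 1) ? 1 : d1); ++j)
        for (int i = 0; i < ((axis == 0) ? 1 : d0); ++i) {
          // iterate over the remaining two axes; the smoothed axis is inner
          int aa = i, bb = j, cc = k;
          for (int q = 0; q < dlen; ++q) {
            if (axis == 0) aa = q; else if (axis == 1) bb = q; else cc = q;
            double acc = 0, wsum = 0;
            int lo = std::max(0, q - h), hi = std::min(dlen - 1, q + h);
            for (int p = lo; p <= hi; ++p) {
              double wt = w[p - q + h];
              R_xlen_t idx;
              if (axis == 0) idx = lin(p, bb, cc, d0, d1);
              else if (axis == 1) idx = lin(aa, p, cc, d0, d1);
              else idx = lin(aa, bb, p, d0, d1);
              acc += wt * cur[idx];
              wsum += wt;
            }
            R_xlen_t oidx;
            if (axis == 0) oidx = lin(aa, bb, cc, d0, d1);
            else if (axis == 1) oidx = lin(aa, bb, cc, d0, d1);
            else oidx = lin(aa, bb, cc, d0, d1);
            nxt[oidx] = acc / wsum;
          }
        }
    cur = nxt;
  }
  return cur;
}

// Central-difference spatial gradient of a 3-D volume, in 1/mm units.
// Returns an n x 3 matrix (d/dx, d/dy, d/dz); one-sided at the borders.
// [[Rcpp::export]]
NumericMatrix c_grad3(NumericVector vol, IntegerVector dim,
                      NumericVector spacing) {
  const int d0 = dim[0], d1 = dim[1], d2 = dim[2];
  R_xlen_t n = (R_xlen_t)d0 * d1 * d2;
  NumericMatrix g(n, 3);
  const double *v = vol.begin();
  for (int k = 0; k < d2; ++k)
    for (int j = 0; j < d1; ++j)
      for (int i = 0; i < d0; ++i) {
        R_xlen_t idx = lin(i, j, k, d0, d1);
        int ip = std::min(i + 1, d0 - 1), im = std::max(i - 1, 0);
        int jp = std::min(j + 1, d1 - 1), jm = std::max(j - 1, 0);
        int kp = std::min(k + 1, d2 - 1), km = std::max(k - 1, 0);
        g(idx, 0) = (v[lin(ip, j, k, d0, d1)] - v[lin(im, j, k, d0, d1)]) /
                    ((ip - im) * spacing[0]);
        g(idx, 1) = (v[lin(i, jp, k, d0, d1)] - v[lin(i, jm, k, d0, d1)]) /
                    ((jp - jm) * spacing[1]);
        g(idx, 2) = (v[lin(i, j, kp, d0, d1)] - v[lin(i, j, km, d0, d1)]) /
                    ((kp - km) * spacing[2]);
      }
  return g;
}

// Morphological dilation of a 3-D mask by an explicit list of integer
// voxel offsets (n x 3).
// [[Rcpp::export]]
LogicalVector c_dilate3(LogicalVector mask, IntegerVector dim,
                        IntegerMatrix offsets) {
  const int d0 = dim[0], d1 = dim[1], d2 = dim[2];
  R_xlen_t n = (R_xlen_t)d0 * d1 * d2;
  LogicalVector out(n);
  for (int r = 0; r < offsets.nrow(); ++r) {
    int oi = offsets(r, 0), oj = offsets(r, 1), ok = offsets(r, 2);
    int i0 = std::max(0, -oi), i1 = std::min(d0, d0 - oi);
    int j0 = std::max(0, -oj), j1 = std::min(d1, d1 - oj);
    int k0 = std::max(0, -ok), k1 = std::min(d2, d2 - ok);
    for (int k = k0; k < k1; ++k)
      for (int j = j0; j < j1; ++j) {
        const int *src = &mask[lin(i0 + oi, j + oj, k + ok, d0, d1)];
        int *dst = &out[lin(i0, j, k, d0, d1)];
        for (int i = 0; i < i1 - i0; ++i)
          if (src[i]) dst[i] = TRUE;
      }
  }
  return out;
}
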