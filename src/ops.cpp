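#include <Rcpp.h>
#include <vector>
#include <limits>
#include <cstring>
using namespace Rcpp;

// Large finite stand-in for +Inf inside the parabola envelope; keeps the
// intersection arithmetic finite when a scan line contains no background.
static const double DT_BIG = 1e15;

// 1D squared distance transform along a sampled line (lower envelope of
// parabolas, Felzenszwalb & Huttenlocher).
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z, int n) {
  const double INF = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      --k;
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = q - v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Squared Euclidean distance from every voxel to the nearest FALSE voxel of
// `mask` (0 on FALSE voxels). Distances are exact center-to-center values, so
// thresholding at r^2 reproduces erosion/dilation with a Euclidean ball of
// integer radius r exactly.
// [[Rcpp::export]]
NumericVector cpp_edt3_sq(LogicalVector mask, IntegerVector dims) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = mask[i] ? DT_BIG : 0.0;

  int nmax = std::max(n1, std::max(n2, n3));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // axis 1 (stride 1)
  for (int i3 = 0; i3 < n3; ++i3)
    for (int i2 = 0; i2 < n2; ++i2) {
      double* p = &out[(R_xlen_t)n1 * (i2 + (R_xlen_t)n2 * i3)];
      for (int i = 0; i < n1; ++i) f[i] = p[i];
      dt1d(f, d, v, z, n1);
      for (int i = 0; i < n1; ++i) p[i] = d[i];
    }
  // axis 2 (stride n1)
  for (int i3 = 0; i3 < n3; ++i3)
    for (int i1 = 0; i1 < n1; ++i1) {
      double* p = &out[i1 + (R_xlen_t)n1 * n2 * i3];
      for (int i = 0; i < n2; ++i) f[i] = p[(R_xlen_t)n1 * i];
      dt1d(f, d, v, z, n2);
      for (int i = 0; i < n2; ++i) p[(R_xlen_t)n1 * i] = d[i];
    }
  // axis 3 (stride n1*n2)
  const R_xlen_t s3 = (R_xlen_t)n1 * n2;
  for (int i2 = 0; i2 < n2; ++i2)
    for (int i1 = 0; i1 < n1; ++i1) {
      double* p = &out[i1 + (R_xlen_t)n1 * i2];
      for (int i = 0; i < n3; ++i) f[i] = p[s3 * i];
      dt1d(f, d, v, z, n3);
      for (int i = 0; i < n3; ++i) p[s3 * i] = d[i];
    }
  // clamp unreachable voxels back to a huge value
  for (R_xlen_t i = 0; i < n; ++i)
    if (out[i] >= DT_BIG) out[i] = DT_BIG;
  return out;
}

// Connected component labeling of TRUE voxels; connectivity 6 or 26.
// Labels are 1..K in discovery order, 0 for background.
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dims,
                                   int connectivity) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  IntegerVector lab(n);
  std::vector<int> off1, off2, off3;
  for (int d3 = -1; d3 <= 1; ++d3)
    for (int d2 = -1; d2 <= 1; ++d2)
      for (int d1 = -1; d1 <= 1; ++d1) {
        int adeg = std::abs(d1) + std::abs(d2) + std::abs(d3);
        if (adeg == 0) continue;
        if (connectivity == 6 && adeg > 1) continue;
        off1.push_back(d1);
        off2.push_back(d2);
        off3.push_back(d3);
      }
  const int noff = (int)off1.size();
  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t seed = 0; seed < n; ++seed) {
    if (!mask[seed] || lab[seed] != 0) continue;
    ++next;
    lab[seed] = next;
    stack.clear();
    stack.push_back(seed);
    while (!stack.empty()) {
      R_xlen_t cur = stack.back();
      stack.pop_back();
      int i1 = (int)(cur % n1);
      int i2 = (int)((cur / n1) % n2);
      int i3 = (int)(cur / ((R_xlen_t)n1 * n2));
      for (int k = 0; k < noff; ++k) {
        int j1 = i1 + off1[k], j2 = i2 + off2[k], j3 = i3 + off3[k];
        if (j1 < 0 || j1 >= n1 || j2 < 0 || j2 >= n2 || j3 < 0 || j3 >= n3)
          continue;
        R_xlen_t idx = j1 + (R_xlen_t)n1 * (j2 + (R_xlen_t)n2 * j3);
        if (mask[idx] && lab[idx] == 0) {
          lab[idx] = next;
          stack.push_back(idx);
        }
      }
    }
  }
  return lab;
}

// Binary median filter with a 3 x 3 in-plane kernel applied independently to
// each axial slice (axial = first array axis, kernel spans axes 2 and 3).
// Out-of-grid neighbors count as background, so the decision is always over
// 9 values: output is TRUE iff at least 5 are TRUE.
// [[Rcpp::export]]
LogicalVector cpp_binary_median3x3(LogicalVector mask, IntegerVector dims) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  LogicalVector out((R_xlen_t)n1 * n2 * n3);
  for (int i3 = 0; i3 < n3; ++i3)
    for (int i2 = 0; i2 < n2; ++i2)
      for (int i1 = 0; i1 < n1; ++i1) {
        int cnt = 0;
        for (int d3 = -1; d3 <= 1; ++d3)
          for (int d2 = -1; d2 <= 1; ++d2) {
            int j2 = i2 + d2, j3 = i3 + d3;
            if (j2 < 0 || j2 >= n2 || j3 < 0 || j3 >= n3) continue;
            if (mask[i1 + (R_xlen_t)n1 * (j2 + (R_xlen_t)n2 * j3)]) ++cnt;
          }
        out[i1 + (R_xlen_t)n1 * (i2 + (R_xlen_t)n2 * i3)] = (cnt >= 5);
      }
  return out;
}

// Gather 3x3 'same'-padded patches for a batch of feature maps.
// X: (B*H*W) x C, samples stacked in row blocks, pixels column-major (H fast).
// Returns (B*H*W) x (9*C); column k + 9*c holds channel c shifted by the k-th
// kernel offset, k = (d_col + 1) * 3 + (d_row + 1).
// [[Rcpp::export]]
NumericMatrix cpp_im2col3x3(NumericMatrix X, int B, int H, int W) {
  const int C = X.ncol();
  const R_xlen_t HW = (R_xlen_t)H * W;
  NumericMatrix out((int)(B * HW), 9 * C);
  for (int c = 0; c < C; ++c) {
    const double* xc = &X(0, c);
    for (int dc = -1; dc <= 1; ++dc)
      for (int dr = -1; dr <= 1; ++dr) {
        int k = (dc + 1) * 3 + (dr + 1);
        double* oc = &out(0, k + 9 * c);
        int r0 = std::max(0, -dr), r1 = H - 1 - std::max(0, dr);
        int nrun = r1 - r0 + 1;
        if (nrun <= 0) continue;
        for (int b = 0; b < B; ++b) {
          R_xlen_t base = b * HW;
          for (int j = 0; j < W; ++j) {
            int js = j + dc;
            if (js < 0 || js >= W) continue;
            std::memcpy(oc + base + (R_xlen_t)j * H + r0,
                        xc + base + (R_xlen_t)js * H + r0 + dr,
                        nrun * sizeof(double));
          }
        }
      }
  }
  return out;
}

// Adjoint of cpp_im2col3x3: scatter-add patch gradients back onto the
// (B*H*W) x C input layout.
// [[Rcpp::export]]
NumericMatrix cpp_col2im3x3(NumericMatrix G, int B, int H, int W, int C) {
  const R_xlen_t HW = (R_xlen_t)H * W;
  NumericMatrix out((int)(B * HW), C);
  for (int c = 0; c < C; ++c) {
    double* oc = &out(0, c);
    for (int dc = -1; dc <= 1; ++dc)
      for (int dr = -1; dr <= 1; ++dr) {
        int k = (dc + 1) * 3 + (dr + 1);
        const double* gc = &G(0, k + 9 * c);
        int r0 = std::max(0, -dr), r1 = H - 1 - std::max(0, dr);
        if (r1 < r0) continue;
        for (int b = 0; b < B; ++b) {
          R_xlen_t base = b * HW;
          for (int j = 0; j < W; ++j) {
            int js = j + dc;
            if (js < 0 || js >= W) continue;
            double* dst = oc + base + (R_xlen_t)js * H + dr;
            const double* src = gc + base + (R_xlen_t)j * H;
            for (int r = r0; r <= r1; ++r) dst[r] += src[r];
          }
        }
      }
  }
  return out;
}
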