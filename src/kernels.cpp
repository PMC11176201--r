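#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>
using namespace Rcpp;

// Haralick feature codes shared with R/texture.R (order matters):
// 0 contrast, 1 dissimilarity, 2 homogeneity, 3 energy, 4 entropy,
// 5 correlation, 6 variance, 7 sum_average, 8 cluster_shade,
// 9 cluster_prominence
static void haralick_from_counts(const std::vector<double>& cnt, int b,
                                 double total, double* out) {
  std::vector<double> px(b, 0.0), py(b, 0.0);
  double contrast = 0, dissim = 0, homog = 0, energy = 0, entropy = 0;
  for (int i = 0; i < b; ++i) {
    for (int j = 0; j < b; ++j) {
      double p = cnt[i * b + j] / total;
      if (p <= 0) continue;
      px[i] += p; py[j] += p;
      double d = (double)(i - j);
      contrast += p * d * d;
      dissim += p * std::fabs(d);
      homog += p / (1.0 + d * d);
      energy += p * p;
      entropy -= p * std::log2(p);
    }
  }
  double mx = 0, my = 0;
  for (int i = 0; i < b; ++i) { mx += i * px[i]; my += i * py[i]; }
  double sx = 0, sy = 0;
  for (int i = 0; i < b; ++i) {
    sx += (i - mx) * (i - mx) * px[i];
    sy += (i - my) * (i - my) * py[i];
  }
  sx = std::sqrt(sx); sy = std::sqrt(sy);
  double corr = 0, variance = 0, sumavg = 0, shade = 0, prom = 0;
  for (int i = 0; i < b; ++i) {
    for (int j = 0; j < b; ++j) {
      double p = cnt[i * b + j] / total;
      if (p <= 0) continue;
      corr += (i - mx) * (j - my) * p;
      variance += (i - mx) * (i - mx) * p;
      sumavg += (i + j) * p;
      double c = i + j - mx - my;
      shade += c * c * c * p;
      prom += c * c * c * c * p;
    }
  }
  corr = (sx == 0 || sy == 0) ? 0.0 : corr / (sx * sy);
  out[0] = contrast; out[1] = dissim; out[2] = homog; out[3] = energy;
  out[4] = entropy; out[5] = corr; out[6] = variance; out[7] = sumavg;
  out[8] = shade; out[9] = prom;
}

// Windowed GLCM statistics for one 2D slice.
// levels: gray levels in [0, nbins-1], negative = invalid; mask: 0/1.
// offx/offy: one co-occurrence offset per (angle, distance) combination.
// For every window centre whose w x w neighbourhood (out-of-grid counted
// as background, denominator w^2) has >= minfrac in-mask voxels, a
// symmetric normalized GLCM is built per offset from pairs with both
// endpoints inside the window and mask, and all ten Haralick features are
// computed. Returns per-offset sums over qualifying windows plus window
// counts, so the caller can aggregate means across slices.
// [[Rcpp::export]]
List glcm_window_slice_cpp(IntegerMatrix levels, IntegerMatrix mask,
                           IntegerVector offx, IntegerVector offy,
                           int nbins, int window, double minfrac) {
  int nx = levels.nrow(), ny = levels.ncol();
  int noff = offx.size();
  int h = (window - 1) / 2;
  NumericMatrix sums(noff, 10);
  IntegerVector counts(noff);
  std::vector<double> cnt((size_t)nbins * nbins);
  double feats[10];

  // integral image of the mask for O(1) in-window foreground counts
  std::vector<int> integ((size_t)(nx + 1) * (ny + 1), 0);
  for (int y = 1; y <= ny; ++y)
    for (int x = 1; x <= nx; ++x)
      integ[(size_t)y * (nx + 1) + x] = mask(x - 1, y - 1) +
        integ[(size_t)(y - 1) * (nx + 1) + x] +
        integ[(size_t)y * (nx + 1) + x - 1] -
        integ[(size_t)(y - 1) * (nx + 1) + x - 1];
  const double denom = (double)window * window;

  for (int cy = 0; cy < ny; ++cy) {
    for (int cx = 0; cx < nx; ++cx) {
      int x0 = std::max(cx - h, 0), x1 = std::min(cx + h, nx - 1);
      int y0 = std::max(cy - h, 0), y1 = std::min(cy + h, ny - 1);
      int fg = integ[(size_t)(y1 + 1) * (nx + 1) + x1 + 1] -
               integ[(size_t)y0 * (nx + 1) + x1 + 1] -
               integ[(size_t)(y1 + 1) * (nx + 1) + x0] +
               integ[(size_t)y0 * (nx + 1) + x0];
      if ((double)fg / denom < minfrac) continue;
      for (int o = 0; o < noff; ++o) {
        int ox = offx[o], oy = offy[o];
        std::fill(cnt.begin(), cnt.end(), 0.0);
        double total = 0.0;
        for (int y = y0; y <= y1; ++y) {
          int yb = y + oy;
          if (yb < y0 || yb > y1) continue;
          for (int x = x0; x <= x1; ++x) {
            int xb = x + ox;
            if (xb < x0 || xb > x1) continue;
            if (!mask(x, y) || !mask(xb, yb)) continue;
            int li = levels(x, y), lj = levels(xb, yb);
            if (li < 0 || lj < 0 || li >= nbins || lj >= nbins) continue;
            cnt[(size_t)li * nbins + lj] += 1.0;  // symmetric: count both
            cnt[(size_t)lj * nbins + li] += 1.0;
            total += 2.0;
          }
        }
        if (total <= 0) continue;
        haralick_from_counts(cnt, nbins, total, feats);
        for (int f = 0; f < 10; ++f) sums(o, f) += feats[f];
        counts[o] += 1;
      }
    }
  }
  return List::create(_["sums"] = sums, _["counts"] = counts);
}

// 1D squared-distance transform (lower envelope of parabolas), grid step s.
static void dt1d(const double* f, double* d, int n, double s) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  const double INF = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0; z[0] = -INF; z[1] = INF;
  for (int q = 1; q < n; ++q) {
    double sq = s * s;
    double num = (f[q] + sq * q * q) - (f[v[k]] + sq * v[k] * v[k]);
    double sden = 2.0 * sq * (q - v[k]);
    double inter = num / sden;
    while (inter <= z[k]) {
      --k;
      num = (f[q] + sq * q * q) - (f[v[k]] + sq * v[k] * v[k]);
      sden = 2.0 * sq * (q - v[k]);
      inter = num / sden;
    }
    ++k;
    v[k] = q; z[k] = inter; z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = s * (q - v[k]);
    d[q] = dq * dq + f[v[k]];
  }
}

// Exact anisotropic squared Euclidean distance transform of a 3D mask:
// distance from each foreground voxel to the nearest background voxel, in
// mm. Background voxels get 0.
// [[Rcpp::export]]
NumericVector edt3_cpp(IntegerVector mask, IntegerVector dim,
                       NumericVector spacing) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t n = (size_t)nx * ny * nz;
  const double INF = 1e30;
  NumericVector out(n);
  for (size_t i = 0; i < n; ++i) out[i] = mask[i] ? INF : 0.0;

  std::vector<double> f(std::max(nx, std::max(ny, nz)));
  std::vector<double> d(f.size());
  // x lines
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      size_t base = (size_t)z * nx * ny + (size_t)y * nx;
      for (int x = 0; x < nx; ++x) f[x] = out[base + x];
      dt1d(f.data(), d.data(), nx, spacing[0]);
      for (int x = 0; x < nx; ++x) out[base + x] = d[x];
    }
  // y lines
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      size_t base = (size_t)z * nx * ny + x;
      for (int y = 0; y < ny; ++y) f[y] = out[base + (size_t)y * nx];
      dt1d(f.data(), d.data(), ny, spacing[1]);
      for (int y = 0; y < ny; ++y) out[base + (size_t)y * nx] = d[y];
    }
  // z lines
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      size_t base = (size_t)y * nx + x;
      for (int z = 0; z < nz; ++z) f[z] = out[base + (size_t)z * nx * ny];
      dt1d(f.data(), d.data(), nz, spacing[2]);
      for (int z = 0; z < nz; ++z) out[base + (size_t)z * nx * ny] = d[z];
    }
  return out;
}
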