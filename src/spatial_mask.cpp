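#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

static double median_of(std::vector<double>& v) {
  size_t n = v.size();
  std::sort(v.begin(), v.end());
  if (n % 2 == 1) return v[n / 2];
  return 0.5 * (v[n / 2 - 1] + v[n / 2]);
}

// Local-median-surface outlier mask on a probe grid.
// For each finite cell, the median of finite neighbors within Chebyshev
// radius `radius` (excluding the cell itself) defines the local surface;
// the cell is masked when |value - median| > k * local MAD (MAD floored at
// a tiny constant so constant backgrounds still expose gross outliers).
// Returns 0 = keep, 1 = mask, 2 = degenerate neighborhood (kept).
// [[Rcpp::export]]
IntegerMatrix spatial_outlier_mask_cpp(NumericMatrix grid, int radius, double k) {
  int nr = grid.nrow(), nc = grid.ncol();
  IntegerMatrix out(nr, nc);
  std::vector<double> nb, dev;
  const double mad_floor = 1e-8;
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) {
      double x = grid(i, j);
      if (!R_finite(x)) { out(i, j) = 0; continue; }
      nb.clear();
      for (int di = -radius; di <= radius; ++di) {
        int ii = i + di;
        if (ii < 0 || ii >= nr) continue;
        for (int dj = -radius; dj <= radius; ++dj) {
          if (di == 0 && dj == 0) continue;
          int jj = j + dj;
          if (jj < 0 || jj >= nc) continue;
          double y = grid(ii, jj);
          if (R_finite(y)) nb.push_back(y);
        }
      }
      if (nb.empty()) { out(i, j) = 2; continue; }
      dev = nb;
      double med = median_of(dev);
      dev.clear();
      for (double y : nb) dev.push_back(std::fabs(y - med));
      double mad = median_of(dev);
      if (mad < mad_floor) mad = mad_floor;
      out(i, j) = (std::fabs(x - med) > k * mad) ? 1 : 0;
    }
  }
  return out;
}

// Row medians for dense numeric matrices (optionally skipping NAs);
// hot path of the replicate summarization and probe centering.
// [[Rcpp::export]]
NumericVector row_medians_cpp(NumericMatrix x, bool na_rm) {
  int nr = x.nrow(), nc = x.ncol();
  NumericVector out(nr);
  std::vector<double> buf;
  buf.reserve(nc);
  for (int i = 0; i < nr; ++i) {
    buf.clear();
    for (int j = 0; j < nc; ++j) {
      double v = x(i, j);
      if (R_finite(v)) buf.push_back(v);
      else if (!na_rm && !ISNA(v)) buf.push_back(v);
    }
    if (buf.empty()) { out[i] = NA_REAL; continue; }
    out[i] = median_of(buf);
  }
  return out;
}
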