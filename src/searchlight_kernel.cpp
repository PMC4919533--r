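// Hot loop of the searchlight RSA: per sphere, Spearman-correlate the
// retrieval instance patterns at the included contrast cells only, and
// return the contrast-GLM slope for the sphere's centre voxel.

#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
using namespace Rcpp;

// average ranks (ties share the mean rank), written into r
static void avg_rank(const std::vector<double>& x, std::vector<double>& r,
                     std::vector<int>& idx) {
  const int p = (int)x.size();
  idx.resize(p);
  for (int i = 0; i < p; ++i) idx[i] = i;
  std::sort(idx.begin(), idx.end(),
            [&x](int a, int b) { return x[a] < x[b]; });
  r.resize(p);
  int i = 0;
  while (i < p) {
    int j = i;
    while (j + 1 < p && x[idx[j + 1]] == x[idx[i]]) ++j;
    double avg = 0.5 * (i + j) + 1.0;
    for (int k = i; k <= j; ++k) r[idx[k]] = avg;
    i = j + 1;
  }
}

// [[Rcpp::export(name = ".searchlight_slopes_cpp")]]
NumericVector searchlight_slopes_cpp(NumericMatrix data, List spheres,
                                     IntegerVector cell_i,
                                     IntegerVector cell_j,
                                     NumericVector w) {
  const int T = data.ncol();
  const R_xlen_t nvox = data.nrow();
  const int ncell = cell_i.size();
  const int ns = spheres.size();
  NumericVector out(ns, NA_REAL);

  std::vector<double> col(64), rk(64);
  std::vector<int> idx(64);

  for (int s = 0; s < ns; ++s) {
    IntegerVector vox = spheres[s];
    const int p = vox.size();
    if (p < 3) continue;
    // standardized average ranks, column-major p x T
    std::vector<double> Z((size_t)p * T);
    std::vector<bool> bad(T, false);
    col.resize(p);
    const double mean_rank = 0.5 * (p + 1);
    for (int t = 0; t < T; ++t) {
      for (int v = 0; v < p; ++v) {
        R_xlen_t row = (R_xlen_t)vox[v] - 1;
        col[v] = data[row + nvox * (R_xlen_t)t];
      }
      avg_rank(col, rk, idx);
      double ss = 0.0;
      for (int v = 0; v < p; ++v) {
        double d = rk[v] - mean_rank;
        ss += d * d;
      }
      if (ss <= 0.0) {
        bad[t] = true;
        continue;
      }
      const double inv = 1.0 / std::sqrt(ss);
      double* zc = &Z[(size_t)p * t];
      for (int v = 0; v < p; ++v) zc[v] = (rk[v] - mean_rank) * inv;
    }
    // similarity at included cells, then the OLS slope on valid cells
    double sw = 0.0, swy = 0.0, sww = 0.0, sy = 0.0;
    int nvalid = 0;
    double wmin = R_PosInf, wmax = R_NegInf;
    std::vector<double> yv(ncell), wv(ncell);
    for (int k = 0; k < ncell; ++k) {
      const int a = cell_i[k] - 1, b = cell_j[k] - 1;
      if (bad[a] || bad[b]) continue;
      const double* za = &Z[(size_t)p * a];
      const double* zb = &Z[(size_t)p * b];
      double dot = 0.0;
      for (int v = 0; v < p; ++v) dot += za[v] * zb[v];
      yv[nvalid] = dot;
      wv[nvalid] = w[k];
      sw += w[k];
      sy += dot;
      if (w[k] < wmin) wmin = w[k];
      if (w[k] > wmax) wmax = w[k];
      ++nvalid;
    }
    if (nvalid < 3 || !(wmax > wmin)) continue;
    const double wbar = sw / nvalid, ybar = sy / nvalid;
    for (int k = 0; k < nvalid; ++k) {
      const double wc = wv[k] - wbar;
      swy += wc * (yv[k] - ybar);
      sww += wc * wc;
    }
    if (sww > 0.0) out[s] = swy / sww;
  }
  return out;
}
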