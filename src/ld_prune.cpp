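#include <Rcpp.h>
using namespace Rcpp;

// Greedy plink-style LD pruning for one chromosome.
//
// X: samples x markers dosage matrix, mean-imputed and centered per marker.
// maf: per-marker minor allele frequency (removal rule: drop the lower-MAF
// member of an offending pair; ties drop the later position).
// Within each `window`-marker span, the retained pair with the highest r^2
// above `r2max` is resolved repeatedly until none remains, then the window
// advances by `step` markers.  Pairwise r^2 within a window is computed
// once and cached (correlations do not change when other markers are
// dropped); for step == 1 a window that merely extends a clean predecessor
// by one marker only needs that marker's pairs checked.
//
// [[Rcpp::export(name = ".ld_prune_chr")]]
IntegerVector ld_prune_chr(NumericMatrix X, NumericVector maf,
                           IntegerVector pos, int window, int step,
                           double r2max) {
  const int n = X.nrow();
  const int m = X.ncol();
  std::vector<bool> keep(m, true);
  std::vector<double> ss(m);
  for (int j = 0; j < m; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += X(i, j) * X(i, j);
    ss[j] = s;
  }
  if (m == 0) return IntegerVector(0);

  auto r2 = [&](int a, int b) {
    if (ss[a] <= 0 || ss[b] <= 0) return 0.0;
    double dot = 0.0;
    for (int i = 0; i < n; ++i) dot += X(i, a) * X(i, b);
    return (dot * dot) / (ss[a] * ss[b]);
  };

  std::vector<double> cache(static_cast<size_t>(window) * window);
  bool prev_clean = false;
  int prev_w1 = -1;
  for (int w0 = 0; w0 < m; w0 += step) {
    int w1 = std::min(w0 + window, m);
    int w = w1 - w0;
    bool dirty = true;
    if (step == 1 && prev_clean) {
      if (w1 == prev_w1) continue;  // strict subset of a clean window
      dirty = false;
      int b = w1 - 1;
      if (keep[b]) {
        for (int a = w0; a < b; ++a) {
          if (keep[a] && r2(a, b) > r2max) {
            dirty = true;
            break;
          }
        }
      }
    }
    if (dirty) {
      // one pass of pairwise r^2 for the window, then greedy max-first
      // removal on the cached values
      for (int a = 0; a < w; ++a) {
        if (!keep[w0 + a]) continue;
        for (int b = a + 1; b < w; ++b) {
          if (!keep[w0 + b]) continue;
          cache[a * window + b] = r2(w0 + a, w0 + b);
        }
      }
      for (;;) {
        double best = r2max;
        int bi = -1, bj = -1;
        for (int a = 0; a < w; ++a) {
          if (!keep[w0 + a]) continue;
          for (int b = a + 1; b < w; ++b) {
            if (!keep[w0 + b]) continue;
            if (cache[a * window + b] > best) {
              best = cache[a * window + b];
              bi = w0 + a;
              bj = w0 + b;
            }
          }
        }
        if (bi < 0) break;
        int drop;
        if (maf[bi] < maf[bj]) drop = bi;
        else if (maf[bj] < maf[bi]) drop = bj;
        else drop = (pos[bi] > pos[bj]) ? bi : bj;  // tie: later position
        keep[drop] = false;
      }
    }
    prev_clean = true;
    prev_w1 = w1;
    if (w1 == m) break;
  }

  std::vector<int> out;
  for (int j = 0; j < m; ++j)
    if (keep[j]) out.push_back(j + 1);
  return wrap(out);
}
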