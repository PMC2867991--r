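#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Per-template match counts for approximate entropy.
// For pattern length m, templates are x[i..i+m-1], i = 0..N-m (N-m+1 of them);
// counts[i] = #{ j != i : max_k |x[i+k]-x[j+k]| <= r } (strict < if strict).
// [[Rcpp::export(name = ".apenCounts")]]
IntegerVector apen_counts(NumericVector x, int m, double r, bool strict) {
  const int n = x.size();
  const int nv = n - m + 1;
  IntegerVector counts(nv);
  for (int i = 0; i < nv; ++i) {
    for (int j = i + 1; j < nv; ++j) {
      double d = 0.0;
      for (int k = 0; k < m; ++k) {
        double dk = std::fabs(x[i + k] - x[j + k]);
        if (dk > d) d = dk;
      }
      bool match = strict ? (d < r) : (d <= r);
      if (match) { counts[i]++; counts[j]++; }
    }
  }
  return counts;
}

// Pair counts of the correlation integral: for each radius in the sorted
// ascending grid, the number of unordered pairs (i,j), |i-j| > w, with
// distance < radius. Returns the per-radius counts and the number of
// admissible pairs.
// [[Rcpp::export(name = ".corrCounts")]]
List corr_counts(NumericMatrix pts, NumericVector radii, int w,
                 bool chebyshev) {
  const int M = pts.nrow(), d = pts.ncol(), nr = radii.size();
  std::vector<double> r2(nr);
  for (int k = 0; k < nr; ++k)
    r2[k] = chebyshev ? radii[k] : radii[k] * radii[k];
  std::vector<long long> hist(nr + 1, 0);
  long long admissible = 0;
  for (int i = 0; i < M; ++i) {
    for (int j = i + w + 1; j < M; ++j) {
      double dist = 0.0;
      if (chebyshev) {
        for (int k = 0; k < d; ++k) {
          double dk = std::fabs(pts(i, k) - pts(j, k));
          if (dk > dist) dist = dk;
        }
      } else {
        for (int k = 0; k < d; ++k) {
          double dk = pts(i, k) - pts(j, k);
          dist += dk * dk;
        }
      }
      ++admissible;
      // first radius index with dist < r  (r2 ascending)
      int lo = 0, hi = nr;
      while (lo < hi) {
        int mid = (lo + hi) / 2;
        if (dist < r2[mid]) hi = mid; else lo = mid + 1;
      }
      ++hist[lo];
    }
  }
  NumericVector counts(nr);
  long long cum = 0;
  // counts[k] = pairs with dist < radii[k]; hist[k] holds pairs whose first
  // qualifying radius is k, so the cumulative sum up to k is the count.
  for (int k = 0; k < nr; ++k) {
    cum += hist[k];
    counts[k] = (double)cum;
  }
  return List::create(_["counts"] = counts,
                      _["n_pairs"] = (double)admissible);
}

// Nearest neighbour of each valid point under a temporal exclusion:
// nn[j] = argmin_i dist(j, i) over valid i with |i - j| > min_sep.
// Ties go to the smaller index; 0 marks "no admissible neighbour".
// [[Rcpp::export(name = ".nnPairs")]]
List nn_pairs(NumericMatrix pts, int min_sep, LogicalVector valid) {
  const int M = pts.nrow(), d = pts.ncol();
  IntegerVector nn(M);
  NumericVector nd(M);
  for (int j = 0; j < M; ++j) {
    nn[j] = 0; nd[j] = NA_REAL;
    if (!valid[j]) continue;
    double best = R_PosInf;
    int besti = -1;
    for (int i = 0; i < M; ++i) {
      if (i == j || !valid[i]) continue;
      int sep = i > j ? i - j : j - i;
      if (sep <= min_sep) continue;
      double dist = 0.0;
      for (int k = 0; k < d; ++k) {
        double dk = pts(i, k) - pts(j, k);
        dist += dk * dk;
      }
      if (dist < best) { best = dist; besti = i; }
    }
    if (besti >= 0) { nn[j] = besti + 1; nd[j] = std::sqrt(best); }
  }
  return List::create(_["nn"] = nn, _["dist"] = nd);
}

// Mean log-divergence curve: for step i = 0..max_steps,
// y[i] = mean over pairs (j, nn[j]) of log ||X_{j+i} - X_{nn[j]+i}||,
// over pairs whose advanced points are both inside the trajectory, valid,
// and at nonzero distance. Returns y, the pair counts, and the number of
// zero-distance exclusions.
// [[Rcpp::export(name = ".divergenceCurve")]]
List divergence_curve(NumericMatrix pts, IntegerVector nn, int max_steps,
                      LogicalVector valid) {
  const int M = pts.nrow(), d = pts.ncol();
  NumericVector y(max_steps + 1);
  IntegerVector np(max_steps + 1);
  int zero_dropped = 0;
  for (int i = 0; i <= max_steps; ++i) {
    double s = 0.0;
    int cnt = 0;
    for (int j = 0; j < M; ++j) {
      int q = nn[j] - 1;
      if (q < 0) continue;
      int a = j + i, b = q + i;
      if (a >= M || b >= M) continue;
      if (!valid[a] || !valid[b]) continue;
      double dist = 0.0;
      for (int k = 0; k < d; ++k) {
        double dk = pts(a, k) - pts(b, k);
        dist += dk * dk;
      }
      if (dist <= 0.0) { ++zero_dropped; continue; }
      s += 0.5 * std::log(dist);
      ++cnt;
    }
    y[i] = cnt > 0 ? s / cnt : NA_REAL;
    np[i] = cnt;
  }
  return List::create(_["y"] = y, _["n_pairs"] = np,
                      _["zero_dropped"] = zero_dropped);
}
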