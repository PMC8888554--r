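// Kernels for the association-network estimators whose permutation loops
// are too hot for interpreted code: local similarity (dynamic programming
// over aligned normal-score series) and the maximal information
// coefficient (grid search with DP-optimized x-axis partitions).

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Local similarity of two aligned series: maximal contiguous run of
// summed products (positive or negative), over alignment delays up to
// max_delay, normalized by series length. Returns signed score.
static double lsa_pair(const double* x, const double* y, int n, int max_delay) {
  double best_pos = 0.0, best_neg = 0.0;
  for (int d = -max_delay; d <= max_delay; ++d) {
    int lo = std::max(0, -d);
    int hi = std::min(n, n - d);  // x[i] aligned with y[i + d]
    double pos = 0.0, neg = 0.0;
    for (int i = lo; i < hi; ++i) {
      double z = x[i] * y[i + d];
      pos = std::max(0.0, pos + z);
      neg = std::max(0.0, neg - z);
      best_pos = std::max(best_pos, pos);
      best_neg = std::max(best_neg, neg);
    }
  }
  double s = std::max(best_pos, best_neg) / n;
  return (best_pos >= best_neg) ? s : -s;
}

// [[Rcpp::export]]
List cpp_lsa_matrix(NumericMatrix X, int max_delay) {
  int n = X.nrow(), D = X.ncol();
  NumericMatrix score(D, D);
  for (int i = 0; i < D; ++i) {
    score(i, i) = lsa_pair(&X(0, i), &X(0, i), n, max_delay);
    for (int j = i + 1; j < D; ++j) {
      double s = lsa_pair(&X(0, i), &X(0, j), n, max_delay);
      score(i, j) = s;
      score(j, i) = s;
    }
  }
  return List::create(_["score"] = score);
}

static inline double plogp(double p) { return p > 0.0 ? p * std::log(p) : 0.0; }

// MIC of one pair from the ranks of x and y (0..n-1, ties broken
// upstream). Grid dimensions (kx, ky) with kx * ky <= B; the y axis is
// equipartitioned, the x axis partition is optimized by dynamic
// programming over equal-frequency superclumps. Both orientations are
// evaluated, making the statistic symmetric.
static double mic_oriented(const std::vector<int>& ord_x,
                           const std::vector<int>& rank_y,
                           int n, int B, int clump_cap) {
  double best = 0.0;
  int ky_max = B / 2;
  for (int ky = 2; ky <= ky_max; ++ky) {
    int kx_max = B / ky;
    if (kx_max < 2) break;
    // y bins: equal frequency
    std::vector<int> ybin(n);
    for (int i = 0; i < n; ++i) {
      int b = (int)((long long)rank_y[i] * ky / n);
      ybin[i] = std::min(b, ky - 1);
    }
    // marginal y entropy
    std::vector<double> yc(ky, 0.0);
    for (int i = 0; i < n; ++i) yc[ybin[i]] += 1.0;
    double hq = 0.0;
    for (int b = 0; b < ky; ++b) hq -= plogp(yc[b] / n);

    // superclumps along x (equal frequency in x order)
    int m = std::min(n, std::max(3 * kx_max, clump_cap));
    std::vector<int> cum((m + 1) * ky, 0);  // prefix counts per y bin
    std::vector<int> csize(m, 0);
    for (int c = 0; c < m; ++c) {
      int lo = (int)((long long)c * n / m);
      int hi = (int)((long long)(c + 1) * n / m);
      csize[c] = hi - lo;
      for (int b = 0; b < ky; ++b) cum[(c + 1) * ky + b] = cum[c * ky + b];
      for (int i = lo; i < hi; ++i) cum[(c + 1) * ky + ybin[ord_x[i]]] += 1;
    }
    // part score f(t+1..i): sum_b (c_b/n) log(c_b/n) - (c/n) log(c/n),
    // additive over parts; DP maximizes the sum over <= kx parts.
    auto part_f = [&](int t, int i) {
      double tot = 0.0, f = 0.0;
      for (int b = 0; b < ky; ++b) {
        double c = cum[i * ky + b] - cum[t * ky + b];
        tot += c;
        f += plogp(c / n);
      }
      return f - plogp(tot / n);
    };
    const double NEG = -1e18;
    std::vector<double> prev(m + 1, NEG), cur(m + 1, NEG);
    for (int i = 1; i <= m; ++i) prev[i] = part_f(0, i);  // one part
    {  // l = 1 grid is uninformative (normalizer log(1)=0); start at l=2
      for (int l = 2; l <= kx_max; ++l) {
        for (int i = l; i <= m; ++i) {
          double bestv = NEG;
          for (int t = l - 1; t < i; ++t) {
            double v = prev[t] + part_f(t, i);
            if (v > bestv) bestv = v;
          }
          cur[i] = bestv;
        }
        double mi = hq + cur[m];
        double norm = std::log((double)std::min(l, ky));
        if (norm > 0.0) best = std::max(best, mi / norm);
        std::swap(prev, cur);
        std::fill(cur.begin(), cur.end(), NEG);
      }
    }
  }
  return std::min(1.0, std::max(0.0, best));
}

static void rank_order(const double* v, int n, std::vector<int>& ord,
                       std::vector<int>& rank) {
  ord.resize(n);
  rank.resize(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::stable_sort(ord.begin(), ord.end(),
                   [&](int a, int b) { return v[a] < v[b]; });
  for (int i = 0; i < n; ++i) rank[ord[i]] = i;
}

// [[Rcpp::export]]
NumericMatrix cpp_mic_matrix(NumericMatrix X, int B, int clump_cap) {
  int n = X.nrow(), D = X.ncol();
  std::vector<std::vector<int>> ords(D), ranks(D);
  for (int j = 0; j < D; ++j) rank_order(&X(0, j), n, ords[j], ranks[j]);
  NumericMatrix mic(D, D);
  for (int i = 0; i < D; ++i) {
    mic(i, i) = 1.0;
    for (int j = i + 1; j < D; ++j) {
      double a = mic_oriented(ords[i], ranks[j], n, B, clump_cap);
      double b = mic_oriented(ords[j], ranks[i], n, B, clump_cap);
      double s = std::max(a, b);
      mic(i, j) = s;
      mic(j, i) = s;
    }
  }
  return mic;
}
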