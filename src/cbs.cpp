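#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Circular binary segmentation max-T scan.
//
// For a sequence x[0..n-1] viewed as a circle, every arc is represented by a
// boundary pair (i, j), 0 <= i < j <= n, (i, j) != (0, n), with the "inside"
// group x[i..j-1] (size k) and the "outside" group the rest (size n-k).
// The statistic is the two-sample t form
//   T = |mean_in - mean_out| / max(s_p * sqrt(1/k + 1/(n-k)), 1e-12)
// with s_p^2 = (SS_in + SS_out) / (n - 2), computed from partial sums.
// Arcs that wrap the origin are complements of non-wrapping arcs and give
// the same T, so scanning i < j covers all splits. Ties are broken toward
// the smallest i, then the smallest j.
// T for one arc, from partial sums (guarded pooled-SD denominator)
static double arc_t(const std::vector<double>& S, const std::vector<double>& Q,
                    int n, int i, int j) {
  const int k = j - i, ko = n - k;
  const double sin_ = S[j] - S[i];
  const double qin = Q[j] - Q[i];
  const double sout = S[n] - sin_;
  const double qout = Q[n] - qin;
  const double ssin = qin - sin_ * sin_ / k;
  const double ssout = qout - sout * sout / ko;
  double sp2 = (ssin + ssout) / (n - 2);
  if (sp2 < 0) sp2 = 0;
  double denom = std::sqrt(sp2 * (1.0 / k + 1.0 / ko));
  if (denom < 1e-12) denom = 1e-12;
  double diff = std::fabs(sin_ / k - sout / ko);
  if (diff < 1e-9) diff = 0.0;  // constant data: rounding noise is not signal
  return diff / denom;
}

static double max_t_scan(const std::vector<double>& x, int* bi, int* bj) {
  const int n = (int)x.size();
  std::vector<double> S(n + 1, 0.0), Q(n + 1, 0.0);
  for (int t = 0; t < n; ++t) {
    S[t + 1] = S[t] + x[t];
    Q[t + 1] = Q[t] + x[t] * x[t];
  }
  const double Sn = S[n];
  // For fixed arc width k, both the mean difference and the pooled SD are
  // monotone functions of |S[i+k] - S[i] - k*Sn/n| (the within-arc and
  // outside sums of squares are quadratics minimized at the same point), so
  // T is maximized by maximizing that centered partial-sum difference.
  // This turns the O(n^2) scan into cheap adds/compares with one full T
  // evaluation per width.
  double best = -1.0;
  int besti = 0, bestj = 1;
  for (int k = 1; k < n; ++k) {
    const double center = (double)k * Sn / n;
    double umax = -1.0;
    int iu = 0;
    for (int i = 0; i + k <= n; ++i) {
      double u = std::fabs(S[i + k] - S[i] - center);
      if (u < 1e-9) u = 0.0;  // flat data: ties resolve to the smallest i
      if (u > umax) {
        umax = u;
        iu = i;
      }
    }
    const double t = arc_t(S, Q, n, iu, iu + k);
    if (t > best ||
        (t == best && (iu < besti || (iu == besti && iu + k < bestj)))) {
      best = t;
      besti = iu;
      bestj = iu + k;
    }
  }
  *bi = besti;
  *bj = bestj;
  return best;
}

// [[Rcpp::export(name = ".cbs_max_t")]]
List cbs_max_t_cpp(NumericVector x) {
  if (x.size() < 4) stop("need at least 4 values");
  std::vector<double> v(x.begin(), x.end());
  int i, j;
  double t = max_t_scan(v, &i, &j);
  return List::create(_["i"] = i, _["j"] = j, _["T"] = t);
}

// Permutation reference distribution of max T with early stopping: once
// `count` (permutations with max T >= t_obs) reaches kstop, the permutation
// p-value can no longer fall below the significance level, so the scan
// aborts. Uses R's RNG; deterministic under set.seed().
// [[Rcpp::export(name = ".cbs_perm_count")]]
IntegerVector cbs_perm_count_cpp(NumericVector x, int nperm, double t_obs,
                                 int kstop) {
  const int n = (int)x.size();
  std::vector<double> v(x.begin(), x.end());
  RNGScope scope;
  int count = 0, done = 0;
  int bi, bj;
  for (int p = 0; p < nperm; ++p) {
    // Fisher-Yates shuffle in place
    for (int t = n - 1; t > 0; --t) {
      int w = (int)std::floor(unif_rand() * (t + 1));
      if (w > t) w = t;
      std::swap(v[t], v[w]);
    }
    double tp = max_t_scan(v, &bi, &bj);
    if (tp >= t_obs) ++count;
    ++done;
    if (count >= kstop) break;
  }
  return IntegerVector::create(count, done);
}
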