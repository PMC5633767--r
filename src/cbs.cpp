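#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Circular binary segmentation core.
//
// For a segment x[0..n-1] consider every circular arc of width w
// (min_width <= w <= n - min_width). The two-sample t statistic between the
// arc and its complement is monotone in u = D^2 * w * (n - w) / n where
// D is the difference of the two means, so maximising u maximises |t| and,
// crucially, u can be compared against a fixed threshold without computing
// t at all: t^2 = (n - 2) * u / (SStot - u). Under permutation SStot is
// invariant, so exceedance tests reduce to u >= u_obs.

static double max_u_scan(const std::vector<double> &P, int n, int min_width,
                         double abort_u, int *best_i, int *best_j) {
  const double T = P[n];
  double best_u = -1.0;
  int bi = -1, bj = -1;
  for (int w = min_width; w <= n - min_width; ++w) {
    // max and min window sum of width w
    double smax = -HUGE_VAL, smin = HUGE_VAL;
    int imax = 0, imin = 0;
    for (int i = 0; i + w <= n; ++i) {
      const double s = P[i + w] - P[i];
      if (s > smax) { smax = s; imax = i; }
      if (s < smin) { smin = s; imin = i; }
    }
    const double h = (double)w * (double)(n - w) / (double)n;
    for (int k = 0; k < 2; ++k) {
      const double s = k == 0 ? smax : smin;
      const int i = k == 0 ? imax : imin;
      const double d = s / w - (T - s) / (n - w);
      const double u = d * d * h;
      if (u > best_u) { best_u = u; bi = i; bj = i + w; }
      if (abort_u >= 0.0 && u >= abort_u) {
        if (best_i) *best_i = bi;
        if (best_j) *best_j = bj;
        return best_u;
      }
    }
  }
  if (best_i) *best_i = bi;
  if (best_j) *best_j = bj;
  return best_u;
}

static double sstot(const NumericVector &x) {
  const int n = x.size();
  double m = 0.0;
  for (int i = 0; i < n; ++i) m += x[i];
  m /= n;
  double ss = 0.0;
  for (int i = 0; i < n; ++i) ss += (x[i] - m) * (x[i] - m);
  return ss;
}

static std::vector<double> prefix(const NumericVector &x) {
  std::vector<double> P(x.size() + 1, 0.0);
  for (int i = 0; i < x.size(); ++i) P[i + 1] = P[i] + x[i];
  return P;
}

// Best circular arc of x. Returns t (possibly Inf), u, and the arc
// boundaries i < j as 0-based cut positions (breakpoints after x[i-1] and
// x[j-1]; i == 0 or j == n means the cut touches the segment edge).
// [[Rcpp::export]]
List cbs_best_arc(NumericVector x, int min_width) {
  const int n = x.size();
  if (n < 2 * min_width)
    return List::create(_["t"] = 0.0, _["u"] = 0.0, _["i"] = 0, _["j"] = n);
  const double ss = sstot(x);
  if (ss <= 1e-12 * n)
    return List::create(_["t"] = 0.0, _["u"] = 0.0, _["i"] = 0, _["j"] = n);
  std::vector<double> P = prefix(x);
  int bi, bj;
  const double u = max_u_scan(P, n, min_width, -1.0, &bi, &bj);
  double t;
  const double rem = ss - u;
  if (rem <= 1e-10 * ss)
    t = R_PosInf;
  else
    t = std::sqrt((n - 2) * u / rem);
  return List::create(_["t"] = t, _["u"] = u, _["i"] = bi, _["j"] = bj);
}

// Permutation p-value for the observed max arc statistic u_obs, with
// sequential early stopping:
//  * stop "not significant" once the exceedance count passes
//    floor(alpha * n_perm), or once it is implausibly high for p <= alpha
//    (>= 5 exceedances and more than 3 binomial SDs above alpha * m);
//  * individual permutation scans abort as soon as any arc reaches u_obs.
// Uses R's RNG so results are reproducible under set.seed().
// [[Rcpp::export]]
List cbs_perm_test(NumericVector x, int min_width, double u_obs, int n_perm,
                   double alpha) {
  const int n = x.size();
  RNGScope scope;
  std::vector<double> v(x.begin(), x.end());
  const int hard_stop = (int)std::floor(alpha * n_perm);
  int exceed = 0, m = 0;
  for (int b = 0; b < n_perm; ++b) {
    // Fisher-Yates shuffle with R's RNG
    for (int i = n - 1; i > 0; --i) {
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(v[i], v[j]);
    }
    std::vector<double> P(n + 1, 0.0);
    for (int i = 0; i < n; ++i) P[i + 1] = P[i] + v[i];
    const double u = max_u_scan(P, n, min_width, u_obs, NULL, NULL);
    ++m;
    if (u >= u_obs) {
      ++exceed;
      if (exceed > hard_stop)
        return List::create(_["p"] = (double)exceed / m, _["n_perm"] = m,
                            _["exceed"] = exceed);
      if (exceed >= 5 &&
          exceed > alpha * m + 3.0 * std::sqrt(m * alpha * (1.0 - alpha)))
        return List::create(_["p"] = (double)exceed / m, _["n_perm"] = m,
                            _["exceed"] = exceed);
    }
  }
  return List::create(_["p"] = (double)exceed / n_perm, _["n_perm"] = n_perm,
                      _["exceed"] = exceed);
}
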