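#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Path (open tour) 2-opt refinement for marker seriation.
// d is a symmetric dissimilarity matrix (no NAs), ord a 1-based order.
// Repeatedly reverses sub-paths while the sum of adjacent dissimilarities
// decreases; returns the improved 1-based order.
// [[Rcpp::export]]
IntegerVector two_opt_path(NumericMatrix d, IntegerVector ord, int max_passes) {
  const int k = ord.size();
  std::vector<int> o(k);
  for (int i = 0; i < k; ++i) o[i] = ord[i] - 1;
  if (k < 3) return ord;
  bool improved = true;
  int pass = 0;
  while (improved && pass++ < max_passes) {
    improved = false;
    for (int i = 0; i < k - 1; ++i) {
      for (int j = i + 1; j < k; ++j) {
        // reverse o[i..j]; edges change at (i-1,i) and (j,j+1)
        double before = 0.0, after = 0.0;
        if (i > 0) {
          before += d(o[i - 1], o[i]);
          after += d(o[i - 1], o[j]);
        }
        if (j < k - 1) {
          before += d(o[j], o[j + 1]);
          after += d(o[i], o[j + 1]);
        }
        if (after < before - 1e-12) {
          for (int a = i, b = j; a < b; ++a, --b) std::swap(o[a], o[b]);
          improved = true;
        }
      }
    }
  }
  IntegerVector out(k);
  for (int i = 0; i < k; ++i) out[i] = o[i] + 1;
  return out;
}

// Or-opt refinement: relocate segments of length 1-3 to any other position
// (optionally reversed) while the path cost decreases. Complements 2-opt,
// which cannot move a single misplaced element.
// [[Rcpp::export]]
IntegerVector or_opt_path(NumericMatrix d, IntegerVector ord, int max_passes) {
  const int k = ord.size();
  std::vector<int> o(k);
  for (int i = 0; i < k; ++i) o[i] = ord[i] - 1;
  if (k < 4) return ord;
  auto edge = [&](int a, int b) -> double {
    if (a < 0 || b < 0 || a >= k || b >= k) return 0.0;
    return d(o[a], o[b]);
  };
  bool improved = true;
  int pass = 0;
  while (improved && pass++ < max_passes) {
    improved = false;
    for (int len = 1; len <= 3 && len < k; ++len) {
      for (int i = 0; i + len <= k; ++i) {
        const int j = i + len - 1;  // segment o[i..j]
        const double removed = edge(i - 1, i) + edge(j, j + 1) -
          ((i > 0 && j < k - 1) ? d(o[i - 1], o[j + 1]) : 0.0);
        // try inserting between p and p+1 (p outside segment)
        for (int p = -1; p < k; ++p) {
          if (p >= i - 1 && p <= j) continue;
          double base = (p >= 0 && p + 1 < k) ? d(o[p], o[p + 1]) : 0.0;
          for (int rev = 0; rev < 2; ++rev) {
            const int hd = rev ? o[j] : o[i], tl = rev ? o[i] : o[j];
            double added = base;
            added = -base;
            if (p >= 0) added += d(o[p], hd);
            if (p + 1 < k) added += d(tl, o[p + 1]);
            if (added < removed - 1e-12) {
              std::vector<int> seg(o.begin() + i, o.begin() + j + 1);
              if (rev) std::reverse(seg.begin(), seg.end());
              std::vector<int> rest;
              rest.reserve(k - len);
              for (int q = 0; q < k; ++q)
                if (q < i || q > j) rest.push_back(o[q]);
              int ins = p;
              if (p > j) ins = p - len;  // index shift after removal
              std::vector<int> neu;
              neu.reserve(k);
              for (int q = 0; q <= ins; ++q) neu.push_back(rest[q]);
              for (int v : seg) neu.push_back(v);
              for (int q = ins + 1; q < (int)rest.size(); ++q)
                neu.push_back(rest[q]);
              o = neu;
              improved = true;
              rev = 2; p = k;  // restart scanning from the modified path
            }
          }
        }
        if (improved) break;
      }
      if (improved) break;
    }
  }
  IntegerVector out(k);
  for (int i = 0; i < k; ++i) out[i] = o[i] + 1;
  return out;
}

// Sum of adjacent dissimilarities along a 1-based order.
// [[Rcpp::export]]
double path_cost(NumericMatrix d, IntegerVector ord) {
  double s = 0.0;
  for (int i = 1; i < ord.size(); ++i) s += d(ord[i - 1] - 1, ord[i] - 1);
  return s;
}
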