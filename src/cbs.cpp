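#include <Rcpp.h>
using namespace Rcpp;

// Maximal circular arc two-sample t-statistic for a profile segment.
//
// For every arc (i, j] (0 <= i < j <= n, arc length k within
// [min_width, n - min_width]) compare the arc mean m1 against the mean m2
// of its complement with the pooled-variance two-sample t-statistic
//   T(i,j) = (m1 - m2) / (s_p * sqrt(1/k + 1/(n-k))),
//   s_p^2  = (SS - k*m1^2 - (n-k)*m2^2) / (n - 2).
// A variance floor guards the perfect-separation case (noise-free step),
// where the pooled variance is exactly zero. Arcs wrapping the segment
// end are complements of non-wrapping arcs and share |T|, so scanning
// non-wrapping arcs is exhaustive.
static double max_arc_stat(const double *x, int n, int min_width,
                           int *best_i, int *best_j) {
  std::vector<double> s(n + 1), s2(n + 1);
  s[0] = s2[0] = 0.0;
  for (int t = 0; t < n; ++t) {
    s[t + 1] = s[t] + x[t];
    s2[t + 1] = s2[t] + x[t] * x[t];
  }
  const double total = s[n], ss = s2[n];
  double best = -1.0;
  int bi = -1, bj = -1;
  for (int k = min_width; k <= n - min_width; ++k) {
    const double w = 1.0 / k + 1.0 / (n - k);
    for (int i = 0; i + k <= n; ++i) {
      const int j = i + k;
      const double arc = s[j] - s[i];
      const double m1 = arc / k;
      const double m2 = (total - arc) / (n - k);
      double v = (ss - k * m1 * m1 - (n - k) * m2 * m2) / (n - 2);
      if (v < 1e-12) v = 1e-12;
      const double t = (m1 - m2) / std::sqrt(v * w);
      const double at = std::fabs(t);
      if (at > best + 1e-12) {
        best = at;
        bi = i;
        bj = j;
      }
    }
  }
  if (best_i) *best_i = bi;
  if (best_j) *best_j = bj;
  return best;
}

// [[Rcpp::export]]
List cpp_cbs_scan(NumericVector x, int min_width) {
  int n = x.size();
  if (n < 2 * min_width || n < 3)
    return List::create(_["i"] = -1, _["j"] = -1, _["stat"] = 0.0);
  int bi, bj;
  double stat = max_arc_stat(x.begin(), n, min_width, &bi, &bj);
  return List::create(_["i"] = bi, _["j"] = bj, _["stat"] = stat);
}

// Permutation reference for the max arc statistic. Returns the number of
// permutations whose maximal statistic reaches `observed`; stops early
// once `count_limit` exceedances are seen (the split is then already
// rejected at the caller's alpha).
// [[Rcpp::export]]
int cpp_cbs_perm_count(NumericVector x, double observed, int n_perm,
                       int min_width, int count_limit) {
  int n = x.size();
  std::vector<double> y(x.begin(), x.end());
  int count = 0;
  for (int p = 0; p < n_perm; ++p) {
    for (int k = n - 1; k > 0; --k) {
      int r = (int)(unif_rand() * (k + 1));
      if (r > k) r = k;
      std::swap(y[k], y[r]);
    }
    double m = max_arc_stat(y.data(), n, min_width, NULL, NULL);
    if (m >= observed - 1e-12) {
      if (++count >= count_limit) return count;
    }
  }
  return count;
}
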