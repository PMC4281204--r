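#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Circular binary segmentation split statistic.
//
// For a series x[0..n-1] viewed as a circle, every arc (i, j] (0 <= i < j <= n,
// taken on the linearised series; wrapped arcs are the complements of these and
// give the same statistic) is compared against its complement with the
// two-sample statistic
//
//   T(i,j) = | S_j - S_i - (l/n) S_n | / sqrt( l (n - l) / n ),  l = j - i,
//
// which is the mean-shift statistic with the common variance factored out
// (permutations keep S_n and n fixed, so the omitted sigma is irrelevant).
// Both the arc and its complement must hold at least min_width probes.

static void cbs_max_stat_core(const std::vector<double>& S, int n,
                              int min_width, double& best, int& bi, int& bj) {
  best = -1.0;
  bi = 0;
  bj = n;
  const double Sn = S[n];
  for (int l = min_width; l <= n - min_width; ++l) {
    const double inv_denom = 1.0 / std::sqrt((double)l * (n - l) / n);
    const double c = (double)l / n * Sn;
    const int imax = n - l;
    for (int i = 0; i <= imax; ++i) {
      double d = std::fabs(S[i + l] - S[i] - c) * inv_denom;
      if (d > best) {  // strict: leftmost/shortest-arc tie-break
        best = d;
        bi = i;
        bj = i + l;
      }
    }
  }
}

static void prefix_sums(const std::vector<double>& x, std::vector<double>& S) {
  const int n = (int)x.size();
  S.resize(n + 1);
  S[0] = 0.0;
  for (int i = 0; i < n; ++i) S[i + 1] = S[i] + x[i];
}

// [[Rcpp::export(name = ".cbs_max_stat")]]
List cbs_max_stat(NumericVector x, int min_width) {
  const int n = x.size();
  if (n < 2 * min_width) {
    return List::create(_["stat"] = 0.0, _["i"] = 0, _["j"] = n);
  }
  std::vector<double> xs(x.begin(), x.end()), S;
  prefix_sums(xs, S);
  double best;
  int bi, bj;
  cbs_max_stat_core(S, n, min_width, best, bi, bj);
  return List::create(_["stat"] = best, _["i"] = bi, _["j"] = bj);
}

// Permutation test for the best split of x, with sequential early stopping:
//  * not-significant stop: once exceedances reach h = floor(alpha*n_perm) + 1
//    the p-value can no longer fall below alpha (Besag-Clifford estimate
//    p = k/m at the stopping time);
//  * significant stop: if no permutation exceeds the observed statistic after
//    m0 = ceil(1/alpha) draws, p = (0+1)/(m0+1) < alpha already.
// Otherwise all n_perm draws run and p = (k+1)/(n_perm+1).
// Uses R's RNG (seed from the calling R session).
// [[Rcpp::export(name = ".cbs_split_test")]]
List cbs_split_test(NumericVector x, int min_width, int n_perm, double alpha) {
  const int n = x.size();
  if (n < 2 * min_width) {
    return List::create(_["stat"] = 0.0, _["i"] = 0, _["j"] = n,
                        _["p"] = 1.0, _["n_perm_used"] = 0);
  }
  std::vector<double> xs(x.begin(), x.end()), S;
  prefix_sums(xs, S);
  double obs;
  int bi, bj;
  cbs_max_stat_core(S, n, min_width, obs, bi, bj);
  if (!(obs > 1e-12)) {  // flat series (constant input): nothing to split
    return List::create(_["stat"] = obs, _["i"] = bi, _["j"] = bj,
                        _["p"] = 1.0, _["n_perm_used"] = 0);
  }

  const int h = (int)std::floor(alpha * n_perm) + 1;
  const int m0 = (int)std::ceil(1.0 / alpha);
  int exceed = 0, m = 0;
  double p = 1.0;
  std::vector<double> perm(xs), Sp;
  RNGScope scope;
  for (m = 1; m <= n_perm; ++m) {
    // Fisher-Yates shuffle with R's RNG
    for (int k = n - 1; k > 0; --k) {
      int r = (int)(unif_rand() * (k + 1));
      if (r > k) r = k;
      std::swap(perm[k], perm[r]);
    }
    prefix_sums(perm, Sp);
    double pbest;
    int pi, pj;
    cbs_max_stat_core(Sp, n, min_width, pbest, pi, pj);
    if (pbest >= obs) ++exceed;
    if (exceed >= h) {  // cannot become significant
      p = (double)exceed / m;
      return List::create(_["stat"] = obs, _["i"] = bi, _["j"] = bj,
                          _["p"] = p, _["n_perm_used"] = m);
    }
    if (m >= m0 && exceed == 0) {  // already significant
      p = 1.0 / (m + 1);
      return List::create(_["stat"] = obs, _["i"] = bi, _["j"] = bj,
                          _["p"] = p, _["n_perm_used"] = m);
    }
  }
  p = (double)(exceed + 1) / (n_perm + 1);
  return List::create(_["stat"] = obs, _["i"] = bi, _["j"] = bj,
                      _["p"] = p, _["n_perm_used"] = n_perm);
}
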