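#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Exact null p-value of the minimum hypergeometric (mHG) statistic.
//
// Null model: the B labelled items are uniformly placed among the N ranks.
// A placement is "rejected" if any prefix of length n in 1..N-1 has a
// hypergeometric upper-tail probability <= stat (up to a relative
// tolerance absorbing floating-point jitter between routes that compute
// the same tail).  The walk over the (ranks seen, labels seen) lattice is
// carried in probability space: w[b] holds the null probability mass of
// paths that have reached b labels without ever entering the rejection
// region.  Rejected mass is accumulated directly, so small p-values are
// computed without cancellation; masses are probabilities (<= 1), so no
// rescaling against overflow is needed, and underflow of surviving mass
// only occurs when p is numerically 1.
//
// [[Rcpp::export]]
double mhg_dp_pvalue_cpp(double stat, int N, int B, double rel_tol) {
  if (N < 1 || B < 1 || B > N)
    stop("mhg_dp_pvalue_cpp: require 1 <= B <= N");
  if (stat >= 1.0) return 1.0;
  const double s = stat * (1.0 + rel_tol);

  // log-factorial table for hypergeometric tails
  std::vector<double> lgf(N + 1);
  lgf[0] = 0.0;
  for (int i = 1; i <= N; ++i) lgf[i] = lgf[i - 1] + std::log((double) i);
  auto lchoose = [&](int n, int k) -> double {
    return lgf[n] - lgf[k] - lgf[n - k];
  };

  std::vector<double> w(B + 1, 0.0);
  w[0] = 1.0;
  double rejected = 0.0;

  for (int n = 1; n <= N; ++n) {
    const int bmax = std::min(n, B);
    const double remaining = (double) (N - (n - 1));
    // transition from prefix n-1 to prefix n (iterate b downwards so that
    // w[b-1] still holds the previous step's mass)
    for (int b = bmax; b >= 0; --b) {
      double acc = 0.0;
      if (b >= 1 && b - 1 <= std::min(n - 1, B))
        acc += w[b - 1] * (double) (B - (b - 1)) / remaining;
      if (b <= std::min(n - 1, B))
        acc += w[b] * (remaining - (double) (B - b)) / remaining;
      w[b] = acc;
    }
    if (n <= N - 1) {
      // rejection region at this prefix: b >= bmin where bmin is the
      // smallest label count whose upper tail P(X >= b) <= s; the tail is
      // decreasing in b, so scan from bmax downwards while it stays small
      const int kmin = std::max(0, n - (N - B));
      double tail = 0.0;
      int bmin = bmax + 1;
      const double lden = lchoose(N, n);
      for (int b = bmax; b >= kmin; --b) {
        tail += std::exp(lchoose(B, b) + lchoose(N - B, n - b) - lden);
        if (tail <= s) bmin = b; else break;
      }
      for (int b = bmin; b <= bmax; ++b) {
        rejected += w[b];
        w[b] = 0.0;
      }
    }
  }

  if (rejected > 1.0) rejected = 1.0;
  if (rejected < 0.0) rejected = 0.0;
  return rejected;
}
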