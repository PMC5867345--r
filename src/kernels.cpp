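#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Heavy O(n^2) kernels for the nonlinear descriptors. All distances are
// Chebyshev (max-norm) on delay embeddings except the Rosenstein neighbour
// search, which uses the Euclidean norm as in the original method.

// Template-match log-frequency Phi_m(r) of Pincus' approximate entropy,
// self-matches included.
static double apen_phi(const NumericVector& x, int m, double r) {
  int n = x.size();
  int N = n - m + 1;
  double acc = 0.0;
  for (int i = 0; i < N; ++i) {
    int cnt = 0;
    for (int j = 0; j < N; ++j) {
      double d = 0.0;
      for (int k = 0; k < m; ++k) {
        double dk = std::fabs(x[i + k] - x[j + k]);
        if (dk > d) d = dk;
        if (d > r) break;
      }
      if (d <= r) ++cnt;
    }
    acc += std::log((double)cnt / (double)N);
  }
  return acc / (double)N;
}

// [[Rcpp::export]]
double apen_cpp(NumericVector x, int m, double r) {
  return apen_phi(x, m, r) - apen_phi(x, m + 1, r);
}

// Correlation sums C_m(eps) for m = 1..mmax on a delay embedding with lag
// tau, excluding pairs closer in time than the Theiler window. eps must be
// sorted increasing. Returns an mmax x length(eps) matrix; row m holds the
// fraction of admissible pairs with Chebyshev distance < eps among vectors
// embedded at dimension m.
// [[Rcpp::export]]
NumericMatrix corr_sums_cpp(NumericVector x, int tau, int mmax,
                            NumericVector eps, int theiler) {
  int n = x.size();
  int ne = eps.size();
  NumericMatrix hist(mmax, ne);      // counts of pairs with d in (eps[k-1], eps[k]] bins
  std::vector<double> npairs(mmax, 0.0);

  for (int i = 0; i < n; ++i) {
    for (int j = i + theiler + 1; j < n; ++j) {
      double d = 0.0;
      for (int m = 1; m <= mmax; ++m) {
        int ii = i + (m - 1) * tau, jj = j + (m - 1) * tau;
        if (jj >= n) break;          // j is the larger index
        double dk = std::fabs(x[ii] - x[jj]);
        if (dk > d) d = dk;
        npairs[m - 1] += 1.0;
        // first eps strictly greater than d (strict inequality d < eps)
        int lo = 0, hi = ne;
        while (lo < hi) { int mid = (lo + hi) / 2; if (eps[mid] > d) hi = mid; else lo = mid + 1; }
        if (lo < ne) hist(m - 1, lo) += 1.0;
      }
    }
  }
  // cumulate bins into C_m(eps) and normalise
  for (int m = 0; m < mmax; ++m) {
    double run = 0.0;
    for (int k = 0; k < ne; ++k) {
      run += hist(m, k);
      hist(m, k) = npairs[m] > 0 ? run / npairs[m] : NA_REAL;
    }
  }
  return hist;
}

// Rosenstein mean log-divergence curve. Embeds x at dimension m, lag tau;
// for each reference point finds its Euclidean nearest neighbour at temporal
// distance > theiler, then tracks log distance over 0..tmax steps.
// Returns the curve of mean log divergence (natural log); entries with no
// contributing pair are NA. Distances below floor_d are clamped to floor_d
// (resolution limit).
// [[Rcpp::export]]
NumericVector rosenstein_cpp(NumericVector x, int m, int tau, int theiler,
                             int tmax, double floor_d) {
  int n = x.size();
  int N = n - (m - 1) * tau;
  if (N < theiler + 2) return NumericVector(0);
  std::vector<int> nn(N, -1);
  for (int i = 0; i < N; ++i) {
    double best = R_PosInf;
    for (int j = 0; j < N; ++j) {
      if (std::abs(i - j) <= theiler) continue;
      double d2 = 0.0;
      for (int k = 0; k < m; ++k) {
        double dk = x[i + k * tau] - x[j + k * tau];
        d2 += dk * dk;
        if (d2 >= best) break;
      }
      if (d2 < best) { best = d2; nn[i] = j; }
    }
  }
  NumericVector curve(tmax + 1);
  IntegerVector cnt(tmax + 1);
  double f2 = floor_d * floor_d;
  for (int i = 0; i < N; ++i) {
    int j = nn[i];
    if (j < 0) continue;
    for (int t = 0; t <= tmax; ++t) {
      if (i + t >= N || j + t >= N) break;
      double d2 = 0.0;
      for (int k = 0; k < m; ++k) {
        double dk = x[i + t + k * tau] - x[j + t + k * tau];
        d2 += dk * dk;
      }
      if (d2 < f2) d2 = f2;
      curve[t] += 0.5 * std::log(d2); cnt[t] += 1;
    }
  }
  for (int t = 0; t <= tmax; ++t)
    curve[t] = cnt[t] > 0 ? curve[t] / cnt[t] : NA_REAL;
  return curve;
}
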