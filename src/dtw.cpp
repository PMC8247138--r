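// Dynamic time warping distances between rows of a series matrix.
// Classic O(T^2) dynamic program with symmetric step pattern
// (min of insertion / deletion / match, L1 local cost) and an
// unconstrained window: with 15-point persistence profiles a band
// constraint would gain nothing.

#include <Rcpp.h>
using namespace Rcpp;

static double dtw_pair(const double* a, const double* b, int T,
                       std::vector<double>& prev,
                       std::vector<double>& curr) {
  for (int j = 0; j < T; ++j)
    prev[j] = std::abs(a[0] - b[j]) + (j > 0 ? prev[j - 1] : 0.0);
  for (int i = 1; i < T; ++i) {
    curr[0] = std::abs(a[i] - b[0]) + prev[0];
    for (int j = 1; j < T; ++j) {
      double best = std::min(prev[j], std::min(prev[j - 1], curr[j - 1]));
      curr[j] = std::abs(a[i] - b[j]) + best;
    }
    std::swap(prev, curr);
  }
  return prev[T - 1];
}

// [[Rcpp::export(name = ".dtwPairwise")]]
NumericMatrix dtwPairwise(NumericMatrix series) {
  int n = series.nrow(), T = series.ncol();
  // row-major copy so each series is contiguous
  std::vector<double> rows((size_t)n * T);
  for (int i = 0; i < n; ++i)
    for (int t = 0; t < T; ++t) rows[(size_t)i * T + t] = series(i, t);
  NumericMatrix D(n, n);
  std::vector<double> prev(T), curr(T);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double d = dtw_pair(&rows[(size_t)i * T], &rows[(size_t)j * T], T,
                          prev, curr);
      D(i, j) = d;
      D(j, i) = d;
    }
  }
  return D;
}

// [[Rcpp::export(name = ".dtwSingle")]]
double dtwSingle(NumericVector a, NumericVector b) {
  if (a.size() != b.size())
    stop("series must have equal length");
  int T = a.size();
  std::vector<double> prev(T), curr(T);
  return dtw_pair(REAL(a), REAL(b), T, prev, curr);
}
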