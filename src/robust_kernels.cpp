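#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <limits>
using namespace Rcpp;

// order statistic (1-based rank) via nth_element; v is modified
static double order_stat(std::vector<double>& v, int rank) {
  std::nth_element(v.begin(), v.begin() + (rank - 1), v.end());
  return v[rank - 1];
}

// Raw Sn statistic (no consistency constant, no finite-sample factor):
// low median over i of the high median over j != i of |x_i - x_j|.
// Inner high median of the n-1 differences: rank floor((n-1)/2) + 1.
// Outer low median of the n values: rank floor((n+1)/2).
// [[Rcpp::export]]
double cpp_sn_raw(NumericVector x) {
  int n = x.size();
  if (n < 2) stop("need at least 2 values");
  std::vector<double> hi(n);
  std::vector<double> d;
  d.reserve(n - 1);
  for (int i = 0; i < n; ++i) {
    d.clear();
    for (int j = 0; j < n; ++j)
      if (j != i) d.push_back(std::abs(x[i] - x[j]));
    hi[i] = order_stat(d, (n - 1) / 2 + 1);
  }
  return order_stat(hi, (n + 1) / 2);
}

// k-th smallest (1-based) of the union of two ascending virtual arrays.
template <typename FA, typename FB>
static double kth_union(int na, int nb, int k, FA A, FB B) {
  int lo = std::max(0, k - nb), hi = std::min(k, na);
  while (lo < hi) {
    int cutA = (lo + hi) / 2;
    int cutB = k - cutA;
    if (cutA < na && cutB > 0 && B(cutB - 1) > A(cutA)) {
      lo = cutA + 1;
    } else if (cutA > 0 && cutB < nb && A(cutA - 1) > B(cutB)) {
      hi = cutA - 1;
    } else {
      lo = hi = cutA;
    }
  }
  int cutA = lo, cutB = k - cutA;
  double best = -std::numeric_limits<double>::infinity();
  if (cutA > 0) best = std::max(best, A(cutA - 1));
  if (cutB > 0) best = std::max(best, B(cutB - 1));
  return best;
}

// O(n log n) Sn statistic: for sorted x the distances from x_i to its left
// and right neighbours form two ascending sequences, so each inner high
// median is a rank selection over two sorted virtual arrays.
// [[Rcpp::export]]
double cpp_sn_raw_fast(NumericVector xx) {
  int n = xx.size();
  if (n < 2) stop("need at least 2 values");
  std::vector<double> x(xx.begin(), xx.end());
  std::sort(x.begin(), x.end());
  int k = (n - 1) / 2 + 1;  // high-median rank among the n-1 distances
  std::vector<double> hi(n);
  for (int i = 0; i < n; ++i) {
    int na = i, nb = n - 1 - i;
    auto A = [&x, i](int m) { return x[i] - x[i - 1 - m]; };
    auto B = [&x, i](int m) { return x[i + 1 + m] - x[i]; };
    hi[i] = kth_union(na, nb, k, A, B);
  }
  return order_stat(hi, (n + 1) / 2);
}

// All pairwise slopes (y_j - y_i) / (x_j - x_i), i < j, skipping ties in x.
// [[Rcpp::export]]
NumericVector cpp_pairwise_slopes(NumericVector x, NumericVector y) {
  int n = x.size();
  std::vector<double> s;
  s.reserve((size_t)n * (n - 1) / 2);
  for (int i = 0; i < n - 1; ++i)
    for (int j = i + 1; j < n; ++j)
      if (x[j] != x[i]) s.push_back((y[j] - y[i]) / (x[j] - x[i]));
  return wrap(s);
}

// All Walsh averages (x_i + x_j)/2, i <= j (singletons included).
// [[Rcpp::export]]
NumericVector cpp_walsh_averages(NumericVector x) {
  int n = x.size();
  NumericVector w((size_t)n * (n + 1) / 2);
  size_t k = 0;
  for (int i = 0; i < n; ++i)
    for (int j = i; j < n; ++j)
      w[k++] = (x[i] + x[j]) / 2.0;
  return w;
}
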