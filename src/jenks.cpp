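#include <Rcpp.h>
#include <limits>
using namespace Rcpp;

// Exact Fisher-Jenks dynamic program: partition the sorted values x into k
// contiguous classes minimising the total within-class sum of squared
// deviations. Returns the 1-based index of the last element of each of the
// first k-1 classes. O(k * n^2) with O(1) interval cost via prefix sums.
// [[Rcpp::export(name = ".fisherJenksDP")]]
IntegerVector fisherJenksDP(NumericVector x, int k) {
  const int n = x.size();
  if (k < 2) stop("k must be >= 2");
  if (n < k) stop("need at least k values");
  std::vector<double> s(n + 1, 0.0), s2(n + 1, 0.0);
  for (int i = 0; i < n; ++i) {
    s[i + 1] = s[i] + x[i];
    s2[i + 1] = s2[i] + x[i] * x[i];
  }
  auto cost = [&](int i, int j) {  // SSD of x[i..j], 0-based inclusive
    const int m = j - i + 1;
    const double sum = s[j + 1] - s[i];
    return s2[j + 1] - s2[i] - sum * sum / m;
  };
  const double inf = std::numeric_limits<double>::infinity();
  // D[m][j]: minimal cost of splitting x[0..j] into m classes
  std::vector<std::vector<double>> D(k + 1, std::vector<double>(n, inf));
  std::vector<std::vector<int>> back(k + 1, std::vector<int>(n, -1));
  for (int j = 0; j < n; ++j) D[1][j] = cost(0, j);
  for (int m = 2; m <= k; ++m) {
    for (int j = m - 1; j < n; ++j) {
      for (int i = m - 1; i <= j; ++i) {
        const double c = D[m - 1][i - 1] + cost(i, j);
        if (c < D[m][j]) { D[m][j] = c; back[m][j] = i; }
      }
    }
  }
  IntegerVector breaks(k - 1);
  int j = n - 1;
  for (int m = k; m >= 2; --m) {
    const int i = back[m][j];        // class m starts at i
    breaks[m - 2] = i;               // last index of class m-1, 1-based
    j = i - 1;
  }
  return breaks;
}
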