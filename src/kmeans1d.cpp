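#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Exact weighted 1D k-means: minimal within-cluster sum of squares over
// partitions of the sorted values into C contiguous runs, by dynamic
// programming with divide-and-conquer split-point optimization (the cost
// matrix is totally monotone), O(C n log n).
// x must be sorted ascending and strictly increasing; w > 0.

struct Prefix {
  std::vector<double> W, WX, WX2;
  explicit Prefix(const NumericVector& x, const NumericVector& w) {
    int n = x.size();
    W.assign(n + 1, 0.0);
    WX.assign(n + 1, 0.0);
    WX2.assign(n + 1, 0.0);
    for (int i = 0; i < n; ++i) {
      W[i + 1] = W[i] + w[i];
      WX[i + 1] = WX[i] + w[i] * x[i];
      WX2[i + 1] = WX2[i] + w[i] * x[i] * x[i];
    }
  }
  // weighted SSQ of run [i..j] (0-based, inclusive) about its mean
  double cost(int i, int j) const {
    double ww = W[j + 1] - W[i];
    double s = WX[j + 1] - WX[i];
    double s2 = WX2[j + 1] - WX2[i];
    double c = s2 - s * s / ww;
    return c > 0.0 ? c : 0.0;
  }
  double mean(int i, int j) const {
    return (WX[j + 1] - WX[i]) / (W[j + 1] - W[i]);
  }
};

static void solve_level(const Prefix& P, const std::vector<double>& Dprev,
                        std::vector<double>& Dcur, std::vector<int>& split,
                        int k, int jlo, int jhi, int ilo, int ihi) {
  if (jlo > jhi) return;
  int jm = jlo + (jhi - jlo) / 2;
  int lo = std::max(ilo, k - 2);      // previous level used >= k-1 points
  int hi = std::min(ihi, jm - 1);
  double best = R_PosInf;
  int arg = lo;
  for (int i = lo; i <= hi; ++i) {
    double v = Dprev[i] + P.cost(i + 1, jm);
    if (v < best) {                   // ties keep the smallest split
      best = v;
      arg = i;
    }
  }
  Dcur[jm] = best;
  split[jm] = arg;
  solve_level(P, Dprev, Dcur, split, k, jlo, jm - 1, ilo, arg);
  solve_level(P, Dprev, Dcur, split, k, jm + 1, jhi, arg, ihi);
}

// [[Rcpp::export]]
List kmeans_dp_cpp(NumericVector x, NumericVector w, int C) {
  int n = x.size();
  if (C < 1 || C > n) stop("C must lie in 1..length(x)");
  Prefix P(x, w);
  std::vector<double> Dprev(n), Dcur(n);
  std::vector<std::vector<int> > splits(C);  // splits[k-1][j] for level k
  for (int j = 0; j < n; ++j) Dprev[j] = P.cost(0, j);
  for (int k = 2; k <= C; ++k) {
    splits[k - 1].assign(n, 0);
    solve_level(P, Dprev, Dcur, splits[k - 1], k, k - 1, n - 1, k - 2, n - 2);
    std::swap(Dprev, Dcur);
  }
  // reconstruct cluster boundaries and weighted means
  NumericVector centers(C);
  IntegerVector sizes(C);
  int j = n - 1;
  for (int k = C; k >= 1; --k) {
    int i = (k == 1) ? 0 : splits[k - 1][j] + 1;
    centers[k - 1] = P.mean(i, j);
    sizes[k - 1] = j - i + 1;
    j = i - 1;
  }
  return List::create(_["centers"] = centers, _["wss"] = Dprev[n - 1],
                      _["sizes"] = sizes);
}
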