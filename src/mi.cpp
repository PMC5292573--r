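#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Kraskov, Stoegbauer & Grassberger algorithm 1: max-norm in the joint
// space; marginal neighbour counts use the strict inequality.
// [[Rcpp::export]]
double kraskov_mi_cpp(NumericVector x, NumericVector y, int k) {
  const int n = x.size();
  std::vector<double> d(n), tmp(n);
  double acc = 0.0;
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) {
      double dx = std::fabs(x[i] - x[j]);
      double dy = std::fabs(y[i] - y[j]);
      d[j] = dx > dy ? dx : dy;
    }
    d[i] = R_PosInf;
    tmp = d;
    std::nth_element(tmp.begin(), tmp.begin() + (k - 1), tmp.end());
    const double eps = tmp[k - 1];
    int nx = 0, ny = 0;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      if (std::fabs(x[i] - x[j]) < eps) ++nx;
      if (std::fabs(y[i] - y[j]) < eps) ++ny;
    }
    acc += R::digamma((double)(nx + 1)) + R::digamma((double)(ny + 1));
  }
  return R::digamma((double)k) + R::digamma((double)n) - acc / n;
}

// Kozachenko-Leonenko nearest-neighbour differential entropy (1-D):
// H = psi(N) - psi(k) + mean(log(2 * r_i)), r_i = k-th neighbour distance.
// [[Rcpp::export]]
double kl_entropy_cpp(NumericVector x, int k) {
  const int n = x.size();
  std::vector<double> d(n);
  double acc = 0.0;
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) d[j] = std::fabs(x[i] - x[j]);
    d[i] = R_PosInf;
    std::nth_element(d.begin(), d.begin() + (k - 1), d.end());
    acc += std::log(2.0 * d[k - 1]);
  }
  return R::digamma((double)n) - R::digamma((double)k) + acc / n;
}
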