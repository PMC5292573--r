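#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Neighbour-distance statistics for the generalized-synchronization
// indices.  For each reference state i the admissible set excludes the
// state itself and every state whose origin time lies within `theiler`
// samples.  Distance ties are broken stably by state index.

struct DistIdx {
  double d;
  int j;
  bool operator<(const DistIdx& o) const {
    if (d != o.d) return d < o.d;
    return j < o.j;
  }
};

static void own_neighbors(const NumericMatrix& X, const IntegerVector& orig,
                          int k, int theiler, IntegerMatrix& own) {
  const int nv = X.nrow(), m = X.ncol();
  std::vector<DistIdx> adm;
  adm.reserve(nv);
  for (int i = 0; i < nv; ++i) {
    adm.clear();
    for (int j = 0; j < nv; ++j) {
      if (j == i || std::abs(orig[j] - orig[i]) <= theiler) continue;
      double s = 0.0;
      for (int c = 0; c < m; ++c) {
        double d = X(i, c) - X(j, c);
        s += d * d;
      }
      adm.push_back({std::sqrt(s), j});
    }
    std::partial_sort(adm.begin(), adm.begin() + k, adm.end());
    for (int q = 0; q < k; ++q) own(i, q) = adm[q].j;
  }
}

// [[Rcpp::export]]
List gs_stats_cpp(NumericMatrix X, NumericMatrix Y, IntegerVector origins,
                  int k, int theiler) {
  const int nv = X.nrow(), m = X.ncol();
  IntegerMatrix ownY(nv, k);
  own_neighbors(Y, origins, k, theiler, ownY);

  NumericVector R_knn(nv), R_all(nv), R_cond(nv), G_cond(nv), G_knn(nv),
      G_all(nv);
  IntegerMatrix ownX(nv, k);
  std::vector<DistIdx> adm;
  std::vector<double> distX(nv);
  std::vector<double> rankpos(nv);
  adm.reserve(nv);

  for (int i = 0; i < nv; ++i) {
    adm.clear();
    double sum_all = 0.0;
    for (int j = 0; j < nv; ++j) {
      if (j == i || std::abs(origins[j] - origins[i]) <= theiler) {
        distX[j] = R_NegInf;  // inadmissible marker
        continue;
      }
      double s = 0.0;
      for (int c = 0; c < m; ++c) {
        double d = X(i, c) - X(j, c);
        s += d * d;
      }
      double dd = std::sqrt(s);
      distX[j] = dd;
      sum_all += dd;
      adm.push_back({dd, j});
    }
    const int nadm = (int)adm.size();
    std::sort(adm.begin(), adm.end());
    double s_knn = 0.0, s_rank = 0.0;
    for (int q = 0; q < nadm; ++q) {
      rankpos[adm[q].j] = q + 1;  // nearest = rank 1
      if (q < k) {
        s_knn += adm[q].d;
        s_rank += q + 1;
        ownX(i, q) = adm[q].j;
      }
    }
    R_knn[i] = s_knn / k;
    R_all[i] = sum_all / nadm;
    G_knn[i] = s_rank / k;       // (k + 1) / 2 by construction
    G_all[i] = nadm / 2.0;

    double s_cond = 0.0, s_grank = 0.0;
    for (int q = 0; q < k; ++q) {
      int b = ownY(i, q);
      s_cond += distX[b];
      s_grank += rankpos[b];
    }
    R_cond[i] = s_cond / k;
    G_cond[i] = s_grank / k;
  }

  // 1-based state indices for the R side
  IntegerMatrix own1(nv, k), cond1(nv, k);
  for (int i = 0; i < nv; ++i)
    for (int q = 0; q < k; ++q) {
      own1(i, q) = ownX(i, q) + 1;
      cond1(i, q) = ownY(i, q) + 1;
    }

  return List::create(_["R_knn"] = R_knn, _["R_all"] = R_all,
                      _["R_cond"] = R_cond, _["G_cond"] = G_cond,
                      _["G_knn"] = G_knn, _["G_all"] = G_all,
                      _["neighbor_idx"] =
                          List::create(_["own"] = own1, _["cond"] = cond1));
}
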