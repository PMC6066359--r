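#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Hartigan & Hartigan dip statistic: the smallest sup-norm distance between
// the empirical cdf and the class of unimodal cdfs (atom allowed at the
// mode).  Computed over distinct values y_k with lower/upper ecdf values
// L_k (before the jump) and U_k (after).  For a convex (ascending) fit over
// a prefix, feasibility at distance d requires gcm(L)_k + d >= U_k - d, so
// the prefix misfit is max_k (U_k - gcm(L)_k); dually for concave suffixes.
// dip = 0.5 * min over mode placements (between knots, or at a knot with an
// atom absorbing that knot's jump) of max(prefix misfit, suffix misfit).

static void prefix_convex_misfit(const std::vector<double>& y,
                                 const std::vector<double>& L,
                                 const std::vector<double>& U,
                                 std::vector<double>& P) {
  // P[k] = misfit of convex fit over knots 0..k-1 (P[0] = 0)
  int K = y.size();
  P.assign(K + 1, 0.0);
  for (int k = 1; k <= K; ++k) {
    // lower convex hull of (y_i, L_i), i in [0, k)
    std::vector<int> h;
    for (int i = 0; i < k; ++i) {
      while (h.size() >= 2) {
        int a = h[h.size() - 2], b = h[h.size() - 1];
        // drop b if it lies on/above segment a--i
        double cross = (y[b] - y[a]) * (L[i] - L[a]) -
                       (L[b] - L[a]) * (y[i] - y[a]);
        if (cross <= 0.0) h.pop_back(); else break;
      }
      h.push_back(i);
    }
    // evaluate hull at each knot, track max U - hull
    double worst = 0.0;
    size_t seg = 0;
    for (int i = 0; i < k; ++i) {
      while (seg + 1 < h.size() && y[h[seg + 1]] <= y[i] &&
             h[seg + 1] <= i) ++seg;
      double hv;
      int a = h[seg];
      if (seg + 1 < h.size()) {
        int b = h[seg + 1];
        hv = (y[b] == y[a]) ? std::min(L[a], L[b])
             : L[a] + (L[b] - L[a]) * (y[i] - y[a]) / (y[b] - y[a]);
      } else hv = L[a];
      double dev = U[i] - hv;
      if (dev > worst) worst = dev;
    }
    P[k] = worst;
  }
}

// [[Rcpp::export]]
double dip_stat_cpp(NumericVector x_sorted) {
  int n = x_sorted.size();
  if (n < 2) return 0.0;
  // collapse ties
  std::vector<double> y, L, U;
  int i = 0;
  while (i < n) {
    int j = i;
    while (j < n && x_sorted[j] == x_sorted[i]) ++j;
    y.push_back(x_sorted[i]);
    L.push_back((double)i / n);
    U.push_back((double)j / n);
    i = j;
  }
  int K = y.size();
  if (K == 1) return 0.0;

  std::vector<double> P;
  prefix_convex_misfit(y, L, U, P);

  // suffix concave misfit via reflection: negate and reverse
  std::vector<double> yr(K), Lr(K), Ur(K), S;
  for (int k = 0; k < K; ++k) {
    yr[k] = -y[K - 1 - k];
    // reflected cdf: 1 - F swaps roles of L and U
    Lr[k] = 1.0 - U[K - 1 - k];
    Ur[k] = 1.0 - L[K - 1 - k];
  }
  prefix_convex_misfit(yr, Lr, Ur, S);
  // S[k] (reflected prefix of length k) == misfit of concave fit over the
  // last k knots; define Srev[j] = misfit over knots j..K-1
  std::vector<double> Srev(K + 1, 0.0);
  for (int k = 0; k <= K; ++k) Srev[K - k] = S[k];

  double best = R_PosInf;
  for (int k = 0; k <= K; ++k) { // mode between knots k-1 and k
    double d = std::max(P[k], Srev[k]);
    if (d < best) best = d;
  }
  for (int k = 0; k < K; ++k) { // mode at knot k with atom: skip it
    double d = std::max(P[k], Srev[k + 1]);
    if (d < best) best = d;
  }
  return 0.5 * best;
}
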