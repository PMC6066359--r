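#include <Rcpp.h>
#include <algorithm>
#include <queue>
#include <vector>
using namespace Rcpp;

// Delayed Gillespie direct method for the two-channel turnover system:
//   methylation        C + M -> 2M         propensity alpha*C*M
//   demethylation init M -> (in transit)   propensity beta*M
//   completion         (in transit) -> C   deterministic, delta_t later
// With delta_t <= 0 the initiation step converts M to C immediately,
// recovering the standard two-reaction direct method.
// [[Rcpp::export]]
List turnover_gillespie_cpp(double alpha, double beta, double delta_t,
                            int C0, int M0, double t_end,
                            NumericVector record_times, bool keep_events,
                            bool seed_history) {
  double t = 0.0;
  long C = C0, M = M0, T = 0;
  std::queue<double> pending; // completion times (FIFO: constant delay)
  if (seed_history && delta_t > 0.0 && beta * M0 > 0.0) {
    // constant pre-history M(t) = M0 on [-delta_t, 0): demethylations
    // initiated before t = 0 complete as a Poisson stream on (0, delta_t]
    int K = (int)R::rpois(beta * (double)M0 * delta_t);
    std::vector<double> ts(K);
    for (int i = 0; i < K; ++i) ts[i] = R::unif_rand() * delta_t;
    std::sort(ts.begin(), ts.end());
    for (int i = 0; i < K; ++i) pending.push(ts[i]);
    T = K;
  }
  int K = record_times.size(), ri = 0;
  IntegerVector recC(K), recM(K), recT(K);
  std::vector<double> ev_t; std::vector<int> ev_type, ev_C, ev_M, ev_T;
  bool immediate = (delta_t <= 0.0);

  auto flush_records = [&](double upto) {
    while (ri < K && record_times[ri] <= upto) {
      recC[ri] = (int)C; recM[ri] = (int)M; recT[ri] = (int)T; ++ri;
    }
  };
  auto log_event = [&](int type) {
    if (keep_events) {
      ev_t.push_back(t); ev_type.push_back(type);
      ev_C.push_back((int)C); ev_M.push_back((int)M); ev_T.push_back((int)T);
    }
  };

  while (t < t_end) {
    double a1 = alpha * (double)C * (double)M;
    double a2 = beta * (double)M;
    double a0 = a1 + a2;
    double t_rxn = (a0 > 0.0) ? t + R::rexp(1.0 / a0) : R_PosInf;
    double t_cmp = pending.empty() ? R_PosInf : pending.front();
    double t_next = (t_cmp <= t_rxn) ? t_cmp : t_rxn;
    if (t_next > t_end || !R_FINITE(t_next)) break;
    flush_records(t_next);
    t = t_next;
    if (t_cmp <= t_rxn) {
      pending.pop(); --T; ++C;
      log_event(3);
    } else {
      if (R::unif_rand() * a0 < a1) {
        --C; ++M;
        log_event(1);
      } else {
        --M;
        if (immediate) { ++C; log_event(2); log_event(3); }
        else { ++T; pending.push(t + delta_t); log_event(2); }
      }
    }
  }
  flush_records(t_end);
  while (ri < K) { recC[ri] = (int)C; recM[ri] = (int)M; recT[ri] = (int)T; ++ri; }

  List ev = R_NilValue;
  if (keep_events)
    ev = List::create(_["time"] = wrap(ev_t), _["type"] = wrap(ev_type),
                      _["C"] = wrap(ev_C), _["M"] = wrap(ev_M),
                      _["in_transit"] = wrap(ev_T));
  return List::create(_["C"] = recC, _["M"] = recM, _["in_transit"] = recT,
                      _["final_time"] = t, _["events"] = ev);
}

// One (k, s) read draw per supplied true rate: coverage from a discretised
// exponential (ceiling), truncated below min_coverage by the memoryless
// shift, then binomial positive reads.
// [[Rcpp::export]]
List sample_reads_cpp(NumericVector rate, double coverage_mean,
                      int min_coverage) {
  int n = rate.size();
  IntegerVector s(n), k(n);
  for (int i = 0; i < n; ++i) {
    double x = R::rexp(coverage_mean);
    s[i] = (min_coverage - 1) + (int)std::ceil(x > 0.0 ? x : 1e-12);
    k[i] = (int)R::rbinom((double)s[i], rate[i]);
  }
  return List::create(_["k"] = k, _["s"] = s);
}
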