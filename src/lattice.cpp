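#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Forward bias of the coupling function: probability-like weight in [0,1]
// favouring a forward step when the partner phase is ahead.
static inline double fwd_bias(double dphi, double eps_c) {
  // dphi in radians, wrapped to (-pi, pi]
  if (dphi > M_PI)  dphi -= 2.0 * M_PI;
  if (dphi <= -M_PI) dphi += 2.0 * M_PI;
  return 0.5 * (1.0 + std::sin(eps_c * dphi));
}

// Continuous-time Markov simulation of the discrete-phase CpG lattice.
// Site i steps its phase +-1 (mod n_states) with rates
//   fwd_i = (n/2pi) [ max(omega_i,0) + sum_j W_ij B_ij + kappa_i sum_{j!=i} sigma_j B_ij ]
//   bwd_i = (n/2pi) [ max(-omega_i,0) + sum_j W_ij (1-B_ij) + kappa_i sum_{j!=i} sigma_j (1-B_ij) ]
// where B_ij is the forward bias at the wrapped phase difference phi_j-phi_i.
// Exact direct-method simulation with incremental O(N) updates per event.
// [[Rcpp::export]]
List lattice_sim_cpp(IntegerVector phase0, int n_states, NumericVector omega,
                     NumericMatrix W, NumericVector kappa, NumericVector sigma,
                     double eps_c, double t_end, double record_every) {
  int N = phase0.size();
  std::vector<int> phi(phase0.begin(), phase0.end());
  double step = 2.0 * M_PI / n_states;
  double c0 = n_states / (2.0 * M_PI);

  std::vector<double> Lf(N), Gf(N), Wrow(N), fwd(N), bwd(N);
  double sig_tot = 0.0;
  for (int j = 0; j < N; ++j) sig_tot += sigma[j];

  auto refresh_site = [&](int i) {
    double lf = 0.0, gf = 0.0;
    for (int j = 0; j < N; ++j) {
      if (j == i) continue;
      double b = fwd_bias((phi[j] - phi[i]) * step, eps_c);
      lf += W(i, j) * b;
      gf += sigma[j] * b;
    }
    Lf[i] = lf; Gf[i] = gf;
  };
  for (int i = 0; i < N; ++i) {
    double wr = 0.0;
    for (int j = 0; j < N; ++j) if (j != i) wr += W(i, j);
    Wrow[i] = wr;
    refresh_site(i);
  }
  auto rates_site = [&](int i) {
    double om = omega[i];
    fwd[i] = c0 * ((om > 0 ? om : 0.0) + Lf[i] + kappa[i] * Gf[i]);
    bwd[i] = c0 * ((om < 0 ? -om : 0.0) + (Wrow[i] - Lf[i]) +
                   kappa[i] * (sig_tot - sigma[i] - Gf[i]));
  };
  for (int i = 0; i < N; ++i) rates_site(i);

  int n_rec = (int)std::floor(t_end / record_every) + 1;
  NumericVector rec_t(n_rec), rec_r(n_rec), rec_psi(n_rec);
  IntegerVector steps_fwd(N), steps_bwd(N);
  double t = 0.0;
  int ri = 0;
  long n_events = 0;

  auto record_upto = [&](double tnew) {
    while (ri < n_rec && ri * record_every <= tnew) {
      double re = 0.0, im = 0.0;
      for (int j = 0; j < N; ++j) {
        re += sigma[j] * std::cos(phi[j] * step);
        im += sigma[j] * std::sin(phi[j] * step);
      }
      rec_t[ri] = ri * record_every;
      rec_r[ri] = std::sqrt(re * re + im * im) / (sig_tot > 0 ? sig_tot : 1.0);
      rec_psi[ri] = std::atan2(im, re);
      ++ri;
    }
  };

  while (t < t_end) {
    double R_tot = 0.0;
    for (int i = 0; i < N; ++i) R_tot += fwd[i] + bwd[i];
    if (R_tot <= 0.0) break;
    double t_next = t + R::rexp(1.0 / R_tot);
    if (t_next > t_end) break;
    record_upto(t_next);
    t = t_next;
    double u = R::unif_rand() * R_tot;
    int k = -1, dir = 0;
    for (int i = 0; i < N; ++i) {
      if (u < fwd[i]) { k = i; dir = +1; break; }
      u -= fwd[i];
      if (u < bwd[i]) { k = i; dir = -1; break; }
      u -= bwd[i];
    }
    if (k < 0) { k = N - 1; dir = -1; } // guard against roundoff
    int old_phi = phi[k];
    phi[k] = ((phi[k] + dir) % n_states + n_states) % n_states;
    if (dir > 0) ++steps_fwd[k]; else ++steps_bwd[k];
    // incremental update of partners' sums, full refresh of site k
    for (int i = 0; i < N; ++i) {
      if (i == k) continue;
      double b_old = fwd_bias((old_phi - phi[i]) * step, eps_c);
      double b_new = fwd_bias((phi[k] - phi[i]) * step, eps_c);
      double db = b_new - b_old;
      Gf[i] += sigma[k] * db;
      if (W(i, k) != 0.0) Lf[i] += W(i, k) * db;
      rates_site(i);
    }
    refresh_site(k);
    rates_site(k);
    if ((++n_events % 50000) == 0) { // periodic full refresh against drift
      for (int i = 0; i < N; ++i) { refresh_site(i); rates_site(i); }
    }
  }
  record_upto(t_end);

  IntegerVector phases(N);
  for (int i = 0; i < N; ++i) phases[i] = phi[i];
  return List::create(_["t"] = rec_t, _["r"] = rec_r, _["psi"] = rec_psi,
                      _["phases"] = phases, _["steps_fwd"] = steps_fwd,
                      _["steps_bwd"] = steps_bwd, _["n_events"] = (double)n_events);
}

// Deterministic mean-field Kuramoto integration (midpoint rule) with
// weighted order parameter z = N^{-1} sum_j sigma_j exp(i phi_j).
// Returns r(t) normalised by mean sigma so that r in [0, 1].
// [[Rcpp::export]]
List kuramoto_sim_cpp(NumericVector phase0, NumericVector omega,
                      NumericVector kappa, NumericVector sigma,
                      double t_end, double dt, double record_every) {
  int N = phase0.size();
  std::vector<double> phi(phase0.begin(), phase0.end());
  double sig_tot = 0.0;
  for (int j = 0; j < N; ++j) sig_tot += sigma[j];
  int nstep = (int)std::ceil(t_end / dt);
  int rec_stride = std::max(1, (int)std::round(record_every / dt));
  std::vector<double> rec_t, rec_r, rec_psi;

  auto field = [&](const std::vector<double>& p, double& r, double& psi) {
    double re = 0.0, im = 0.0;
    for (int j = 0; j < N; ++j) {
      re += sigma[j] * std::cos(p[j]);
      im += sigma[j] * std::sin(p[j]);
    }
    r = std::sqrt(re * re + im * im) / N; // dynamical normalisation N^{-1}
    psi = std::atan2(im, re);
  };

  std::vector<double> half(N);
  double r, psi;
  for (int s = 0; s <= nstep; ++s) {
    if (s % rec_stride == 0 || s == nstep) {
      field(phi, r, psi);
      rec_t.push_back(s * dt);
      rec_r.push_back(r * N / (sig_tot > 0 ? sig_tot : 1.0));
      rec_psi.push_back(psi);
    }
    if (s == nstep) break;
    field(phi, r, psi);
    for (int i = 0; i < N; ++i)
      half[i] = phi[i] + 0.5 * dt * (omega[i] + kappa[i] * r * std::sin(psi - phi[i]));
    field(half, r, psi);
    for (int i = 0; i < N; ++i)
      phi[i] += dt * (omega[i] + kappa[i] * r * std::sin(psi - half[i]));
  }
  NumericVector phases(N);
  for (int i = 0; i < N; ++i) {
    double tw = 2.0 * M_PI;
    phases[i] = phi[i] - std::floor(phi[i] / tw) * tw;
  }
  return List::create(_["t"] = wrap(rec_t), _["r"] = wrap(rec_r),
                      _["psi"] = wrap(rec_psi), _["phases"] = phases);
}
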