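#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Linear interpolation of the stored solution grid (step dt, origin 0).
// Times <= 0 fall back to the constant pre-history value.
static inline double hist_interp(const std::vector<double>& v, double v0,
                                 double t, double dt) {
  if (t <= 0.0) return v0;
  double idx = t / dt;
  int i0 = (int)std::floor(idx);
  double w = idx - (double)i0;
  if ((size_t)(i0 + 1) >= v.size()) return v.back();
  return v[i0] * (1.0 - w) + v[i0 + 1] * w;
}

static inline double hill_frac(double x, double thr, double h) {
  if (x <= 0.0) return 0.0;
  double xn = std::pow(x, h);
  return xn / (std::pow(thr, h) + xn);
}

struct DdeRhs {
  int variant;           // 0 baseline, 1 linear_denovo, 2 hill, 3 scheduled rates
  double eps, A, B, m, n;
  void operator()(double u, double v, double vdel,
                  double s_cm, double s_mc, double s_mc_del,
                  double& du, double& dv) const {
    switch (variant) {
    case 1:
      du = vdel - u * (v + eps);
      dv = u * (v + eps) - v;
      break;
    case 2: {
      double conv = hill_frac(u * v, B, m);
      du = hill_frac(vdel, A, n) - conv;
      dv = conv - hill_frac(v, A, n);
      break;
    }
    case 3:
      du = s_mc_del * vdel - s_cm * u * v;
      dv = s_cm * u * v - s_mc * v;
      break;
    default:
      du = vdel - u * v;
      dv = u * v - v;
    }
  }
};

// Fixed-step RK4 method of steps for the dimensionless delayed turnover
// system.  Schedules (variant 3) are sampled on the half-step grid
// (2*n_steps+1 values) and, for the delayed factor, pre-shifted by -delta_tau.
// [[Rcpp::export]]
NumericMatrix dde_rk4_cpp(double u0, double v0, double delta_tau,
                          double t_max, double dt, int variant,
                          double eps, double A, double B,
                          double m, double n,
                          NumericVector s_cm, NumericVector s_mc,
                          NumericVector s_mc_del) {
  int nstep = (int)std::round(t_max / dt);
  std::vector<double> uu(nstep + 1), vv(nstep + 1);
  uu[0] = u0; vv[0] = v0;
  DdeRhs rhs{variant, eps, A, B, m, n};
  bool no_delay = (delta_tau <= 0.0);
  bool sched = (variant == 3);
  double one = 1.0;
  for (int j = 0; j < nstep; ++j) {
    double t = j * dt;
    double u = uu[j], v = vv[j];
    // delayed v at the three stage times (t, t+dt/2, t+dt)
    double vd0, vdh, vd1;
    if (!no_delay) {
      vd0 = hist_interp(vv, v0, t - delta_tau, dt);
      vdh = hist_interp(vv, v0, t + 0.5 * dt - delta_tau, dt);
      vd1 = hist_interp(vv, v0, t + dt - delta_tau, dt);
    } else {
      vd0 = vdh = vd1 = 0.0; // filled per-stage below
    }
    double c0 = one, ch = one, c1 = one, m0 = one, mh = one, m1 = one,
           d0 = one, dh = one, d1 = one;
    if (sched) {
      c0 = s_cm[2 * j];     ch = s_cm[2 * j + 1];     c1 = s_cm[2 * j + 2];
      m0 = s_mc[2 * j];     mh = s_mc[2 * j + 1];     m1 = s_mc[2 * j + 2];
      d0 = s_mc_del[2 * j]; dh = s_mc_del[2 * j + 1]; d1 = s_mc_del[2 * j + 2];
    }
    double k1u, k1v, k2u, k2v, k3u, k3v, k4u, k4v;
    rhs(u, v, no_delay ? v : vd0, c0, m0, d0, k1u, k1v);
    {
      double u2 = u + 0.5 * dt * k1u, v2 = v + 0.5 * dt * k1v;
      rhs(u2, v2, no_delay ? v2 : vdh, ch, mh, dh, k2u, k2v);
    }
    {
      double u3 = u + 0.5 * dt * k2u, v3 = v + 0.5 * dt * k2v;
      rhs(u3, v3, no_delay ? v3 : vdh, ch, mh, dh, k3u, k3v);
    }
    {
      double u4 = u + dt * k3u, v4 = v + dt * k3v;
      rhs(u4, v4, no_delay ? v4 : vd1, c1, m1, d1, k4u, k4v);
    }
    double un = u + dt / 6.0 * (k1u + 2.0 * k2u + 2.0 * k3u + k4u);
    double vn = v + dt / 6.0 * (k1v + 2.0 * k2v + 2.0 * k3v + k4v);
    uu[j + 1] = (un < 0.0) ? 0.0 : un;
    vv[j + 1] = (vn < 0.0) ? 0.0 : vn;
  }
  NumericMatrix out(nstep + 1, 3);
  for (int j = 0; j <= nstep; ++j) {
    out(j, 0) = j * dt;
    out(j, 1) = uu[j];
    out(j, 2) = vv[j];
  }
  colnames(out) = CharacterVector::create("tau", "u", "v");
  return out;
}
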