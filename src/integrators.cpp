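#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Parameter vector layout: must match .PAR_NUMERIC in R/parameters.R.
enum ParIdx {
  P_Cm = 0, P_gNa, P_gK, P_gL, P_gCa, P_gKCa,
  P_VNa, P_VK, P_VL, P_VCa,
  P_tau_n, P_tau_x, P_tau_C,
  P_a_n, P_Vhalf_n, P_a_m, P_Vhalf_m, P_a_x, P_Vhalf_x,
  P_KR, P_Kd, P_g2, P_V2,
  P_Vth, P_Vreset, P_Vmax, P_t1, P_tau_r, P_eps,
  P_x_reset, P_C_reset, P_dx, P_dC,
  P_N
};

static inline double zinf(double V, double a, double Vhalf) {
  return 1.0 / (1.0 + std::exp(-2.0 * a * (V - Vhalf)));
}

struct Pars {
  double p[P_N];
  explicit Pars(const NumericVector& v) {
    if (v.size() != P_N) stop("parameter vector has wrong length");
    for (int i = 0; i < P_N; ++i) p[i] = v[i];
  }
  inline double minf(double V) const { return zinf(V, p[P_a_m], p[P_Vhalf_m]); }
  inline double ninf(double V) const { return zinf(V, p[P_a_n], p[P_Vhalf_n]); }
  inline double xinf(double V) const { return zinf(V, p[P_a_x], p[P_Vhalf_x]); }
  inline double cinf(double V, double x) const {
    return -p[P_KR] * p[P_gCa] * x * x * (V - p[P_VCa]);
  }
};

static inline void hh_deriv(const Pars& pp, double mu, const double* s,
                            double* d) {
  const double* p = pp.p;
  double V = s[0], n = s[1], x = s[2], C = s[3];
  double m = pp.minf(V);
  double INa = p[P_gNa] * m * m * m * (1.0 - n) * (V - p[P_VNa]);
  double IK = p[P_gK] * n * n * n * n * (V - p[P_VK]);
  double IL = p[P_gL] * (V - p[P_VL]);
  double ICa = p[P_gCa] * x * x * (V - p[P_VCa]);
  double IKCa = p[P_gKCa] * C / (C + p[P_Kd]) * (V - p[P_VK]);
  d[0] = (mu - (INa + IK + IL + ICa + IKCa)) / p[P_Cm];
  d[1] = (pp.ninf(V) - n) / p[P_tau_n];
  d[2] = (pp.xinf(V) - x) / p[P_tau_x];
  d[3] = (pp.cinf(V, x) - C) / p[P_tau_C];
}

static inline void qif_deriv(const Pars& pp, double mu, const double* s,
                             double* d) {
  const double* p = pp.p;
  double V = s[0], x = s[1], C = s[2];
  double ICa = p[P_gCa] * x * x * (V - p[P_VCa]);
  double IKCa = p[P_gKCa] * C / (C + p[P_Kd]) * (V - p[P_VK]);
  double dv = V - p[P_V2];
  d[0] = (mu + p[P_g2] * dv * dv - ICa - IKCa) / p[P_Cm];
  d[1] = (pp.xinf(V) - x) / p[P_tau_x];
  d[2] = (pp.cinf(V, x) - C) / p[P_tau_C];
}

template <int N, typename Deriv>
static inline void rk4_step(const Pars& pp, double mu, double dt,
                            const double* s, double* out, Deriv deriv) {
  double k1[N], k2[N], k3[N], k4[N], tmp[N];
  deriv(pp, mu, s, k1);
  for (int i = 0; i < N; ++i) tmp[i] = s[i] + 0.5 * dt * k1[i];
  deriv(pp, mu, tmp, k2);
  for (int i = 0; i < N; ++i) tmp[i] = s[i] + 0.5 * dt * k2[i];
  deriv(pp, mu, tmp, k3);
  for (int i = 0; i < N; ++i) tmp[i] = s[i] + dt * k3[i];
  deriv(pp, mu, tmp, k4);
  for (int i = 0; i < N; ++i)
    out[i] = s[i] + dt / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
}

static inline bool finite_state(const double* s, int n) {
  for (int i = 0; i < n; ++i)
    if (!std::isfinite(s[i]) || std::fabs(s[i]) > 1e6) return false;
  return true;
}

// [[Rcpp::export(name = ".hh_integrate_cpp")]]
List hh_integrate_cpp(NumericVector pars, double mu, double duration,
                      double dt, NumericVector init, double vdetect,
                      bool record, int thin, double guard) {
  Pars pp(pars);
  if (init.size() != 4) stop("HH initial state must have 4 components");
  double s[4] = {init[0], init[1], init[2], init[3]};
  long nsteps = (long)std::ceil(duration / dt);
  std::vector<double> times, Vv, nv, xv, Cv, spikes;
  if (record) {
    long cap = nsteps / thin + 2;
    times.reserve(cap); Vv.reserve(cap); nv.reserve(cap);
    xv.reserve(cap); Cv.reserve(cap);
  }
  double t = 0.0, last_spike = -1e18;
  if (record) {
    times.push_back(t); Vv.push_back(s[0]); nv.push_back(s[1]);
    xv.push_back(s[2]); Cv.push_back(s[3]);
  }
  double nxt[4];
  for (long k = 0; k < nsteps; ++k) {
    rk4_step<4>(pp, mu, dt, s, nxt, hh_deriv);
    if (!finite_state(nxt, 4))
      stop("HH integration blew up at t = %f (mu = %f)", t, mu);
    double tnew = t + dt;
    if (s[0] < vdetect && nxt[0] >= vdetect) {
      double th = t + dt * (vdetect - s[0]) / (nxt[0] - s[0]);
      if (th - last_spike > guard) {
        spikes.push_back(th);
        last_spike = th;
      }
    }
    for (int i = 0; i < 4; ++i) s[i] = nxt[i];
    t = tnew;
    if (record && ((k + 1) % thin == 0)) {
      times.push_back(t); Vv.push_back(s[0]); nv.push_back(s[1]);
      xv.push_back(s[2]); Cv.push_back(s[3]);
    }
  }
  List out = List::create(_["spike_times"] = wrap(spikes),
                          _["final_state"] = NumericVector::create(
                            s[0], s[1], s[2], s[3]));
  if (record) {
    out["times"] = wrap(times);
    out["V"] = wrap(Vv); out["n"] = wrap(nv);
    out["x"] = wrap(xv); out["C"] = wrap(Cv);
  }
  return out;
}

static inline double spike_waveform(double t, const double* p) {
  if (t < p[P_t1])
    return p[P_Vth] + (p[P_Vmax] - p[P_Vth]) / p[P_t1] * t;
  return p[P_Vmax] +
         (p[P_Vreset] - p[P_Vmax]) / (p[P_tau_r] - p[P_t1]) * (t - p[P_t1]);
}

// Integrate the gating pair (x, C) with V clamped to the artificial spike
// waveform over [0, tau_r] (RK4, step <= dt).
static void gating_through_spike(const Pars& pp, double x0, double C0,
                                 double dt, double* xC_end) {
  const double* p = pp.p;
  double s[2] = {x0, C0};
  long nsub = (long)std::ceil(p[P_tau_r] / dt);
  double h = p[P_tau_r] / nsub;
  for (long k = 0; k < nsub; ++k) {
    double t0 = k * h;
    double k1[2], k2[2], k3[2], k4[2], tmp[2];
    auto gd = [&](double tt, const double* u, double* d) {
      double V = spike_waveform(tt, p);
      d[0] = (pp.xinf(V) - u[0]) / p[P_tau_x];
      d[1] = (pp.cinf(V, u[0]) - u[1]) / p[P_tau_C];
    };
    gd(t0, s, k1);
    tmp[0] = s[0] + 0.5 * h * k1[0]; tmp[1] = s[1] + 0.5 * h * k1[1];
    gd(t0 + 0.5 * h, tmp, k2);
    tmp[0] = s[0] + 0.5 * h * k2[0]; tmp[1] = s[1] + 0.5 * h * k2[1];
    gd(t0 + 0.5 * h, tmp, k3);
    tmp[0] = s[0] + h * k3[0]; tmp[1] = s[1] + h * k3[1];
    gd(t0 + h, tmp, k4);
    s[0] += h / 6.0 * (k1[0] + 2 * k2[0] + 2 * k3[0] + k4[0]);
    s[1] += h / 6.0 * (k1[1] + 2 * k2[1] + 2 * k3[1] + k4[1]);
  }
  xC_end[0] = s[0]; xC_end[1] = s[1];
}

// [[Rcpp::export(name = ".gating_through_spike_cpp")]]
NumericVector gating_through_spike_cpp(NumericVector pars, double x0,
                                       double C0, double dt) {
  Pars pp(pars);
  double e[2];
  gating_through_spike(pp, x0, C0, dt, e);
  return NumericVector::create(_["x_end"] = e[0], _["C_end"] = e[1]);
}

// reset_mode: 0 = spike_waveform, 1 = fixed_delta, 2 = fixed_reset
// [[Rcpp::export(name = ".qif_integrate_cpp")]]
List qif_integrate_cpp(NumericVector pars, double mu, double duration,
                       double dt, NumericVector init, int reset_mode,
                       bool record, int thin) {
  Pars pp(pars);
  const double* p = pp.p;
  if (init.size() != 3) stop("QIF initial state must have 3 components");
  double s[3] = {init[0], init[1], init[2]};
  std::vector<double> times, Vv, xv, Cv, spikes, x_at_reset, C_at_reset;
  if (record) {
    long cap = (long)std::ceil(duration / dt) / thin + 16;
    times.reserve(cap); Vv.reserve(cap); xv.reserve(cap); Cv.reserve(cap);
  }
  double t = 0.0;
  long k_since_record = 0;
  if (record) {
    times.push_back(t); Vv.push_back(s[0]); xv.push_back(s[1]);
    Cv.push_back(s[2]);
  }
  double nxt[3];
  while (t < duration) {
    double h = std::min(dt, duration - t);
    rk4_step<3>(pp, mu, h, s, nxt, qif_deriv);
    if (!finite_state(nxt, 3))
      stop("QIF integration blew up at t = %f (mu = %f)", t, mu);
    if (nxt[0] >= p[P_Vth]) {
      // locate the crossing within the step by linear interpolation
      double th = (p[P_Vth] - s[0]) / (nxt[0] - s[0]);
      double tc = t + th * h;
      double xc = s[1] + th * (nxt[1] - s[1]);
      double Cc = s[2] + th * (nxt[2] - s[2]);
      spikes.push_back(tc);
      if (record) {  // spike sample clamped at threshold
        times.push_back(tc); Vv.push_back(p[P_Vth]);
        xv.push_back(xc); Cv.push_back(Cc);
      }
      double xr, Cr;
      if (reset_mode == 0) {
        double e[2];
        gating_through_spike(pp, xc, Cc, dt, e);
        xr = e[0]; Cr = e[1];
      } else if (reset_mode == 1) {
        xr = xc + p[P_dx]; Cr = Cc + p[P_dC];
      } else {
        xr = p[P_x_reset]; Cr = p[P_C_reset];
      }
      if (xr < 0) xr = 0; if (xr > 1) xr = 1; if (Cr < 0) Cr = 0;
      x_at_reset.push_back(xr); C_at_reset.push_back(Cr);
      t = tc + p[P_tau_r];
      s[0] = p[P_Vreset]; s[1] = xr; s[2] = Cr;
      if (record && t < duration) {
        times.push_back(t); Vv.push_back(s[0]); xv.push_back(s[1]);
        Cv.push_back(s[2]);
      }
      k_since_record = 0;
      continue;
    }
    for (int i = 0; i < 3; ++i) s[i] = nxt[i];
    t += h;
    if (record && (++k_since_record % thin == 0)) {
      times.push_back(t); Vv.push_back(s[0]); xv.push_back(s[1]);
      Cv.push_back(s[2]);
    }
  }
  List out = List::create(_["spike_times"] = wrap(spikes),
                          _["x_at_reset"] = wrap(x_at_reset),
                          _["C_at_reset"] = wrap(C_at_reset),
                          _["final_state"] = NumericVector::create(
                            s[0], s[1], s[2]));
  if (record) {
    out["times"] = wrap(times);
    out["V"] = wrap(Vv); out["x"] = wrap(xv); out["C"] = wrap(Cv);
  }
  return out;
}
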