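#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Gating kinetics of the reduced single-compartment TC relay neuron.
// Voltages in mV, times in ms, current densities in pA/um^2,
// conductances in nS/um^2 (model units of the reduced TC literature).

static inline double m_inf(double v) { return 1.0 / (1.0 + std::exp(-(v + 37.0) / 7.0)); }
static inline double p_inf(double v) { return 1.0 / (1.0 + std::exp(-(v + 60.0) / 6.2)); }
static inline double h_inf(double v) { return 1.0 / (1.0 + std::exp((v + 41.0) / 4.0)); }
static inline double r_inf(double v) { return 1.0 / (1.0 + std::exp((v + 84.0) / 4.0)); }

static inline double tau_h(double v) {
  double ah = 0.128 * std::exp(-(v + 46.0) / 18.0);
  double bh = 4.0 / (1.0 + std::exp(-(v + 23.0) / 5.0));
  return 1.0 / (ah + bh);
}
static inline double tau_r(double v) { return 28.0 + std::exp(-(v + 25.0) / 10.5); }

struct TCPar {
  double cm, gl, el, gna, ena, gk, ek, gt, et, igi;
  double sgn_gi, sgn_sm; // +1: subtract the current literally; -1: add it
};

static inline void tc_derivs(double v, double h, double r, double ism,
                             const TCPar &p, double &dv, double &dh, double &dr) {
  double mi = m_inf(v), pi = p_inf(v);
  double om_h = 1.0 - h;
  double il = p.gl * (v - p.el);
  double ina = p.gna * mi * mi * mi * h * (v - p.ena);
  double ik = p.gk * 0.75 * om_h * om_h * om_h * om_h * (v - p.ek);
  double it = p.gt * pi * pi * r * (v - p.et);
  dv = (-il - ina - ik - it - p.sgn_gi * p.igi - p.sgn_sm * ism) / p.cm;
  dh = (h_inf(v) - h) / tau_h(v);
  dr = 2.5 * (r_inf(v) - r) / tau_r(v);
}

// Fixed-step classical RK4 over n steps of size dt.  The applied current is
// sampled on the half grid: i_sm_half has 2n+1 entries, entry 2i at t_i and
// entry 2i+1 at t_i + dt/2, so all four stages see the exact stimulus value.
// [[Rcpp::export(name = ".tc_rk4_cpp")]]
List tc_rk4_cpp(NumericVector par, NumericVector i_sm_half, double dt,
                double v0, double h0, double r0) {
  if (par.size() != 12) stop("internal: parameter pack must have 12 entries");
  TCPar p;
  p.cm = par[0]; p.gl = par[1]; p.el = par[2]; p.gna = par[3]; p.ena = par[4];
  p.gk = par[5]; p.ek = par[6]; p.gt = par[7]; p.et = par[8]; p.igi = par[9];
  p.sgn_gi = par[10]; p.sgn_sm = par[11];

  R_xlen_t nhalf = i_sm_half.size();
  if (nhalf < 1 || nhalf % 2 == 0) stop("internal: half-grid stimulus must have odd length");
  R_xlen_t n = (nhalf - 1) / 2;

  NumericVector vout(n + 1), hout(n + 1), rout(n + 1);
  double v = v0, h = h0, r = r0;
  vout[0] = v; hout[0] = h; rout[0] = r;
  bool gate_excursion = false;
  const double tol = 1e-6;

  double k1v, k1h, k1r, k2v, k2h, k2r, k3v, k3h, k3r, k4v, k4h, k4r;
  for (R_xlen_t i = 0; i < n; ++i) {
    double i0 = i_sm_half[2 * i], ih = i_sm_half[2 * i + 1], i1 = i_sm_half[2 * i + 2];
    tc_derivs(v, h, r, i0, p, k1v, k1h, k1r);
    tc_derivs(v + 0.5 * dt * k1v, h + 0.5 * dt * k1h, r + 0.5 * dt * k1r, ih, p, k2v, k2h, k2r);
    tc_derivs(v + 0.5 * dt * k2v, h + 0.5 * dt * k2h, r + 0.5 * dt * k2r, ih, p, k3v, k3h, k3r);
    tc_derivs(v + dt * k3v, h + dt * k3h, r + dt * k3r, i1, p, k4v, k4h, k4r);
    v += dt / 6.0 * (k1v + 2.0 * k2v + 2.0 * k3v + k4v);
    h += dt / 6.0 * (k1h + 2.0 * k2h + 2.0 * k3h + k4h);
    r += dt / 6.0 * (k1r + 2.0 * k2r + 2.0 * k3r + k4r);
    if (!std::isfinite(v) || std::fabs(v) > 200.0)
      stop("integration failure: |V| exceeded 200 mV at step %d (t = %.4f ms)",
           (int)(i + 1), (double)(i + 1) * dt);
    if (h < -tol || h > 1.0 + tol || r < -tol || r > 1.0 + tol) gate_excursion = true;
    vout[i + 1] = v; hout[i + 1] = h; rout[i + 1] = r;
  }

  return List::create(_["v"] = vout, _["h"] = hout, _["r"] = rout,
                      _["gate_excursion"] = gate_excursion);
}
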