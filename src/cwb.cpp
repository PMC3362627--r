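#include <Rcpp.h>
using namespace Rcpp;

// Wang-Buzsaki rate functions; vtrap handles the removable singularity of
// the x/(1-exp(-x/s)) form
static inline double vtrap(double x, double s) {
  if (std::fabs(x / s) < 1e-6) return s * (1.0 - x / (2.0 * s));
  return x / (1.0 - std::exp(-x / s));
}

static inline double alpha_m(double v) { return 0.1 * vtrap(v + 35.0, 10.0); }
static inline double beta_m(double v)  { return 4.0 * std::exp(-(v + 60.0) / 18.0); }
static inline double alpha_h(double v) { return 0.07 * std::exp(-(v + 58.0) / 20.0); }
static inline double beta_h(double v)  { return 1.0 / (1.0 + std::exp(-0.1 * (v + 28.0))); }
static inline double alpha_n(double v) { return 0.01 * vtrap(v + 34.0, 10.0); }
static inline double beta_n(double v)  { return 0.125 * std::exp(-(v + 44.0) / 80.0); }

struct CwbPar {
  double c_m, g_na, g_k, g_l, e_na, e_k, e_l, phi;
  double p, v_half, k_slope, q, tau_m, mu, kappa, q_noncoop;
  int coop_wb; // 0 = Boltzmann steady state, 1 = WB m_inf at shifted voltage
};

static inline double coop_minf(double v_shifted, const CwbPar& P) {
  if (P.coop_wb) {
    double am = alpha_m(v_shifted), bm = beta_m(v_shifted);
    return am / (am + bm);
  }
  return 1.0 / (1.0 + std::exp(-(v_shifted - P.v_half) / P.k_slope));
}

// derivative of (v, h, n, m_c, h_c)
static inline void rhs(const double* y, double i_ext, const CwbPar& P,
                       double* dy) {
  const double v = y[0], h = y[1], n = y[2], m_c = y[3], h_c = y[4];
  const double am = alpha_m(v), bm = beta_m(v);
  const double minf = am / (am + bm);
  const double mcq = std::pow(m_c, P.q);
  const double i_na = P.g_na *
    ((1.0 - P.p) * std::pow(minf, P.q_noncoop) * h + P.p * mcq * h_c) *
    (v - P.e_na);
  const double i_k = P.g_k * std::pow(n, 4.0) * (v - P.e_k);
  const double i_l = P.g_l * (v - P.e_l);
  dy[0] = (-i_na - i_k - i_l + i_ext) / P.c_m;
  dy[1] = P.phi * (alpha_h(v) * (1.0 - h) - beta_h(v) * h);
  dy[2] = P.phi * (alpha_n(v) * (1.0 - n) - beta_n(v) * n);
  dy[3] = (coop_minf(v + P.mu * h_c * mcq, P) - m_c) / P.tau_m;
  dy[4] = P.phi * (alpha_h(v) * (1.0 - h_c) -
                   beta_h(v) * (1.0 + P.kappa * mcq) * h_c);
}

static CwbPar unpack(List par) {
  CwbPar P;
  P.c_m = par["c_m"]; P.g_na = par["g_na"]; P.g_k = par["g_k"];
  P.g_l = par["g_l"]; P.e_na = par["e_na"]; P.e_k = par["e_k"];
  P.e_l = par["e_l"]; P.phi = par["phi"];
  P.p = par["p"]; P.v_half = par["v_half"]; P.k_slope = par["k_slope"];
  P.q = par["q"]; P.tau_m = par["tau_m"]; P.mu = par["mu"];
  P.kappa = par["kappa"]; P.q_noncoop = par["q_noncoop"];
  P.coop_wb = as<int>(par["coop_wb"]);
  return P;
}

// [[Rcpp::export(name = ".cwb_integrate_cpp")]]
List cwb_integrate_cpp(NumericVector state0, double dt, int n_steps,
                       NumericVector i_input, List par) {
  CwbPar P = unpack(par);
  if (i_input.size() != n_steps)
    stop("i_input must have one value per integration step");

  NumericVector v(n_steps + 1), h(n_steps + 1), n(n_steps + 1),
                m_c(n_steps + 1), h_c(n_steps + 1);
  double y[5], k1[5], k2[5], k3[5], k4[5], tmp[5];
  for (int j = 0; j < 5; ++j) y[j] = state0[j];
  v[0] = y[0]; h[0] = y[1]; n[0] = y[2]; m_c[0] = y[3]; h_c[0] = y[4];
  long clip_events = 0;
  int bad_step = -1;

  for (int i = 0; i < n_steps; ++i) {
    const double ie = i_input[i]; // stimulus held constant over the step
    rhs(y, ie, P, k1);
    for (int j = 0; j < 5; ++j) tmp[j] = y[j] + 0.5 * dt * k1[j];
    rhs(tmp, ie, P, k2);
    for (int j = 0; j < 5; ++j) tmp[j] = y[j] + 0.5 * dt * k2[j];
    rhs(tmp, ie, P, k3);
    for (int j = 0; j < 5; ++j) tmp[j] = y[j] + dt * k3[j];
    rhs(tmp, ie, P, k4);
    for (int j = 0; j < 5; ++j)
      y[j] += dt / 6.0 * (k1[j] + 2.0 * k2[j] + 2.0 * k3[j] + k4[j]);
    for (int j = 1; j < 5; ++j) { // clip gating variables to [0, 1]
      if (y[j] < 0.0) { y[j] = 0.0; ++clip_events; }
      else if (y[j] > 1.0) { y[j] = 1.0; ++clip_events; }
    }
    if (!std::isfinite(y[0])) { bad_step = i + 1; break; }
    v[i + 1] = y[0]; h[i + 1] = y[1]; n[i + 1] = y[2];
    m_c[i + 1] = y[3]; h_c[i + 1] = y[4];
  }

  return List::create(_["v"] = v, _["h"] = h, _["n"] = n,
                      _["m_c"] = m_c, _["h_c"] = h_c,
                      _["clip_events"] = (double)clip_events,
                      _["bad_step"] = bad_step);
}
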