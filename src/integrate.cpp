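#include <Rcpp.h>
using namespace Rcpp;

// Single-compartment hybrid model: leak + hyperpolarization-activated cation
// current (Ih, one first-order gate) + low-threshold inactivating current
// (rebound, instantaneous activation, slow inactivation) + slowly
// inactivating K current (delays the first spike) + phenomenological spike
// emission (threshold/reset/refractory, spike-triggered adaptation current,
// adaptive threshold) + an explicit depolarization-block rule: emission is
// suppressed while the low-pass-filtered membrane voltage exceeds v_block.
//
// Units: mV, pA, nS, pF, ms  (pF*mV/ms = pA, nS*mV = pA).

static inline double sigm(double v, double half, double slope) {
  // slope > 0: decreasing with v (activates on hyperpolarization)
  return 1.0 / (1.0 + std::exp((v - half) / slope));
}

struct ModelPar {
  double C, gL, EL;
  double gh, Eh, h_half, h_slope, tau_h;
  double gT, ET, Tm_half, Tm_slope, Th_half, Th_slope, tau_Th;
  double gD, EK, Da_half, Da_slope, Db_half, Db_slope, tau_Db;
  double theta0, d_theta, tau_theta, v_reset, t_ref, b_w, tau_w;
  double v_spike, v_block, tau_filt;
};

static ModelPar unpack(const NumericVector& p) {
  ModelPar m;
  m.C = p["c_m"];         m.gL = p["g_l"];       m.EL = p["e_l"];
  m.gh = p["g_h"];        m.Eh = p["e_h"];
  m.h_half = p["h_half"]; m.h_slope = p["h_slope"]; m.tau_h = p["tau_h"];
  m.gT = p["g_t"];        m.ET = p["e_t"];
  m.Tm_half = p["tm_half"]; m.Tm_slope = p["tm_slope"];
  m.Th_half = p["th_half"]; m.Th_slope = p["th_slope"]; m.tau_Th = p["tau_th_gate"];
  m.gD = p["g_d"];        m.EK = p["e_k"];
  m.Da_half = p["da_half"]; m.Da_slope = p["da_slope"];
  m.Db_half = p["db_half"]; m.Db_slope = p["db_slope"]; m.tau_Db = p["tau_db"];
  m.theta0 = p["theta0"]; m.d_theta = p["d_theta"]; m.tau_theta = p["tau_theta"];
  m.v_reset = p["v_reset"]; m.t_ref = p["t_ref"];
  m.b_w = p["b_w"];       m.tau_w = p["tau_w"];
  m.v_spike = p["v_spike"]; m.v_block = p["v_block"]; m.tau_filt = p["tau_filt"];
  return m;
}

// steady-state gate values at a fixed voltage
static inline double mh_inf(const ModelPar& m, double v) { return sigm(v, m.h_half,  m.h_slope); }
static inline double hT_inf(const ModelPar& m, double v) { return sigm(v, m.Th_half, m.Th_slope); }
static inline double bD_inf(const ModelPar& m, double v) { return sigm(v, m.Db_half, m.Db_slope); }
// instantaneous activations (increase with depolarization: negative slope arg)
static inline double mT_inf(const ModelPar& m, double v) { return sigm(v, m.Tm_half, -m.Tm_slope); }
static inline double aD_inf(const ModelPar& m, double v) { return sigm(v, m.Da_half, -m.Da_slope); }

static inline double ionic(const ModelPar& m, double v,
                           double mh, double hT, double bD) {
  double IL = m.gL * (v - m.EL);
  double Ih = m.gh * mh * (v - m.Eh);
  double IT = m.gT * mT_inf(m, v) * hT * (v - m.ET);
  double ID = m.gD * aD_inf(m, v) * bD * (v - m.EK);
  return IL + Ih + IT + ID;
}

//' @noRd
// [[Rcpp::export]]
double total_ionic_steady_cpp(NumericVector par, double v) {
  ModelPar m = unpack(par);
  return ionic(m, v, mh_inf(m, v), hT_inf(m, v), bD_inf(m, v));
}

// Current-clamp sweep. Returns sampled voltage trace (dt_out grid, first
// sample at t = 0) and spike peak times. Voltage starts from v0 with gates at
// their steady state for v0; bias_pA is applied throughout.
// [[Rcpp::export]]
List sim_cc_cpp(NumericVector par, double step_pA, double bias_pA,
                double t_total, double onset, double duration,
                double dt, double dt_out, double v0,
                NumericVector noise, std::string sweep_label) {
  ModelPar m = unpack(par);
  const int n_steps = (int)std::round(t_total / dt);
  const int thin = (int)std::round(dt_out / dt);
  const int n_out = n_steps / thin + 1;

  double V = v0;
  double mh = mh_inf(m, v0), hT = hT_inf(m, v0), bD = bD_inf(m, v0);
  double w = 0.0, theta = m.theta0, refr = 0.0, Vf = v0;

  const double a_h  = 1.0 - std::exp(-dt / m.tau_h);
  const double a_T  = 1.0 - std::exp(-dt / m.tau_Th);
  const double a_D  = 1.0 - std::exp(-dt / m.tau_Db);
  const double a_f  = 1.0 - std::exp(-dt / m.tau_filt);
  const bool has_noise = noise.size() > 0;

  NumericVector out(n_out);
  std::vector<double> spikes;
  out[0] = V;

  for (int i = 0; i < n_steps; ++i) {
    double t = i * dt;
    double Iinj = bias_pA + ((t >= onset && t < onset + duration) ? step_pA : 0.0);
    if (has_noise) Iinj += noise[i % noise.size()];

    double Iion = ionic(m, V, mh, hT, bD) + w;
    V += dt * (Iinj - Iion) / m.C;
    mh += a_h * (mh_inf(m, V) - mh);
    hT += a_T * (hT_inf(m, V) - hT);
    bD += a_D * (bD_inf(m, V) - bD);
    w += dt * (-w / m.tau_w);
    theta += dt * (m.theta0 - theta) / m.tau_theta;
    Vf += a_f * (V - Vf);
    if (refr > 0) refr -= dt;

    if (!std::isfinite(V))
      stop("non-finite membrane voltage during sweep '%s'", sweep_label.c_str());

    bool blocked = Vf > m.v_block;
    if (V >= theta && refr <= 0 && !blocked) {
      spikes.push_back(t + dt);
      V = m.v_reset;
      w += m.b_w;
      theta += m.d_theta;
      refr = m.t_ref;
    }
    if ((i + 1) % thin == 0) out[(i + 1) / thin] = V;
  }

  // paint spike peaks into the sampled trace so threshold-based event
  // detection sees overshooting action potentials
  for (double ts : spikes) {
    int k = (int)std::round(ts / dt_out);
    if (k >= 0 && k < n_out) out[k] = m.v_spike;
  }

  return List::create(_["response"] = out,
                      _["spike_times"] = wrap(spikes));
}

// Voltage-clamp sweep under an ideal clamp: V follows the command exactly,
// gates relax toward their steady state at the clamped voltage, and the
// recorded signal is the total ionic current (outward positive, pA).
// [[Rcpp::export]]
List sim_vc_cpp(NumericVector par, double v_hold, double v_step,
                double t_total, double onset, double duration,
                double dt, double dt_out, std::string sweep_label) {
  ModelPar m = unpack(par);
  const int n_steps = (int)std::round(t_total / dt);
  const int thin = (int)std::round(dt_out / dt);
  const int n_out = n_steps / thin + 1;

  double mh = mh_inf(m, v_hold), hT = hT_inf(m, v_hold), bD = bD_inf(m, v_hold);
  const double a_h = 1.0 - std::exp(-dt / m.tau_h);
  const double a_T = 1.0 - std::exp(-dt / m.tau_Th);
  const double a_D = 1.0 - std::exp(-dt / m.tau_Db);

  NumericVector out(n_out);
  out[0] = ionic(m, v_hold, mh, hT, bD);

  for (int i = 0; i < n_steps; ++i) {
    double t = i * dt;
    double V = (t >= onset && t < onset + duration) ? v_step : v_hold;
    mh += a_h * (mh_inf(m, V) - mh);
    hT += a_T * (hT_inf(m, V) - hT);
    bD += a_D * (bD_inf(m, V) - bD);
    double I = ionic(m, V, mh, hT, bD);
    if (!std::isfinite(I))
      stop("non-finite clamp current during sweep '%s'", sweep_label.c_str());
    if ((i + 1) % thin == 0) out[(i + 1) / thin] = I;
  }
  return List::create(_["response"] = out);
}
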