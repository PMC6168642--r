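#include <Rcpp.h>
using namespace Rcpp;

// Multi-compartment Hodgkin-Huxley cable solver.
//
// Units follow the usual compartmental-modelling convention: mV, ms, nA,
// uS, nF. The tree is encoded by a parent vector with parent[i] < i
// (root = compartment 0 = soma), so the linear system of the implicit
// voltage step is solved exactly with Hines elimination (leaf-to-root
// factorization, root-to-leaf back-substitution).
//
// Channels: transient Na (m^3 h), delayed-rectifier K (n^4), leak.
// Gates are advanced analytically (exponential Euler) at the current
// voltage, then the voltage step is backward Euler with conductances
// frozen, which is unconditionally stable.
//
// Excitatory synapses are two-exponential conductances; because the
// waveform is linear in its events, all synapses that share a compartment
// are aggregated into one (rise, decay) state pair per compartment.

static inline double alpha_m(double v) {
  double x = v + 40.0;
  if (std::fabs(x) < 1e-6) return 1.0; // limit of 0.1*x/(1-exp(-x/10))
  return 0.1 * x / (1.0 - std::exp(-x / 10.0));
}
static inline double beta_m(double v) { return 4.0 * std::exp(-(v + 65.0) / 18.0); }
static inline double alpha_h(double v) { return 0.07 * std::exp(-(v + 65.0) / 20.0); }
static inline double beta_h(double v) { return 1.0 / (1.0 + std::exp(-(v + 35.0) / 10.0)); }
static inline double alpha_n(double v) {
  double x = v + 55.0;
  if (std::fabs(x) < 1e-6) return 0.1;
  return 0.01 * x / (1.0 - std::exp(-x / 10.0));
}
static inline double beta_n(double v) { return 0.125 * std::exp(-(v + 65.0) / 80.0); }

// [[Rcpp::export]]
List cable_run_cpp(IntegerVector parent,
                   NumericVector cm_nf, NumericVector ga_us,
                   NumericVector gna_us, NumericVector gk_us,
                   NumericVector gl_us,
                   double ena, double ek, double el,
                   double v_init,
                   NumericVector ev_time, IntegerVector ev_comp,
                   NumericVector ev_w,
                   double tau_rise, double tau_decay, double e_syn,
                   double dt, double duration,
                   double v_thresh, int record_every,
                   double rate_scale) {
  const int n = parent.size();
  const int nsteps = (int) std::lround(duration / dt);

  std::vector<double> V(n, v_init), m(n), h(n), ng(n);
  for (int i = 0; i < n; ++i) {
    double am = alpha_m(v_init), bm = beta_m(v_init);
    double ah = alpha_h(v_init), bh = beta_h(v_init);
    double an = alpha_n(v_init), bn = beta_n(v_init);
    m[i] = am / (am + bm); h[i] = ah / (ah + bh); ng[i] = an / (an + bn);
  }

  // rate lookup tables over the working voltage range (0.05 mV bins,
  // linear interpolation), rebuilt per call since dt is fixed
  const double tab_v0 = -120.0, tab_v1 = 80.0, tab_dv = 0.05;
  const int tab_n = (int) std::lround((tab_v1 - tab_v0) / tab_dv) + 1;
  const double tab_inv_dv = 1.0 / tab_dv;
  std::vector<double> tab_minf(tab_n), tab_mexp(tab_n),
      tab_hinf(tab_n), tab_hexp(tab_n), tab_ninf(tab_n), tab_nexp(tab_n);
  for (int j = 0; j < tab_n; ++j) {
    double v = tab_v0 + j * tab_dv;
    double am = alpha_m(v) * rate_scale, bm = beta_m(v) * rate_scale;
    double ah = alpha_h(v) * rate_scale, bh = beta_h(v) * rate_scale;
    double an = alpha_n(v) * rate_scale, bn = beta_n(v) * rate_scale;
    tab_minf[j] = am / (am + bm); tab_mexp[j] = std::exp(-dt * (am + bm));
    tab_hinf[j] = ah / (ah + bh); tab_hexp[j] = std::exp(-dt * (ah + bh));
    tab_ninf[j] = an / (an + bn); tab_nexp[j] = std::exp(-dt * (an + bn));
  }

  // biexponential normalization so one event of weight w peaks at w
  double tp = tau_rise * tau_decay / (tau_decay - tau_rise) *
              std::log(tau_decay / tau_rise);
  double norm = 1.0 / (std::exp(-tp / tau_decay) - std::exp(-tp / tau_rise));
  const double dec_r = std::exp(-dt / tau_rise);
  const double dec_d = std::exp(-dt / tau_decay);
  std::vector<double> synA(n, 0.0), synB(n, 0.0);

  std::vector<double> D(n), R(n), OD(n);
  std::vector<double> spikes;
  std::vector<double> vrec;
  bool above = V[0] >= v_thresh;
  int ei = 0; const int nev = ev_time.size();
  bool blown = false; double blow_t = NA_REAL;

  for (int k = 0; k < nsteps && !blown; ++k) {
    const double t = k * dt;

    // synaptic events arriving in [t, t+dt)
    while (ei < nev && ev_time[ei] < t + dt) {
      int c = ev_comp[ei];
      synA[c] += ev_w[ei] * norm;
      synB[c] += ev_w[ei] * norm;
      ++ei;
    }
    for (int i = 0; i < n; ++i) { synA[i] *= dec_r; synB[i] *= dec_d; }

    // gate update (exponential Euler, interpolated rate tables)
    for (int i = 0; i < n; ++i) {
      double x = (V[i] - tab_v0) * tab_inv_dv;
      if (x < 0.0) x = 0.0;
      if (x > tab_n - 1.001) x = tab_n - 1.001;
      int j = (int) x;
      double fr = x - j;
      if (gna_us[i] > 0.0) {
        double mi = tab_minf[j] + fr * (tab_minf[j + 1] - tab_minf[j]);
        double me = tab_mexp[j] + fr * (tab_mexp[j + 1] - tab_mexp[j]);
        double hi = tab_hinf[j] + fr * (tab_hinf[j + 1] - tab_hinf[j]);
        double he = tab_hexp[j] + fr * (tab_hexp[j + 1] - tab_hexp[j]);
        m[i] = mi + (m[i] - mi) * me;
        h[i] = hi + (h[i] - hi) * he;
      }
      if (gk_us[i] > 0.0) {
        double ni = tab_ninf[j] + fr * (tab_ninf[j + 1] - tab_ninf[j]);
        double ne = tab_nexp[j] + fr * (tab_nexp[j + 1] - tab_nexp[j]);
        ng[i] = ni + (ng[i] - ni) * ne;
      }
    }

    // assemble backward-Euler system
    for (int i = 0; i < n; ++i) {
      double gna = gna_us[i] * m[i] * m[i] * m[i] * h[i];
      double gk = gk_us[i] * ng[i] * ng[i] * ng[i] * ng[i];
      double gs = synB[i] - synA[i];
      if (gs < 0.0) gs = 0.0;
      double cdt = cm_nf[i] / dt;
      D[i] = cdt + gl_us[i] + gna + gk + gs;
      R[i] = cdt * V[i] + gl_us[i] * el + gna * ena + gk * ek + gs * e_syn;
      OD[i] = 0.0;
    }
    for (int i = 1; i < n; ++i) {
      int p = parent[i];
      D[i] += ga_us[i]; D[p] += ga_us[i];
      OD[i] = -ga_us[i];
    }
    // Hines elimination (parent[i] < i)
    for (int i = n - 1; i >= 1; --i) {
      int p = parent[i];
      double f = OD[i] / D[i];
      D[p] -= f * OD[i];
      R[p] -= f * R[i];
    }
    V[0] = R[0] / D[0];
    for (int i = 1; i < n; ++i)
      V[i] = (R[i] - OD[i] * V[parent[i]]) / D[i];

    if (!std::isfinite(V[0])) { blown = true; blow_t = t; break; }

    // somatic spike detection: upward threshold crossing
    if (!above && V[0] >= v_thresh) { spikes.push_back(t + dt); above = true; }
    else if (above && V[0] < v_thresh) above = false;

    if (record_every > 0 && ((k + 1) % record_every == 0))
      vrec.push_back(V[0]);
  }

  return List::create(
    _["spike_times"] = wrap(spikes),
    _["v_soma"] = wrap(vrec),
    _["v_final"] = wrap(V),
    _["diverged"] = blown,
    _["diverged_at"] = blow_t);
}
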