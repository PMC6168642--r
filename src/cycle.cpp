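#include <Rcpp.h>
using namespace Rcpp;

// Discrete-time stepper for the three-stage synaptic vesicle cycle:
//   (1) per-slot preparation in the readily releasable pool, exact
//       exponential relaxation of the state value s_i toward s_m;
//   (2) calcium-gated exocytosis at a limited number of release sites,
//       rate-capped per site (wall-clock refractory) and per synapse
//       (minimum spacing in gate-open time);
//   (3) return to the recycling pool at rate min(v_rm, (h_m - h)/tau_r)
//       with fractional accrual so the pool count stays integral.
//
// The gate is supplied as merged, sorted half-open windows [start, end).
// State is passed in and out so the caller can change tau_s between
// segments (energy regulation) without losing pool/site history.

static double open_overlap(double t0, double t1,
                           const NumericVector &ws, const NumericVector &we,
                           int &wi) {
  // advance window pointer past windows ending before t0, then sum overlap
  int n = ws.size();
  while (wi < n && we[wi] <= t0) ++wi;
  double o = 0.0;
  for (int j = wi; j < n && ws[j] < t1; ++j) {
    double a = ws[j] > t0 ? ws[j] : t0;
    double b = we[j] < t1 ? we[j] : t1;
    if (b > a) o += b - a;
  }
  return o;
}

// [[Rcpp::export]]
List cycle_run_cpp(NumericVector win_start, NumericVector win_end,
                   double t0, double t1, double dt,
                   double tau_s, List params, List state,
                   double sample_dt) {
  const int n_rrp = as<int>(params["n_rrp"]);
  const double s_m = as<double>(params["s_m"]);
  const double prep_thr = as<double>(params["prep_fraction"]) * s_m;
  const int n_sites = as<int>(params["n_sites"]);
  const double site_refr = as<double>(params["site_refractory"]);
  const double spacing = as<double>(params["release_spacing"]); // gate-open s
  const double v_rm = as<double>(params["v_rm"]);
  const double tau_r = as<double>(params["tau_r"]);
  const int h_m = as<int>(params["h_m"]);

  NumericVector s = clone(as<NumericVector>(state["s"]));
  LogicalVector occupied = clone(as<LogicalVector>(state["occupied"]));
  int pool = as<int>(state["pool"]);
  NumericVector site_busy = clone(as<NumericVector>(state["site_busy"]));
  int in_transit = as<int>(state["in_transit"]);
  double released = as<double>(state["released"]);
  double returned = as<double>(state["returned"]);
  double return_accum = as<double>(state["return_accum"]);
  double next_release_open = as<double>(state["next_release_open"]);
  double open_clock = as<double>(state["open_clock"]);

  const int nsteps = (int) std::lround((t1 - t0) / dt);
  const double decay = std::exp(-dt / tau_s);
  const double eps = 1e-9;
  int wi = 0;

  std::vector<double> rel_times;
  int sample_every = sample_dt > 0 ? (int) std::lround(sample_dt / dt) : 0;
  std::vector<double> samp_t, samp_pool, samp_vr, samp_transit, samp_rel;

  for (int k = 0; k < nsteps; ++k) {
    const double t = t0 + k * dt;
    const double o = open_overlap(t, t + dt, win_start, win_end, wi);
    const double open_start = open_clock;
    open_clock += o;

    // refill empty RRP slots from the recycling pool (vesicles enter at s=0)
    for (int i = 0; i < n_rrp && pool > 0; ++i) {
      if (!occupied[i]) { occupied[i] = true; s[i] = 0.0; --pool; }
    }

    // exact exponential preparation update (step-size invariant)
    for (int i = 0; i < n_rrp; ++i)
      if (occupied[i]) s[i] = s_m + (s[i] - s_m) * decay;

    // calcium-gated release while tokens, prepared vesicles and sites allow
    if (o > 0.0) {
      for (;;) {
        double rt_open = next_release_open > open_start ? next_release_open
                                                        : open_start;
        if (rt_open > open_clock + eps) break; // synapse cap exhausted
        // most-prepared slot first (tie: lowest index)
        int slot = -1; double best = -1.0;
        for (int i = 0; i < n_rrp; ++i)
          if (occupied[i] && s[i] >= prep_thr && s[i] > best) {
            best = s[i]; slot = i;
          }
        if (slot < 0) break; // nothing prepared
        int site = -1; double earliest = R_PosInf;
        for (int j = 0; j < n_sites; ++j)
          if (site_busy[j] <= t + eps && site_busy[j] < earliest) {
            earliest = site_busy[j]; site = j;
          }
        if (site < 0) break; // all sites refractory
        site_busy[site] = t + site_refr;
        next_release_open = rt_open + spacing;
        occupied[slot] = false;
        released += 1.0; ++in_transit;
        rel_times.push_back(t);
        if (pool > 0) { occupied[slot] = true; s[slot] = 0.0; --pool; }
      }
    }

    // endocytotic return, rate set by the pool deficit and capped at v_rm
    double v_r = (double)(h_m - pool) / tau_r;
    if (v_r > v_rm) v_r = v_rm;
    if (v_r < 0.0) v_r = 0.0;
    if (in_transit > 0) {
      return_accum += v_r * dt;
      while (return_accum >= 1.0 && in_transit > 0 && pool < h_m) {
        ++pool; --in_transit; returned += 1.0; return_accum -= 1.0;
      }
    } else {
      return_accum = 0.0; // endocytosis pipeline empty
    }

    if (sample_every > 0 && ((k + 1) % sample_every == 0)) {
      samp_t.push_back(t + dt);
      samp_pool.push_back(pool);
      samp_vr.push_back(v_r);
      samp_transit.push_back(in_transit);
      samp_rel.push_back(released);
    }
  }

  List out_state = List::create(
    _["s"] = s, _["occupied"] = occupied, _["pool"] = pool,
    _["site_busy"] = site_busy, _["in_transit"] = in_transit,
    _["released"] = released, _["returned"] = returned,
    _["return_accum"] = return_accum,
    _["next_release_open"] = next_release_open,
    _["open_clock"] = open_clock);

  return List::create(
    _["state"] = out_state,
    _["release_times"] = wrap(rel_times),
    _["sample_t"] = wrap(samp_t),
    _["sample_pool"] = wrap(samp_pool),
    _["sample_vr"] = wrap(samp_vr),
    _["sample_in_transit"] = wrap(samp_transit),
    _["sample_released"] = wrap(samp_rel));
}
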