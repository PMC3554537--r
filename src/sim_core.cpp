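// Network integration engine.
//
// Per-synapse conductances with a shared decay constant are aggregated into
// per-neuron receptor pools (AMPA, NMDA fast/slow, GABA, afferent): decay is
// then one multiply per neuron per step and a presynaptic spike deposits its
// increment into the postsynaptic pool.  Short-term depression D depends only
// on the presynaptic spike train, so it is stored per presynaptic neuron.
// HSP scaling factors are stored per (postsynaptic PY, microdomain) pair,
// one excitatory and one inhibitory value: all synapses assigned to a domain
// share the same drive terms and the same initial value s = 1, so their
// trajectories coincide.
//
// All randomness (afferent Poisson drive) draws from R's RNG so that
// set.seed() at the R level makes runs fully reproducible.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double getd(const List& l, const char* nm) {
  return as<double>(l[nm]);
}

// [[Rcpp::export]]
List sim_core_cpp(List net, List par, List state, List ctrl) {
  // ---- network arrays (0-based indices) ----
  const IntegerVector ntype = net["ntype"];          // 0 = PY, 1 = IN
  const int N = ntype.size();
  const IntegerVector syn_post = net["syn_post"];
  const IntegerVector syn_kind = net["syn_kind"];    // 0 PP, 1 IP, 2 PI, 3 II
  const IntegerVector syn_dom  = net["syn_dom"];     // global domain id, -1 if none
  const IntegerVector out_ptr  = net["out_ptr"];     // CSR over presyn neuron
  const IntegerVector out_syn  = net["out_syn"];
  const NumericVector aff_rate = net["aff_rate"];    // Hz, per neuron
  const NumericVector I_inj    = net["I_inj"];       // constant injected current
  const int ndom = as<int>(net["ndom"]);
  const LogicalVector dom_active = net["dom_active"];
  const IntegerVector dom_ptr = net["dom_ptr"];      // CSR: presyn PY sets per domain
  const IntegerVector dom_pre = net["dom_pre"];
  const IntegerVector dom_post = net["dom_post"];    // owning PY neuron per domain

  // ---- parameters ----
  const double C = getd(par, "C"), gNa = getd(par, "g_na"), gK = getd(par, "g_k"),
    gL = getd(par, "g_l"), gAHP = getd(par, "g_ahp"),
    ENa = getd(par, "e_na"), EK = getd(par, "e_k"), EL = getd(par, "e_l"),
    V1 = getd(par, "v1"), V2 = getd(par, "v2"), V3 = getd(par, "v3"),
    V4 = getd(par, "v4"), phi = getd(par, "phi"),
    thresh = getd(par, "spike_threshold"),
    tau_z = getd(par, "tau_z"), delta_z = getd(par, "delta_z"),
    tau_ampa = getd(par, "tau_ampa"), tau_gaba = getd(par, "tau_gaba"),
    tau_nf = getd(par, "tau_nmda_fast"), tau_ns = getd(par, "tau_nmda_slow"),
    tau_d = getd(par, "tau_d"), dstr = getd(par, "d"),
    Eexc = getd(par, "e_exc"), Egaba = getd(par, "e_gaba"),
    ghat_pp = getd(par, "ghat_pp"), ghat_ip = getd(par, "ghat_ip"),
    ghat_pi = getd(par, "ghat_pi"), ghat_ii = getd(par, "ghat_ii"),
    nmda_frac = getd(par, "nmda_frac"),
    ghat_aff_py = getd(par, "ghat_aff_py"), ghat_aff_in = getd(par, "ghat_aff_in"),
    tau_aff = getd(par, "tau_aff"), Eaff = getd(par, "e_aff"),
    kappa = getd(par, "kappa"), r_target = getd(par, "r_target"),
    tau_rate = getd(par, "tau_rate_ms"),
    s_min = getd(par, "s_min"), s_max = getd(par, "s_max"),
    dt_hsp = getd(par, "dt_hsp_ms");
  const int scheme = as<int>(par["scheme"]);   // 0 local, 1 global,
                                               // 2 global_up_local_down,
                                               // 3 global_up_no_down
  const bool hsp_on = as<bool>(par["hsp_on"]);

  // ---- control ----
  const double dt = getd(ctrl, "dt"), total_ms = getd(ctrl, "total_ms");
  const long nstep = (long) std::llround(total_ms / dt);
  const IntegerVector rec_idx = ctrl["record_v_idx"];
  const int rec_stride = as<int>(ctrl["record_stride"]);
  const bool collect_spikes = as<bool>(ctrl["collect_spikes"]);
  const int ts_stride = as<int>(ctrl["ts_stride"]);
  const double t0 = getd(ctrl, "t_offset");

  // ---- state (copied so that the caller's list is untouched) ----
  NumericVector V = clone(as<NumericVector>(state["V"]));
  NumericVector w = clone(as<NumericVector>(state["w"]));
  NumericVector z = clone(as<NumericVector>(state["z"]));
  NumericVector D = clone(as<NumericVector>(state["D"]));
  NumericVector r = clone(as<NumericVector>(state["r"]));       // EMA rate, Hz
  NumericVector gA = clone(as<NumericVector>(state["g_ampa"]));
  NumericVector gG = clone(as<NumericVector>(state["g_gaba"]));
  NumericVector xf = clone(as<NumericVector>(state["x_fast"]));
  NumericVector xs = clone(as<NumericVector>(state["x_slow"]));
  NumericVector gF = clone(as<NumericVector>(state["g_aff"]));
  NumericVector s_exc = clone(as<NumericVector>(state["s_exc"]));
  NumericVector s_inh = clone(as<NumericVector>(state["s_inh"]));
  LogicalVector latch = clone(as<LogicalVector>(state["in_spike"]));

  // precomputed per-step factors
  const double dec_ampa = std::exp(-dt / tau_ampa), dec_gaba = std::exp(-dt / tau_gaba),
    dec_nf = std::exp(-dt / tau_nf), dec_ns = std::exp(-dt / tau_ns),
    dec_aff = std::exp(-dt / tau_aff), dec_z = std::exp(-dt / tau_z),
    dec_d = std::exp(-dt / tau_d), dec_r = std::exp(-dt / tau_rate);
  const double r_kick = 1000.0 / tau_rate;       // Hz per spike for the EMA
  // NMDA peak normalization: unit increments to both components give a
  // conductance peak of (ts/tf)^(-tf/(ts-tf)) - (ts/tf)^(-ts/(ts-tf)).
  const double tpk = std::log(tau_ns / tau_nf) * tau_ns * tau_nf / (tau_ns - tau_nf);
  const double nmda_peak = std::exp(-tpk / tau_ns) - std::exp(-tpk / tau_nf);
  const double ghat_nmda = nmda_frac * ghat_pp / nmda_peak;

  const int hsp_stride = std::max(1, (int) std::llround(dt_hsp / dt));
  const double dt_hsp_s = hsp_stride * dt / 1000.0;

  std::vector<double> sp_t; std::vector<int> sp_i;
  const int nrec = rec_idx.size();
  const long nrec_steps = (nrec > 0 && nstep > 0) ? ((nstep - 1) / rec_stride + 1) : 0;
  NumericMatrix vrec(nrec > 0 ? nrec_steps : 0, nrec);
  const long nts = (ts_stride > 0 && nstep > 0) ? ((nstep - 1) / ts_stride + 1) : 0;
  NumericMatrix ts(nts, 3);  // time, mean PY EMA rate, mean active-domain s_exc
  long clip_events = 0;
  long rec_row = 0, ts_row = 0;

  int n_py = 0;
  for (int i = 0; i < N; ++i) if (ntype[i] == 0) ++n_py;

  for (long step = 0; step < nstep; ++step) {
    const double t = t0 + step * dt;

    if (nrec > 0 && step % rec_stride == 0 && rec_row < nrec_steps) {
      for (int k = 0; k < nrec; ++k) vrec(rec_row, k) = V[rec_idx[k]];
      ++rec_row;
    }
    if (ts_stride > 0 && step % ts_stride == 0 && ts_row < nts) {
      double rs = 0, ss = 0; int na = 0;
      for (int i = 0; i < N; ++i) if (ntype[i] == 0) rs += r[i];
      for (int m = 0; m < ndom; ++m) if (dom_active[m]) { ss += s_exc[m]; ++na; }
      ts(ts_row, 0) = t;
      ts(ts_row, 1) = n_py > 0 ? rs / n_py : 0.0;
      ts(ts_row, 2) = na > 0 ? ss / na : NA_REAL;
      ++ts_row;
    }

    // membrane + gating update, spike detection
    for (int i = 0; i < N; ++i) {
      const double v = V[i];
      const bool is_py = (ntype[i] == 0);
      const double minf = 0.5 * (1.0 + std::tanh((v - V1) / V2));
      const double winf = 0.5 * (1.0 + std::tanh((v - V3) / V4));
      const double lamw = phi * std::cosh((v - V3) / (2.0 * V4));
      const double g_nmda = xs[i] - xf[i];
      double I = gA[i] * (v - Eexc) + (g_nmda > 0 ? g_nmda : 0) * (v - Eexc)
        + gG[i] * (v - Egaba) + gF[i] * (v - Eaff) + I_inj[i];
      if (is_py) I += gAHP * z[i] * (v - EK);
      const double dV = (-gNa * minf * (v - ENa) - gK * w[i] * (v - EK)
                         - gL * (v - EL) - I) / C;
      const double vnew = v + dt * dV;
      w[i] = winf + (w[i] - winf) * std::exp(-dt * lamw);
      V[i] = vnew;

      // decay of pools and slow variables
      gA[i] *= dec_ampa; gG[i] *= dec_gaba; xf[i] *= dec_nf; xs[i] *= dec_ns;
      gF[i] *= dec_aff;
      if (is_py) z[i] *= dec_z;
      D[i] = 1.0 - (1.0 - D[i]) * dec_d;
      r[i] *= dec_r;

      // afferent Poisson drive (per-step Bernoulli thinning)
      const double rate = aff_rate[i];
      if (rate > 0 && unif_rand() < rate * dt * 1e-3)
        gF[i] += is_py ? ghat_aff_py : ghat_aff_in;

      // upward threshold crossing with latch
      if (!latch[i] && vnew >= thresh) {
        latch[i] = true;
        if (collect_spikes) { sp_t.push_back(t + dt); sp_i.push_back(i); }
        r[i] += r_kick;
        if (is_py) { z[i] += delta_z; if (z[i] > 1.0) z[i] = 1.0; }
        // deliver to postsynaptic pools
        const double Di = D[i];
        for (int k = out_ptr[i]; k < out_ptr[i + 1]; ++k) {
          const int s = out_syn[k];
          const int post = syn_post[s];
          switch (syn_kind[s]) {
          case 0: { // PY -> PY: AMPA + NMDA, scaled by s and D
            const double sc = s_exc[syn_dom[s]] * Di;
            gA[post] += ghat_pp * sc;
            xf[post] += ghat_nmda * sc; xs[post] += ghat_nmda * sc;
            break; }
          case 1:   // IN -> PY: GABA, scaled by domain s_inh, D fixed at 1
            gG[post] += ghat_ip * s_inh[syn_dom[s]];
            break;
          case 2:   // PY -> IN: AMPA only, depressing, no HSP
            gA[post] += ghat_pi * Di;
            break;
          default:  // IN -> IN
            gG[post] += ghat_ii;
          }
        }
        if (ntype[i] == 0) D[i] *= (1.0 - dstr);   // depression: excitatory only
      } else if (latch[i] && vnew < thresh) {
        latch[i] = false;
      }
      if (!std::isfinite(vnew))
        stop("non-finite membrane potential at t = %f ms (neuron %d)", t, i + 1);
    }

    // HSP update at its own cadence
    if (hsp_on && kappa > 0 && (step + 1) % hsp_stride == 0) {
      double rglob = 0;
      for (int i = 0; i < N; ++i) if (ntype[i] == 0) rglob += r[i];
      rglob = n_py > 0 ? rglob / n_py : 0.0;
      for (int m = 0; m < ndom; ++m) {
        if (!dom_active[m]) continue;
        double u;
        if (scheme == 0) {                 // local: presynaptic-set mean
          double acc = 0; int cnt = 0;
          for (int k = dom_ptr[m]; k < dom_ptr[m + 1]; ++k) { acc += r[dom_pre[k]]; ++cnt; }
          u = cnt > 0 ? acc / cnt : rglob;
        } else u = rglob;                  // all global_* schemes
        double down = 0;
        if (scheme != 3) {
          const double v_drive = (scheme == 1) ? rglob : r[dom_post[m]];
          down = std::max(0.0, v_drive / r_target - 1.0);
        }
        const double up = std::max(0.0, 1.0 - u / r_target);
        const double ds = kappa * (up - down) * dt_hsp_s;
        double se = s_exc[m] + ds, si = s_inh[m] - ds;
        if (se < s_min) { se = s_min; ++clip_events; }
        if (se > s_max) { se = s_max; ++clip_events; }
        if (si < s_min) { si = s_min; ++clip_events; }
        if (si > s_max) { si = s_max; ++clip_events; }
        s_exc[m] = se; s_inh[m] = si;
      }
    }
  }

  List out_state = List::create(
    _["V"] = V, _["w"] = w, _["z"] = z, _["D"] = D, _["r"] = r,
    _["g_ampa"] = gA, _["g_gaba"] = gG, _["x_fast"] = xf, _["x_slow"] = xs,
    _["g_aff"] = gF, _["s_exc"] = s_exc, _["s_inh"] = s_inh,
    _["in_spike"] = latch);
  return List::create(
    _["spike_t"] = wrap(sp_t), _["spike_i"] = wrap(sp_i),
    _["state"] = out_state, _["vrec"] = vrec, _["ts"] = ts,
    _["clip_events"] = clip_events,
    _["t_end"] = t0 + nstep * dt);
}
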