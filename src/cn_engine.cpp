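// Fixed-step (exponential-Euler) integrator for a two-compartment
// conductance-based cerebellar nucleus neuron.
//
// Soma: fast Na (instantaneous activation, h gate), delayed-rectifier K,
// leak, persistent Na with slow inactivation.  Dendrite: leak, HCN,
// low-voltage-activated (T-type) Ca with inactivation, and all synapses:
// GABA-A from Purkinje neurons with frequency-dependent depression, and
// mossy-fiber AMPA + fast/slow NMDA with sigmoidal voltage dependence.
// Units: ms, mV, nS, pA, pF throughout.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double vtrap(double x, double y) {
  // x / (1 - exp(-x/y)) with the removable singularity at x = 0 handled
  return (std::fabs(x / y) < 1e-6) ? y * (1.0 + x / (2.0 * y))
                                   : x / (1.0 - std::exp(-x / y));
}

static inline double rss_release(double r) {
  return 0.08 + 0.60 * std::exp(-2.84 * r) + 0.32 * std::exp(-0.02 * r);
}
static inline double tau_depression(double r) {
  return 2.0 + 2500.0 * std::exp(-0.274 * r) + 100.0 * std::exp(-0.022 * r);
}

struct DblExp {
  // double-exponential conductance as difference of two decaying
  // accumulators; increments are normalized so one event of weight w
  // peaks at w
  double ar = 0.0, ad = 0.0, fr, fd, norm;
  void init(double tau_r, double tau_d, double dt) {
    fr = std::exp(-dt / tau_r);
    fd = std::exp(-dt / tau_d);
    double tp = tau_r * tau_d / (tau_d - tau_r) * std::log(tau_d / tau_r);
    norm = 1.0 / (std::exp(-tp / tau_d) - std::exp(-tp / tau_r));
  }
  inline void add(double w) { ar += w * norm; ad += w * norm; }
  inline void decay() { ar *= fr; ad *= fd; }
  inline double g() const { return ad - ar; }
};

// [[Rcpp::export(name = ".cn_engine")]]
List cn_engine(List prm,
               NumericVector pn_t, IntegerVector pn_syn,
               NumericVector pn_rate_hz,
               NumericVector mf_t,
               double duration, double dt,
               bool record, double record_dt) {
  auto P = [&](const char* nm) { return as<double>(prm[nm]); };

  const double Cs = P("c_soma"), Cd = P("c_dend"), gc = P("g_couple");
  const double gNa = P("g_na"), gK = P("g_kdr"), gLs = P("g_leak_soma");
  const double gLd = P("g_leak_dend"), EL = P("e_leak");
  const double gNaP = P("g_nap"), gCaT = P("g_calva"), gH = P("g_hcn");
  const double ENa = P("e_na"), EK = P("e_k"), ECa = P("e_ca"),
               EH = P("e_hcn"), EGABA = P("e_gaba"), Eexc = P("e_exc");
  const double g_gaba_max = P("gaba_gmax") * P("inh_gain");
  const double g_ampa_max = P("ampa_gmax") * P("exc_gain");
  const double g_nmdaf_max = P("nmdaf_gmax") * P("exc_gain");
  const double g_nmdas_max = P("nmdas_gmax") * P("exc_gain");
  const double s1f = P("nmdaf_s1"), s2f = P("nmdaf_s2");
  const double s1s = P("nmdas_s1"), s2s = P("nmdas_s2");
  const double vthresh = P("spike_threshold"), refrac = P("refractory");
  const double tau_hp = P("nap_tau_h"), tau_ht = P("calva_tau_h"),
               tau_mh = P("hcn_tau_m");

  DblExp gaba, ampa, nmdaf, nmdas;
  gaba.init(P("gaba_tau_rise"), P("gaba_tau_decay"), dt);
  ampa.init(P("ampa_tau_rise"), P("ampa_tau_decay"), dt);
  nmdaf.init(P("nmdaf_tau_rise"), P("nmdaf_tau_decay"), dt);
  nmdas.init(P("nmdas_tau_rise"), P("nmdas_tau_decay"), dt);

  // per-synapse depression state; release starts at the steady state for
  // each train's mean rate
  const int n_syn = pn_rate_hz.size();
  std::vector<double> rel(n_syn), t_last(n_syn, -1.0);
  for (int s = 0; s < n_syn; ++s) rel[s] = rss_release(pn_rate_hz[s]);

  const int n_steps = (int)std::ceil(duration / dt);
  const int rec_every = record ? std::max(1, (int)std::round(record_dt / dt)) : 0;
  const int n_rec = record ? n_steps / rec_every + 1 : 0;
  NumericVector rt(n_rec), rvs(n_rec), rvd(n_rec), rht(n_rec), rhp(n_rec),
                rgi(n_rec);
  std::vector<double> spikes;
  spikes.reserve(256);

  // initial state
  double Vs = -60.0, Vd = -60.0;
  double hNa = 0.8, nK = 0.1;
  double hP = 1.0 / (1.0 + std::exp((Vs + 80.0) / 7.0));
  double hT = 1.0 / (1.0 + std::exp((Vd + 80.0) / 5.0));
  double mH = 1.0 / (1.0 + std::exp((Vd + 75.0) / 5.5));

  int ipn = 0, imf = 0, irec = 0;
  const int n_pn = pn_t.size(), n_mf = mf_t.size();
  double last_spike = -1e9, v_prev = Vs;
  bool diverged = false;

  for (int step = 0; step <= n_steps; ++step) {
    double t = step * dt;

    // deliver events in [t, t + dt)
    while (ipn < n_pn && pn_t[ipn] < t + dt) {
      int s = pn_syn[ipn];
      if (t_last[s] >= 0.0) {
        double isi = pn_t[ipn] - t_last[s];
        if (isi > 1e-9) {
          double r = 1000.0 / isi;  // instantaneous frequency, Hz
          double rs = rss_release(r);
          rel[s] = rs + (rel[s] - rs) * std::exp(-isi / tau_depression(r));
        }
      }
      t_last[s] = pn_t[ipn];
      gaba.add(g_gaba_max * rel[s]);
      ++ipn;
    }
    while (imf < n_mf && mf_t[imf] < t + dt) {
      ampa.add(g_ampa_max);
      nmdaf.add(g_nmdaf_max);
      nmdas.add(g_nmdas_max);
      ++imf;
    }

    // gates (exponential Euler at current voltages)
    {
      double am = 0.1 * vtrap(Vs + 35.0, 10.0);
      double bm = 4.0 * std::exp(-(Vs + 60.0) / 18.0);
      double ah = 0.35 * std::exp(-(Vs + 58.0) / 20.0);
      double bh = 5.0 / (1.0 + std::exp(-0.1 * (Vs + 28.0)));
      double an = 0.05 * vtrap(Vs + 34.0, 10.0);
      double bn = 0.625 * std::exp(-(Vs + 44.0) / 80.0);
      double hinf = ah / (ah + bh), htau = 1.0 / (ah + bh);
      double ninf = an / (an + bn), ntau = 1.0 / (an + bn);
      hNa = hinf + (hNa - hinf) * std::exp(-dt / htau);
      nK = ninf + (nK - ninf) * std::exp(-dt / ntau);

      double hpinf = 1.0 / (1.0 + std::exp((Vs + 80.0) / 7.0));
      hP = hpinf + (hP - hpinf) * std::exp(-dt / tau_hp);
      double htinf = 1.0 / (1.0 + std::exp((Vd + 80.0) / 5.0));
      hT = htinf + (hT - htinf) * std::exp(-dt / tau_ht);
      double mhinf = 1.0 / (1.0 + std::exp((Vd + 75.0) / 5.5));
      mH = mhinf + (mH - mhinf) * std::exp(-dt / tau_mh);

      double minf = am / (am + bm);
      double gNa_t = gNa * minf * minf * minf * hNa;
      double gK_t = gK * nK * nK * nK * nK;
      double mpinf = 1.0 / (1.0 + std::exp(-(Vs + 57.0) / 5.0));
      double gNaP_t = gNaP * mpinf * hP;
      double mtinf = 1.0 / (1.0 + std::exp(-(Vd + 52.0) / 7.4));
      double gCaT_t = gCaT * mtinf * mtinf * hT;
      double gH_t = gH * mH;

      double ff = 1.0 / (1.0 + s1f * std::exp(-s2f * Vd));
      double fs = 1.0 / (1.0 + s1s * std::exp(-s2s * Vd));
      double g_inh = gaba.g();
      double g_exc = ampa.g() + nmdaf.g() * ff + nmdas.g() * fs;

      // soma
      double gtot_s = gLs + gNa_t + gK_t + gNaP_t + gc;
      double isrc_s = gLs * EL + gNa_t * ENa + gK_t * EK + gNaP_t * ENa +
                      gc * Vd;
      double vinf_s = isrc_s / gtot_s;
      double Vs_new = vinf_s + (Vs - vinf_s) * std::exp(-dt * gtot_s / Cs);

      // dendrite
      double gtot_d = gLd + gCaT_t + gH_t + g_inh + g_exc + gc;
      double isrc_d = gLd * EL + gCaT_t * ECa + gH_t * EH + g_inh * EGABA +
                      g_exc * Eexc + gc * Vs;
      double vinf_d = isrc_d / gtot_d;
      double Vd_new = vinf_d + (Vd - vinf_d) * std::exp(-dt * gtot_d / Cd);

      Vs = Vs_new;
      Vd = Vd_new;
      if (record && step % rec_every == 0 && irec < n_rec) {
        rt[irec] = t; rvs[irec] = Vs; rvd[irec] = Vd;
        rht[irec] = hT; rhp[irec] = hP; rgi[irec] = g_inh;
        ++irec;
      }
    }

    gaba.decay(); ampa.decay(); nmdaf.decay(); nmdas.decay();

    if (!std::isfinite(Vs) || !std::isfinite(Vd)) { diverged = true; break; }
    if (v_prev < vthresh && Vs >= vthresh && t - last_spike > refrac) {
      spikes.push_back(t);
      last_spike = t;
    }
    v_prev = Vs;
  }

  if (diverged)
    stop("integration diverged (non-finite membrane potential); reduce dt");

  List out = List::create(
    _["spikes"] = NumericVector(spikes.begin(), spikes.end()));
  if (record) {
    if (irec < n_rec) {
      rt = head(rt, irec); rvs = head(rvs, irec); rvd = head(rvd, irec);
      rht = head(rht, irec); rhp = head(rhp, irec); rgi = head(rgi, irec);
    }
    out["trace"] = DataFrame::create(
      _["t"] = rt, _["v_soma"] = rvs, _["v_dend"] = rvd,
      _["h_calva"] = rht, _["h_nap"] = rhp, _["g_inh"] = rgi);
  }
  return out;
}
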