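#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Units throughout: mV, ms, nA, uS (microsiemens), nF.
// With these, g * V is in nA and dV/dt = I / C_m is in mV/ms.

// ---------------------------------------------------------------------------
// Gating-rate functions (rates in 1/ms, V in mV).
// The 0/0 forms of alpha_n (V = -20 mV) and alpha_m (V = -16 mV) are
// evaluated by a first-order series within 1e-6 mV of the singular voltage:
//   c*x / (1 - exp(-x/10)) -> 10*c * (1 + x/20) + O(x^2)
// ---------------------------------------------------------------------------

static inline double f_alpha_n(double V) {
  double x = V + 20.0;
  if (std::fabs(x) < 1e-6) return 0.1 * (1.0 + x / 20.0);
  return 0.01 * x / (1.0 - std::exp(-x / 10.0));
}
static inline double f_beta_n(double V) {
  return 0.125 * std::exp(-(V + 30.0) / 80.0);
}
static inline double f_alpha_m(double V) {
  double x = V + 16.0;
  if (std::fabs(x) < 1e-6) return 1.0 * (1.0 + x / 20.0);
  return 0.1 * x / (1.0 - std::exp(-x / 10.0));
}
static inline double f_beta_m(double V) {
  return 4.0 * std::exp(-(V + 41.0) / 18.0);
}
static inline double f_alpha_h(double V) {
  return 0.07 * std::exp(-(V + 30.0) / 20.0);
}
static inline double f_beta_h(double V) {
  return 1.0 / (1.0 + std::exp(-V / 10.0));
}
static inline double f_m_inf(double V) {
  double a = f_alpha_m(V), b = f_beta_m(V);
  return a / (a + b);
}

// [[Rcpp::export]]
NumericVector cpp_gating_rates(double V, int gate) {
  double a, b;
  if (gate == 0)      { a = f_alpha_n(V); b = f_beta_n(V); }
  else if (gate == 1) { a = f_alpha_m(V); b = f_beta_m(V); }
  else                { a = f_alpha_h(V); b = f_beta_h(V); }
  return NumericVector::create(_["alpha"] = a, _["beta"] = b);
}

// [[Rcpp::export]]
double cpp_m_inf(double V) { return f_m_inf(V); }

// [[Rcpp::export]]
NumericVector cpp_gating_steady(double V) {
  double an = f_alpha_n(V), bn = f_beta_n(V);
  double ah = f_alpha_h(V), bh = f_beta_h(V);
  return NumericVector::create(_["n"] = an / (an + bn), _["h"] = ah / (ah + bh));
}

// Membrane and gating time-derivatives.  p = (Cm, phi, gK, gNa, gL, VK, VNa, VL).
static inline void derivs(double V, double n, double h, double Isyn,
                          const double *p,
                          double &dV, double &dn, double &dh) {
  double m = f_m_inf(V);
  double n2 = n * n;
  dV = (-p[2] * n2 * n2 * (V - p[5])
        - p[3] * m * m * m * h * (V - p[6])
        - p[4] * (V - p[7]) + Isyn) / p[0];
  dn = p[1] * (f_alpha_n(V) * (1.0 - n) - f_beta_n(V) * n);
  dh = p[1] * (f_alpha_h(V) * (1.0 - h) - f_beta_h(V) * h);
}

// [[Rcpp::export]]
NumericVector cpp_derivs(double V, double n, double h, double Isyn,
                         NumericVector p) {
  double dV, dn, dh;
  derivs(V, n, h, Isyn, p.begin(), dV, dn, dh);
  return NumericVector::create(_["dV"] = dV, _["dn"] = dn, _["dh"] = dh);
}

// ---------------------------------------------------------------------------
// Single-cell simulation, Heun (predictor-corrector) scheme.
//
// External input: constant current + optional rectangular pulse + optional
// train of conductance events through one double-exponential synapse
// (event times are snapped to the integration grid; rise and decay
// accumulators each gain +1 per event and decay with their own tau, so
// g(t) = g' / (tau_d - tau_r) * (A_d - A_r) reproduces the closed-form
// double exponential exactly for an isolated event).
//
// Spikes: upward crossing of v_th with a lockout; spike times linearly
// interpolated between grid points.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_simulate_single(NumericVector p, double V0, double n0, double h0,
                         double I_const, double duration, double dt,
                         double pulse_amp, double pulse_start, double pulse_dur,
                         NumericVector syn_times, double syn_g,
                         double syn_tr, double syn_td, double syn_E,
                         double v_th, double lockout, bool record) {
  int n_steps = (int)std::lround(duration / dt);
  const double *pp = p.begin();

  double V = V0;
  double n = (n0 >= 0.0) ? n0 : f_alpha_n(V0) / (f_alpha_n(V0) + f_beta_n(V0));
  double h = (h0 >= 0.0) ? h0 : f_alpha_h(V0) / (f_alpha_h(V0) + f_beta_h(V0));

  // synaptic event machinery
  bool has_syn = syn_times.size() > 0 && syn_g != 0.0;
  std::vector<int> ev_steps(syn_times.size());
  for (int i = 0; i < syn_times.size(); ++i)
    ev_steps[i] = (int)std::lround(syn_times[i] / dt);
  std::sort(ev_steps.begin(), ev_steps.end());
  size_t ev_ptr = 0;
  double a_r = 0.0, a_d = 0.0;
  double dec_r = has_syn ? std::exp(-dt / syn_tr) : 1.0;
  double dec_d = has_syn ? std::exp(-dt / syn_td) : 1.0;
  double syn_norm = has_syn ? syn_g / (syn_td - syn_tr) : 0.0;

  NumericVector Vtr, ntr, htr;
  if (record) {
    Vtr = NumericVector(n_steps + 1);
    ntr = NumericVector(n_steps + 1);
    htr = NumericVector(n_steps + 1);
    Vtr[0] = V; ntr[0] = n; htr[0] = h;
  }
  std::vector<double> spikes;
  double last_spike = -1e18;

  double pulse_end = pulse_start + pulse_dur;

  for (int k = 0; k < n_steps; ++k) {
    double t = k * dt;
    // deliver events arriving at time t
    while (ev_ptr < ev_steps.size() && ev_steps[ev_ptr] == k) {
      a_r += 1.0; a_d += 1.0; ++ev_ptr;
    }
    double I_t = I_const;
    if (pulse_amp != 0.0 && t >= pulse_start && t < pulse_end) I_t += pulse_amp;
    if (has_syn) I_t += -syn_norm * (a_d - a_r) * (V - syn_E);

    double k1V, k1n, k1h;
    derivs(V, n, h, I_t, pp, k1V, k1n, k1h);
    double Vp = V + dt * k1V;
    double np = n + dt * k1n;
    double hp = h + dt * k1h;

    // advance synapse to t + dt
    a_r *= dec_r; a_d *= dec_d;
    double t2 = t + dt;
    double I_t2 = I_const;
    if (pulse_amp != 0.0 && t2 >= pulse_start && t2 < pulse_end) I_t2 += pulse_amp;
    if (has_syn) I_t2 += -syn_norm * (a_d - a_r) * (Vp - syn_E);

    double k2V, k2n, k2h;
    derivs(Vp, np, hp, I_t2, pp, k2V, k2n, k2h);
    double Vn = V + 0.5 * dt * (k1V + k2V);
    double nn = n + 0.5 * dt * (k1n + k2n);
    double hn = h + 0.5 * dt * (k1h + k2h);

    if (!std::isfinite(Vn) || std::fabs(Vn) > 200.0)
      stop("integration failure: |V| exceeded 200 mV at t = %f ms", t2);

    if (V < v_th && Vn >= v_th && (t2 - last_spike) > lockout) {
      double tc = t + dt * (v_th - V) / (Vn - V);
      spikes.push_back(tc);
      last_spike = tc;
    }

    V = Vn; n = nn; h = hn;
    if (record) { Vtr[k + 1] = V; ntr[k + 1] = n; htr[k + 1] = h; }
  }

  List out = List::create(
    _["spikes"] = NumericVector(spikes.begin(), spikes.end()),
    _["V_end"] = V, _["n_end"] = n, _["h_end"] = h);
  if (record) { out["V"] = Vtr; out["n"] = ntr; out["h"] = htr; }
  return out;
}

// ---------------------------------------------------------------------------
// Full network simulation.
//
// Populations: neurons 0 .. n_exc-1 are excitatory, the rest inhibitory.
// Connectivity is passed in CSR-like form: adj_off (length n+1, 0-based
// offsets into adj_tgt / adj_del), adj_tgt (0-based postsynaptic indices),
// adj_del (delays in integration steps, applied to recurrent events only).
//
// External drive: each neuron receives an independent Poisson event train
// whose common instantaneous rate lambda(t) (spikes/s) is sampled on the
// integration grid; per-step event counts are Poisson with mean
// lambda * dt.  External events are applied with zero delay.
//
// Synapses: double-exponential conductances via paired rise/decay
// accumulators (see above).  Recurrent AMPA and external AMPA share
// kinetics but have separate conductance scales; GABA has its own kinetics.
//
// Uses the R RNG (seed with set.seed() before calling).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_run_network(int n, int n_exc,
                     IntegerVector adj_off, IntegerVector adj_tgt,
                     IntegerVector adj_del,
                     NumericVector lambda,      // spikes/s, length >= n_steps
                     NumericVector Cm,          // per neuron, nF
                     NumericVector pshared,     // (phi, gK, gNa, gL, VK, VNa, VL)
                     double tr_a, double td_a, double E_a,   // AMPA kinetics
                     double g_rec, double g_ext,             // uS
                     double tr_g, double td_g, double E_g,   // GABA kinetics
                     double g_gaba,                          // uS
                     double dt, int n_steps,
                     NumericVector V0,
                     IntegerVector rec_ids,     // 0-based neuron ids to record
                     int rec_stride,            // steps per recorded bin
                     double v_th, double lockout) {
  RNGScope rngScope;

  // per-neuron parameter block (Cm varies, rest shared)
  std::vector<double> par(8);
  par[1] = pshared[0]; par[2] = pshared[1]; par[3] = pshared[2];
  par[4] = pshared[3]; par[5] = pshared[4]; par[6] = pshared[5];
  par[7] = pshared[6];

  std::vector<double> V(n), gn(n), gh(n);
  for (int i = 0; i < n; ++i) {
    V[i] = V0[i];
    gn[i] = f_alpha_n(V[i]) / (f_alpha_n(V[i]) + f_beta_n(V[i]));
    gh[i] = f_alpha_h(V[i]) / (f_alpha_h(V[i]) + f_beta_h(V[i]));
  }

  std::vector<double> ext_r(n, 0.0), ext_d(n, 0.0);
  std::vector<double> rec_r(n, 0.0), rec_d(n, 0.0);
  std::vector<double> gab_r(n, 0.0), gab_d(n, 0.0);

  double dec_ar = std::exp(-dt / tr_a), dec_ad = std::exp(-dt / td_a);
  double dec_gr = std::exp(-dt / tr_g), dec_gd = std::exp(-dt / td_g);
  double norm_a = 1.0 / (td_a - tr_a);
  double norm_g = 1.0 / (td_g - tr_g);

  int max_del = 0;
  for (int e = 0; e < adj_del.size(); ++e)
    if (adj_del[e] > max_del) max_del = adj_del[e];
  int D = max_del + 2;
  std::vector<double> ringE((size_t)D * n, 0.0), ringG((size_t)D * n, 0.0);

  std::vector<double> last_spike(n, -1e18);
  std::vector<int> spk_id;  std::vector<double> spk_t;
  spk_id.reserve(1 << 16);  spk_t.reserve(1 << 16);

  // population observables on the integration grid (excitatory targets)
  NumericVector lfp_ampa(n_steps + 1), lfp_gaba(n_steps + 1);
  NumericVector mean_ext(n_steps + 1), mean_net(n_steps + 1);

  // recorded single-neuron traces, averaged within rec_stride-step bins
  int n_rec = rec_ids.size();
  int n_bins = n_steps / rec_stride;
  NumericMatrix recV(n_rec, n_bins), recA(n_rec, n_bins),
                recG(n_rec, n_bins), recS(n_rec, n_bins);
  std::vector<int> rec_slot(n, -1);
  for (int r = 0; r < n_rec; ++r) rec_slot[rec_ids[r]] = r;
  double inv_stride = 1.0 / rec_stride;

  for (int k = 0; k < n_steps; ++k) {
    double t = k * dt;
    double t2 = t + dt;
    // deliver recurrent events scheduled for this step
    size_t slot = (size_t)(k % D) * n;
    for (int i = 0; i < n; ++i) {
      double we = ringE[slot + i];
      if (we != 0.0) { rec_r[i] += we; rec_d[i] += we; ringE[slot + i] = 0.0; }
      double wg = ringG[slot + i];
      if (wg != 0.0) { gab_r[i] += wg; gab_d[i] += wg; ringG[slot + i] = 0.0; }
    }

    double mu = lambda[k] * 1e-3 * dt;   // expected external events per step
    double s_ampa = 0.0, s_gaba = 0.0, s_ext = 0.0, s_net = 0.0;
    int bin = k / rec_stride;

    for (int i = 0; i < n; ++i) {
      // external arrivals at time t (zero contribution at the arrival instant)
      if (mu > 0.0) {
        double c = R::rpois(mu);
        if (c > 0.0) { ext_r[i] += c; ext_d[i] += c; }
      }
      par[0] = Cm[i];

      double gA = norm_a * (g_ext * (ext_d[i] - ext_r[i]) +
                            g_rec * (rec_d[i] - rec_r[i]));
      double gG = norm_g * g_gaba * (gab_d[i] - gab_r[i]);
      double Vi = V[i];
      double I1 = -gA * (Vi - E_a) - gG * (Vi - E_g);

      double k1V, k1n, k1h;
      derivs(Vi, gn[i], gh[i], I1, par.data(), k1V, k1n, k1h);
      double Vp = Vi + dt * k1V;
      double np = gn[i] + dt * k1n;
      double hp = gh[i] + dt * k1h;

      // advance conductances to t + dt
      ext_r[i] *= dec_ar; ext_d[i] *= dec_ad;
      rec_r[i] *= dec_ar; rec_d[i] *= dec_ad;
      gab_r[i] *= dec_gr; gab_d[i] *= dec_gd;

      double gA2 = norm_a * (g_ext * (ext_d[i] - ext_r[i]) +
                             g_rec * (rec_d[i] - rec_r[i]));
      double gG2 = norm_g * g_gaba * (gab_d[i] - gab_r[i]);
      double I2 = -gA2 * (Vp - E_a) - gG2 * (Vp - E_g);

      double k2V, k2n, k2h;
      derivs(Vp, np, hp, I2, par.data(), k2V, k2n, k2h);
      double Vn = Vi + 0.5 * dt * (k1V + k2V);
      gn[i] += 0.5 * dt * (k1n + k2n);
      gh[i] += 0.5 * dt * (k1h + k2h);

      if (!std::isfinite(Vn) || std::fabs(Vn) > 200.0)
        stop("integration failure: |V| exceeded 200 mV (neuron %d, t = %f ms)",
             i + 1, t2);

      if (Vi < v_th && Vn >= v_th && (t2 - last_spike[i]) > lockout) {
        double tc = t + dt * (v_th - Vi) / (Vn - Vi);
        spk_id.push_back(i + 1);
        spk_t.push_back(tc);
        last_spike[i] = tc;
        // enqueue delayed recurrent events
        bool is_exc = i < n_exc;
        for (int e = adj_off[i]; e < adj_off[i + 1]; ++e) {
          int arrive = k + 1 + adj_del[e];
          if (arrive >= n_steps) continue;
          size_t pos = (size_t)(arrive % D) * n + adj_tgt[e];
          if (is_exc) ringE[pos] += 1.0; else ringG[pos] += 1.0;
        }
      }
      V[i] = Vn;

      // currents at t + dt (post-update state) for observables
      double IA = -gA2 * (Vn - E_a);
      double IG = -gG2 * (Vn - E_g);
      double IE = -norm_a * g_ext * (ext_d[i] - ext_r[i]) * (Vn - E_a);
      if (i < n_exc) {
        s_ampa += std::fabs(IA);
        s_gaba += std::fabs(IG);
        s_ext  += IE;
        s_net  += IA + IG;
      }
      int r = rec_slot[i];
      if (r >= 0) {
        recV(r, bin) += Vn * inv_stride;
        recA(r, bin) += IA * inv_stride;
        recG(r, bin) += IG * inv_stride;
        recS(r, bin) += (IA + IG) * inv_stride;
      }
    }

    lfp_ampa[k + 1] = s_ampa / n_exc;
    lfp_gaba[k + 1] = s_gaba / n_exc;
    mean_ext[k + 1] = s_ext / n_exc;
    mean_net[k + 1] = s_net / n_exc;

    if (k % 20000 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(
    _["spike_id"] = IntegerVector(spk_id.begin(), spk_id.end()),
    _["spike_t"] = NumericVector(spk_t.begin(), spk_t.end()),
    _["lfp_ampa"] = lfp_ampa, _["lfp_gaba"] = lfp_gaba,
    _["mean_ext"] = mean_ext, _["mean_net"] = mean_net,
    _["rec_V"] = recV, _["rec_ampa"] = recA,
    _["rec_gaba"] = recG, _["rec_syn"] = recS);
}
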