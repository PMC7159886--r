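// Two-cell half-center circuit integrator.
//
// Seven gated currents per cell (Na, CaT, CaS, A, KCa, Kd, H) plus leak and a
// graded inhibitory synapse in each direction.  All currents are ohmic in V at
// frozen gating, so V, every gating variable, Ca and s are each advanced with
// exponential Euler; the scheme is unconditionally stable, which matters
// because g/c transiently reaches ~10^3 / ms during the Na upstroke.
//
// State layout (length 28):
//   per cell (13): V, m[Na,CaT,CaS,A,KCa,Kd,H], h[Na,CaT,CaS,A], Ca
//   then: s12 (activation of synapse onto cell 1), s21 (onto cell 2).
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const int NCH = 7;           // gated channels
static const int NHH = 4;           // inactivating channels (first four)
static const int CELL_LEN = 1 + NCH + NHH + 1;

// steady-state sigmoids: 1/(1+exp((V - vh)/k))
static inline double sig(double V, double vh, double k) {
  return 1.0 / (1.0 + std::exp((V + vh) / k));
}

struct Kin {
  double minf(int c, double V) const {
    switch (c) {
      case 0: return sig(V, 25.5, -5.29);   // Na
      case 1: return sig(V, 27.1, -7.2);    // CaT
      case 2: return sig(V, 33.0, -8.1);    // CaS
      case 3: return sig(V, 27.2, -8.7);    // A
      case 4: return sig(V, 28.3, -12.6);   // KCa (voltage factor only)
      case 5: return sig(V, 12.3, -11.8);   // Kd
      default: return sig(V, 70.0, 6.0);    // H
    }
  }
  double taum(int c, double V) const {
    switch (c) {
      case 0: return 1.32 - 1.26 / (1.0 + std::exp((V + 120.0) / -25.0));
      case 1: return 21.7 - 21.3 / (1.0 + std::exp((V + 68.1) / -20.5));
      case 2: return 1.4 + 7.0 / (std::exp((V + 27.0) / 10.0) +
                                  std::exp((V + 70.0) / -13.0));
      case 3: return 11.6 - 10.4 / (1.0 + std::exp((V + 32.9) / -15.2));
      case 4: return 90.3 - 75.1 / (1.0 + std::exp((V + 46.0) / -22.7));
      case 5: return 7.2 - 6.4 / (1.0 + std::exp((V + 28.3) / -19.2));
      default: return 272.0 + 1499.0 / (1.0 + std::exp((V + 42.2) / -8.73));
    }
  }
  double hinf(int c, double V) const {
    switch (c) {
      case 0: return sig(V, 48.9, 5.18);
      case 1: return sig(V, 32.1, 5.5);
      case 2: return sig(V, 60.0, 6.2);
      default: return sig(V, 56.9, 4.9);
    }
  }
  double tauh(int c, double V) const {
    switch (c) {
      case 0: return (0.67 / (1.0 + std::exp((V + 62.9) / -10.0))) *
                     (1.5 + 1.0 / (1.0 + std::exp((V + 34.9) / 3.6)));
      case 1: return 105.0 - 89.8 / (1.0 + std::exp((V + 55.0) / -16.9));
      case 2: return 60.0 + 150.0 / (std::exp((V + 55.0) / 9.0) +
                                     std::exp((V + 65.0) / -16.0));
      default: return 38.6 - 29.2 / (1.0 + std::exp((V + 38.9) / -26.5));
    }
  }
};

static const int P_EXP[NCH] = {3, 3, 3, 3, 4, 4, 1};

// Voltage-indexed lookup tables for x_inf(V) and 1 - exp(-dt/tau(V)).
struct Tables {
  double vlo, vhi, step, inv;
  int n;
  std::vector<double> minf[NCH], am[NCH], hinf[NHH], ah[NHH], sinf;
  void build(double dt, double V_half, double V_slope) {
    Kin K;
    vlo = -150.0; vhi = 80.0; step = 0.02;
    n = (int)std::floor((vhi - vlo) / step) + 2;
    inv = 1.0 / step;
    for (int c = 0; c < NCH; ++c) { minf[c].resize(n); am[c].resize(n); }
    for (int c = 0; c < NHH; ++c) { hinf[c].resize(n); ah[c].resize(n); }
    sinf.resize(n);
    for (int i = 0; i < n; ++i) {
      double V = vlo + i * step;
      for (int c = 0; c < NCH; ++c) {
        minf[c][i] = K.minf(c, V);
        am[c][i] = -std::expm1(-dt / K.taum(c, V));
      }
      for (int c = 0; c < NHH; ++c) {
        hinf[c][i] = K.hinf(c, V);
        ah[c][i] = -std::expm1(-dt / K.tauh(c, V));
      }
      sinf[i] = 1.0 / (1.0 + std::exp((V_half + V) / V_slope));
    }
  }
  inline double at(const std::vector<double>& t, double V) const {
    double x = (V - vlo) * inv;
    if (x <= 0.0) return t.front();
    int i = (int)x;
    if (i >= n - 1) return t.back();
    double f = x - i;
    return t[i] * (1.0 - f) + t[i + 1] * f;
  }
};

// [[Rcpp::export]]
List simulate_hcc_cpp(NumericVector gbar1, NumericVector gbar2,
                      double g_leak1, double g_leak2,
                      double g12, double g21,
                      NumericVector consts, double duration, double dt,
                      NumericVector init, int record_every,
                      bool use_tables, bool record_state) {
  const double E_leak = consts["E_leak"], E_Na = consts["E_Na"],
               E_K = consts["E_K"], E_H = consts["E_H"],
               E_syn = consts["E_syn"], V_half = consts["V_half"],
               V_slope = consts["V_slope"], tau_syn = consts["tau_syn"],
               Ca_out = consts["Ca_out"], tau_Ca = consts["tau_Ca"],
               Ca_base = consts["Ca_base"], f_Ca = consts["Ca_influx"],
               KCa_half = consts["KCa_halfsat"], RT2F = consts["nernst_RT2F"],
               c_m = consts["c_m"];
  Kin K;
  Tables T;
  if (use_tables) T.build(dt, V_half, V_slope);

  const long nsteps = (long)std::llround(duration / dt);
  const long nrec = nsteps / record_every + 1;
  NumericVector times(nrec), V1out(nrec), V2out(nrec);
  NumericMatrix states;
  if (record_state) states = NumericMatrix(nrec, 28);

  std::vector<double> st(init.begin(), init.end());
  const double gl[2] = {g_leak1, g_leak2};
  const double* gb[2] = {REAL(gbar1), REAL(gbar2)};
  const double a_syn = -std::expm1(-dt / tau_syn);
  const double a_ca = -std::expm1(-dt / tau_Ca);

  bool blown = false;
  // running invariant monitors
  double gate_min = 1.0, gate_max = 0.0, ca_min = R_PosInf;

  long irec = 0;
  auto record = [&](long step) {
    times[irec] = step * dt;
    V1out[irec] = st[0];
    V2out[irec] = st[CELL_LEN];
    if (record_state)
      for (int j = 0; j < 28; ++j) states(irec, j) = st[j];
    ++irec;
  };
  record(0);

  for (long step = 1; step <= nsteps; ++step) {
    double newst[28];
    double Vpre[2] = {st[0], st[CELL_LEN]};
    double s_onto[2] = {st[26], st[27]};       // s12 gates input to cell 1
    double g_syn_onto[2] = {g12, g21};
    for (int cell = 0; cell < 2; ++cell) {
      const int off = cell * CELL_LEN;
      const double V = st[off];
      const double Ca = st[off + 1 + NCH + NHH];
      const double E_Ca = RT2F * std::log(Ca_out / Ca);
      const double E_rev[NCH] = {E_Na, E_Ca, E_Ca, E_K, E_K, E_K, E_H};
      double g_tot = gl[cell] + g_syn_onto[cell] * s_onto[cell];
      double gE = gl[cell] * E_leak +
                  g_syn_onto[cell] * s_onto[cell] * E_syn;
      double I_Ca_tot = 0.0;
      const double caf = Ca / (Ca + KCa_half);
      for (int c = 0; c < NCH; ++c) {
        double m = st[off + 1 + c];
        double mp = m;
        for (int k = 1; k < P_EXP[c]; ++k) mp *= m;
        double geff = gb[cell][c] * mp;
        if (c < NHH) geff *= st[off + 1 + NCH + c];
        g_tot += geff;
        gE += geff * E_rev[c];
        if (c == 1 || c == 2) I_Ca_tot += geff * (V - E_Ca);
      }
      // gating updates (exponential Euler towards x_inf at current V)
      for (int c = 0; c < NCH; ++c) {
        double mi, a;
        if (use_tables) { mi = T.at(T.minf[c], V); a = T.at(T.am[c], V); }
        else { mi = K.minf(c, V); a = -std::expm1(-dt / K.taum(c, V)); }
        if (c == 4) mi *= caf;
        double m = st[off + 1 + c];
        newst[off + 1 + c] = m + (mi - m) * a;
      }
      for (int c = 0; c < NHH; ++c) {
        double hi, a;
        if (use_tables) { hi = T.at(T.hinf[c], V); a = T.at(T.ah[c], V); }
        else { hi = K.hinf(c, V); a = -std::expm1(-dt / K.tauh(c, V)); }
        double h = st[off + 1 + NCH + c];
        newst[off + 1 + NCH + c] = h + (hi - h) * a;
      }
      // calcium
      double Ca_inf = Ca_base - f_Ca * I_Ca_tot;
      double Ca_new = Ca + (Ca_inf - Ca) * a_ca;
      if (Ca_new < 1e-6) Ca_new = 1e-6;  // keep Nernst defined
      newst[off + 1 + NCH + NHH] = Ca_new;
      // membrane voltage
      double V_inf = gE / g_tot;
      newst[off] = V_inf + (V - V_inf) * std::exp(-dt * g_tot / c_m);
    }
    // synaptic activations driven by the *other* cell's voltage
    for (int cell = 0; cell < 2; ++cell) {
      double vp = Vpre[1 - cell];
      double si = use_tables ? T.at(T.sinf, vp)
                             : 1.0 / (1.0 + std::exp((V_half + vp) / V_slope));
      double s = st[26 + cell];
      newst[26 + cell] = s + (si - s) * a_syn;
    }
    for (int j = 0; j < 28; ++j) st[j] = newst[j];
    if (!std::isfinite(st[0]) || !std::isfinite(st[CELL_LEN]) ||
        std::fabs(st[0]) > 500.0 || std::fabs(st[CELL_LEN]) > 500.0) {
      blown = true;
      if (step % record_every == 0) record(step);
      break;
    }
    for (int cell = 0; cell < 2; ++cell) {
      const int off = cell * CELL_LEN;
      for (int c = 0; c < NCH + NHH; ++c) {
        double x = st[off + 1 + c];
        if (x < gate_min) gate_min = x;
        if (x > gate_max) gate_max = x;
      }
      double Ca = st[off + 1 + NCH + NHH];
      if (Ca < ca_min) ca_min = Ca;
    }
    if (step % record_every == 0) record(step);
  }

  if (irec < nrec) {  // truncated by blow-up
    times = times[Range(0, irec - 1)];
    V1out = V1out[Range(0, irec - 1)];
    V2out = V2out[Range(0, irec - 1)];
  }
  List out = List::create(
    _["times"] = times, _["V1"] = V1out, _["V2"] = V2out,
    _["blown"] = blown,
    _["final_state"] = NumericVector(st.begin(), st.end()),
    _["gate_min"] = gate_min, _["gate_max"] = gate_max,
    _["ca_min"] = ca_min);
  if (record_state) out["states"] = states;
  return out;
}

// One synchronous exponential-Euler step exposed for order checks from R.
// [[Rcpp::export]]
NumericVector hcc_step_cpp(NumericVector gbar1, NumericVector gbar2,
                           double g_leak1, double g_leak2,
                           double g12, double g21, NumericVector consts,
                           double dt, NumericVector init) {
  List r = simulate_hcc_cpp(gbar1, gbar2, g_leak1, g_leak2, g12, g21,
                            consts, dt, dt, init, 1, false, false);
  return r["final_state"];
}
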