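// Exponential-Euler integrator for a single-compartment, 8-conductance
// stomatogastric-type neuron with thin-shell calcium dynamics, plus the
// closed-loop calcium-target regulation model (mRNA -> conductance).
//
// Channel order everywhere: A, CaS, CaT, H, Kd, Leak, NaV, KCa.
// Units: V mV, t ms, conductance density uS/mm^2, current density nA/mm^2,
// [Ca] uM, area mm^2, shell volume mm^3, Cm nF/mm^2.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const int NCH = 8;
// gating exponents (Prinz-lineage STG kinetics)
static const int P_EXP[NCH] = {3, 3, 3, 1, 4, 0, 3, 4};
static const int Q_EXP[NCH] = {1, 1, 1, 0, 0, 0, 1, 0};
static const bool HAS_H[NCH] = {true, true, true, false, false, false, true, false};
static const bool IS_CA[NCH] = {false, true, true, false, false, false, false, false};
// fixed reversal potentials, mV (CaS/CaT replaced by Nernst each step)
static const double E_REV[NCH] = {-80.0, 0.0, 0.0, -20.0, -80.0, -50.0, 50.0, -80.0};

static const double FARADAY = 96485.0;      // C/mol
static const double RT_2F = 12.199;         // mV, RT/2F at ~283 K
static const double KCA_HALF = 3.0;         // uM, half-activation of KCa by calcium
static const double V_DIVERGE = 500.0;      // mV, sanity bound

inline double sig(double V, double Vh, double k) {
  // logistic 1 / (1 + exp((V + Vh) / k)); k < 0 rising with V
  return 1.0 / (1.0 + std::exp((V + Vh) / k));
}

struct Gates {
  double minf[NCH], hinf[NCH], taum[NCH], tauh[NCH];
};

static void gating_functions(double V, double Ca, Gates &g) {
  // A-type potassium
  g.minf[0] = sig(V, 27.2, -8.7);
  g.hinf[0] = sig(V, 56.9, 4.9);
  g.taum[0] = 23.2 - 20.8 * sig(V, 32.9, -15.2);
  g.tauh[0] = 77.2 - 58.4 * sig(V, 38.9, -26.5);
  // CaS (slow calcium)
  g.minf[1] = sig(V, 33.0, -8.1);
  g.hinf[1] = sig(V, 60.0, 6.2);
  g.taum[1] = 2.8 + 14.0 / (std::exp((V + 27.0) / 10.0) + std::exp((V + 70.0) / -13.0));
  g.tauh[1] = 120.0 + 300.0 / (std::exp((V + 55.0) / 9.0) + std::exp((V + 65.0) / -16.0));
  // CaT (transient calcium)
  g.minf[2] = sig(V, 27.1, -7.2);
  g.hinf[2] = sig(V, 32.1, 5.5);
  g.taum[2] = 43.4 - 42.6 * sig(V, 68.1, -20.5);
  g.tauh[2] = 210.0 - 179.6 * sig(V, 55.0, -16.9);
  // H (hyperpolarisation-activated inward)
  g.minf[3] = sig(V, 75.0, 5.5);
  g.hinf[3] = 1.0;
  g.taum[3] = 2.0 / (std::exp((V + 169.7) / -11.6) + std::exp((V - 26.7) / 14.3));
  g.tauh[3] = 1.0;
  // Kd (delayed rectifier)
  g.minf[4] = sig(V, 12.3, -11.8);
  g.hinf[4] = 1.0;
  g.taum[4] = 14.4 - 12.8 * sig(V, 28.3, -19.2);
  g.tauh[4] = 1.0;
  // Leak
  g.minf[5] = 1.0; g.hinf[5] = 1.0; g.taum[5] = 1.0; g.tauh[5] = 1.0;
  // NaV
  g.minf[6] = sig(V, 25.5, -5.29);
  g.hinf[6] = sig(V, 48.9, 5.18);
  g.taum[6] = 2.64 - 2.52 * sig(V, 120.0, -25.0);
  g.tauh[6] = (1.34 * sig(V, 62.9, -10.0)) * (1.5 + sig(V, 34.9, 3.6));
  // KCa (calcium-gated potassium); activation scaled by Ca/(Ca + K_half)
  g.minf[7] = (Ca / (Ca + KCA_HALF)) * sig(V, 28.3, -12.6);
  g.hinf[7] = 1.0;
  g.taum[7] = 180.6 - 150.2 * sig(V, 46.0, -22.7);
  g.tauh[7] = 1.0;
}

inline double ipow(double x, int n) {
  double r = 1.0;
  for (int i = 0; i < n; ++i) r *= x;
  return r;
}

// [[Rcpp::export(name = ".gating_cpp")]]
List gating_cpp(double V, double Ca) {
  Gates g;
  gating_functions(V, Ca, g);
  NumericVector minf(NCH), hinf(NCH), taum(NCH), tauh(NCH);
  for (int i = 0; i < NCH; ++i) {
    minf[i] = g.minf[i]; hinf[i] = g.hinf[i];
    taum[i] = g.taum[i]; tauh[i] = g.tauh[i];
  }
  return List::create(_["m_inf"] = minf, _["h_inf"] = hinf,
                      _["tau_m"] = taum, _["tau_h"] = tauh);
}

// Steady-state current densities at voltage(s) V with calcium frozen at Ca.
// Returns total and calcium-only current density (outward positive).
// [[Rcpp::export(name = ".ss_currents_cpp")]]
List ss_currents_cpp(NumericVector gbar, NumericVector V, double Ca,
                     double Ca_out) {
  int n = V.size();
  NumericVector itot(n), ica(n);
  double ECa = RT_2F * std::log(Ca_out / Ca);
  for (int t = 0; t < n; ++t) {
    Gates g;
    gating_functions(V[t], Ca, g);
    double s_tot = 0.0, s_ca = 0.0;
    for (int i = 0; i < NCH; ++i) {
      double E = IS_CA[i] ? ECa : E_REV[i];
      double open = ipow(g.minf[i], P_EXP[i]) * (Q_EXP[i] ? g.hinf[i] : 1.0);
      double cur = gbar[i] * open * (V[t] - E);
      s_tot += cur;
      if (IS_CA[i]) s_ca += cur;
    }
    itot[t] = s_tot;
    ica[t] = s_ca;
  }
  return List::create(_["i_total"] = itot, _["i_ca"] = ica);
}

struct CellState {
  double V, Ca;
  double m[NCH], h[NCH];
};

static void init_state(CellState &st, double V0, double Ca0) {
  st.V = V0; st.Ca = Ca0;
  Gates g;
  gating_functions(V0, Ca0, g);
  for (int i = 0; i < NCH; ++i) { st.m[i] = g.minf[i]; st.h[i] = g.hinf[i]; }
}

// one exponential-Euler step; returns calcium current density used
static bool step_cell(CellState &st, const double *gd, double dt,
                      double Cm, double flux_coef, double tauCa,
                      double Ca0, double Ca_out) {
  Gates g;
  gating_functions(st.V, st.Ca, g);
  for (int i = 0; i < NCH; ++i) {
    if (P_EXP[i] > 0) {
      st.m[i] = g.minf[i] + (st.m[i] - g.minf[i]) * std::exp(-dt / g.taum[i]);
      if (st.m[i] < 0.0) st.m[i] = 0.0; else if (st.m[i] > 1.0) st.m[i] = 1.0;
    } else st.m[i] = 1.0;
    if (HAS_H[i]) {
      st.h[i] = g.hinf[i] + (st.h[i] - g.hinf[i]) * std::exp(-dt / g.tauh[i]);
      if (st.h[i] < 0.0) st.h[i] = 0.0; else if (st.h[i] > 1.0) st.h[i] = 1.0;
    } else st.h[i] = 1.0;
  }
  double ECa = RT_2F * std::log(Ca_out / st.Ca);
  double gsum = 0.0, gEsum = 0.0, gca[2] = {0.0, 0.0};
  int k = 0;
  for (int i = 0; i < NCH; ++i) {
    double open = ipow(st.m[i], P_EXP[i]) * (Q_EXP[i] ? st.h[i] : 1.0);
    double gi = gd[i] * open;
    double E = IS_CA[i] ? ECa : E_REV[i];
    gsum += gi;
    gEsum += gi * E;
    if (IS_CA[i]) gca[k++] = gi;
  }
  if (gsum > 1e-12) {
    double Vinf = gEsum / gsum;
    st.V = Vinf + (st.V - Vinf) * std::exp(-dt * gsum / Cm);
  } // else V frozen (no conductance at all)
  if (!std::isfinite(st.V) || std::fabs(st.V) > V_DIVERGE) return false;
  double iCa = (gca[0] + gca[1]) * (st.V - ECa); // nA/mm^2, outward positive
  double flux = -flux_coef * iCa;                // uM/ms, influx positive
  double Ca_eq = Ca0 + tauCa * flux;
  st.Ca = Ca_eq + (st.Ca - Ca_eq) * std::exp(-dt / tauCa);
  if (st.Ca < 1e-9) st.Ca = 1e-9;
  return std::isfinite(st.Ca);
}

// Fixed-parameter simulation.
// init: numeric vector c(V, Ca, m[8], h[8]) or length-2 c(V, Ca) for
// steady-state gating, or length 0 for defaults.
// [[Rcpp::export(name = ".sim_neuron_cpp")]]
List sim_neuron_cpp(NumericVector gbar, double Cm, double A, double eta,
                    double phi, double tauCa, double Ca0, double Ca_out,
                    double dt, double t_total, double burnin,
                    NumericVector init, int record_stride) {
  if (gbar.size() != NCH) stop("gbar must have 8 entries");
  double flux_coef = phi * A / (2.0 * FARADAY * eta); // per (nA/mm^2) -> uM/ms
  CellState st;
  if (init.size() >= 2 + 2 * NCH) {
    st.V = init[0]; st.Ca = init[1];
    for (int i = 0; i < NCH; ++i) { st.m[i] = init[2 + i]; st.h[i] = init[2 + NCH + i]; }
  } else if (init.size() == 2) {
    init_state(st, init[0], init[1]);
  } else {
    init_state(st, -60.0, Ca0);
  }
  long nsteps = (long)std::llround(t_total / dt);
  long nburn = (long)std::llround(burnin / dt);
  double gd[NCH];
  for (int i = 0; i < NCH; ++i) gd[i] = gbar[i];

  bool rec = record_stride > 0;
  long nrec = rec ? (nsteps / record_stride + 1) : 0;
  NumericVector tV(rec ? nrec : 0), tCa(rec ? nrec : 0), tt(rec ? nrec : 0);
  long ri = 0;
  if (rec) { tt[0] = 0.0; tV[0] = st.V; tCa[0] = st.Ca; ri = 1; }

  double ca_sum = 0.0;
  long ca_n = 0;
  bool ok = true;
  long s = 0;
  for (; s < nsteps; ++s) {
    ok = step_cell(st, gd, dt, Cm, flux_coef, tauCa, Ca0, Ca_out);
    if (!ok) break;
    if (s >= nburn) { ca_sum += st.Ca; ++ca_n; }
    if (rec && ((s + 1) % record_stride == 0) && ri < nrec) {
      tt[ri] = (s + 1) * dt; tV[ri] = st.V; tCa[ri] = st.Ca; ++ri;
    }
  }
  NumericVector fin(2 + 2 * NCH);
  fin[0] = st.V; fin[1] = st.Ca;
  for (int i = 0; i < NCH; ++i) { fin[2 + i] = st.m[i]; fin[2 + NCH + i] = st.h[i]; }
  if (rec && ri < nrec) { // divergence: truncate records
    tt = head(tt, ri); tV = head(tV, ri); tCa = head(tCa, ri);
  }
  return List::create(
    _["t"] = tt, _["V"] = tV, _["Ca"] = tCa,
    _["mean_Ca"] = ca_n > 0 ? ca_sum / ca_n : NA_REAL,
    _["diverged"] = !ok, _["t_end"] = s * dt, _["final_state"] = fin);
}

// Closed-loop simulation: membrane + calcium + mRNA/conductance regulation
// + optional linear growth of A and eta (relative rate k per ms).
// Controller state mu_i and conductance density g_i are in density units
// (uS/mm^2), as are the regulation equations; growth enters through a
// dilution term -(Adot/A) g_i on the conductance density (new membrane
// dilutes existing channels; the calcium error then drives resynthesis).
// Early stop: every check_every ms compare densities with previous
// checkpoint; converged when max relative change < tol_drift (only if
// k_growth == 0 and t > min_time).
// [[Rcpp::export(name = ".sim_closed_loop_cpp")]]
List sim_closed_loop_cpp(NumericVector g0, NumericVector tau_mu, double tau_g,
                         double Ca_target, double k_growth,
                         double Cm, double A0, double eta0,
                         double phi, double tauCa, double Ca0, double Ca_out,
                         double dt, double t_total,
                         double log_every, double check_every,
                         double tol_drift, double min_time,
                         NumericVector init) {
  if (g0.size() != NCH || tau_mu.size() != NCH) stop("need 8 channels");
  CellState st;
  if (init.size() == 2) init_state(st, init[0], init[1]);
  else init_state(st, -60.0, Ca0);

  double A = A0, eta = eta0;
  double mu[NCH], gd[NCH];
  for (int i = 0; i < NCH; ++i) {
    mu[i] = g0[i];       // density units
    gd[i] = g0[i];
  }
  long nsteps = (long)std::llround(t_total / dt);
  long log_stride = std::max(1L, (long)std::llround(log_every / dt));
  long check_stride = std::max(1L, (long)std::llround(check_every / dt));
  long nlog = nsteps / log_stride + 1;
  NumericMatrix logm(nlog, 2 + NCH + 2); // t, g density x8, A, winCa
  CharacterVector dummy;
  long li = 0;
  double win_ca = 0.0;
  long win_n = 0;
  double prev_g[NCH];
  for (int i = 0; i < NCH; ++i) prev_g[i] = gd[i];
  bool ok = true, converged = false;
  double decay_g = std::exp(-dt / tau_g);

  logm(0, 0) = 0.0;
  for (int i = 0; i < NCH; ++i) logm(0, 1 + i) = gd[i];
  logm(0, 1 + NCH) = A;
  logm(0, 2 + NCH) = st.Ca;
  li = 1;

  long s = 0;
  for (; s < nsteps; ++s) {
    double flux_coef = phi * A / (2.0 * FARADAY * eta);
    ok = step_cell(st, gd, dt, Cm, flux_coef, tauCa, Ca0, Ca_out);
    if (!ok) break;
    double err = Ca_target - st.Ca;
    double dil = (k_growth != 0.0) ? (dt * k_growth * A0 / A) : 0.0;
    for (int i = 0; i < NCH; ++i) {
      mu[i] += dt * err / tau_mu[i];
      if (mu[i] < 0.0) mu[i] = 0.0;
      gd[i] = mu[i] + (gd[i] - mu[i]) * decay_g;
      if (dil != 0.0) gd[i] -= dil * gd[i];
      if (gd[i] < 0.0) gd[i] = 0.0;
    }
    if (k_growth != 0.0) {
      A += dt * k_growth * A0;
      eta += dt * k_growth * eta0;
    }
    win_ca += st.Ca; ++win_n;
    if ((s + 1) % log_stride == 0 && li < nlog) {
      logm(li, 0) = (s + 1) * dt;
      for (int i = 0; i < NCH; ++i) logm(li, 1 + i) = gd[i];
      logm(li, 1 + NCH) = A;
      logm(li, 2 + NCH) = win_ca / win_n;
      win_ca = 0.0; win_n = 0;
      ++li;
    }
    if ((s + 1) % check_stride == 0) {
      double drift = 0.0;
      for (int i = 0; i < NCH; ++i) {
        double ref = std::max(prev_g[i], 1e-6);
        double d = std::fabs(gd[i] - prev_g[i]) / ref;
        if (d > drift) drift = d;
        prev_g[i] = gd[i];
      }
      if (k_growth == 0.0 && (s + 1) * dt >= min_time && drift < tol_drift) {
        converged = true;
        ++s;
        break;
      }
    }
  }
  NumericVector gfin(NCH);
  for (int i = 0; i < NCH; ++i) gfin[i] = gd[i];
  return List::create(
    _["log"] = logm(Range(0, std::max(0L, li - 1)), _),
    _["g_final"] = gfin, _["A_final"] = A, _["eta_final"] = eta,
    _["Ca_final"] = st.Ca,
    _["t_end"] = s * dt, _["diverged"] = !ok, _["converged"] = converged);
}
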