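#include <Rcpp.h>
#include <vector>
#include <cmath>

// Courtemanche-Ramirez-Nattel human atrial ionic model (21 state variables)
// and an explicit lumped-mass finite-element monodomain time loop.
//
// State layout per node (column of a 21 x n matrix):
//   0 Vm(mV) 1 m 2 h 3 j 4 oa 5 oi 6 ua 7 ui 8 xr 9 xs 10 d 11 f 12 fCa
//   13 u 14 v 15 w 16 Nai 17 Ki 18 Cai 19 Caup 20 Carel  (concentrations mM)
//
// Sign conventions: stimulus amplitude is given depolarizing-positive in
// pA/pF; inside the monodomain balance it enters as Istim = -amplitude so
// that Im = Cm dVm/dt + Iion + Istim equals the diffusion current per unit
// membrane area.

namespace cm {

const double R = 8.3143, T = 310.0, F = 96.4867;
const double Cm_cell = 100.0;             // pF, whole-cell capacitance
const double V_cell = 20100.0;            // um^3
const double V_i = 0.68 * V_cell;
const double V_up = 0.0552 * V_cell;
const double V_rel = 0.0048 * V_cell;
const double Na_o = 140.0, Ca_o = 1.8, K_o = 5.4;
const double g_Na = 7.8, g_K1 = 0.09, g_to = 0.1652;
const double g_Kr = 0.029411765, g_Ks = 0.12941176, g_Ca_L = 0.12375;
const double g_B_Na = 0.0006744375, g_B_Ca = 0.001131;
const double i_NaK_max = 0.59933874, Km_Na_i = 10.0, Km_K_o = 1.5;
const double I_NaCa_max = 1600.0, K_mNa = 87.5, K_mCa = 1.38;
const double K_sat = 0.1, gamma_ = 0.35;
const double i_CaP_max = 0.275;
const double K_rel = 30.0, tau_tr = 180.0;
const double I_up_max = 0.005, K_up = 0.00092, Ca_up_max = 15.0;
const double CMDN_max = 0.05, TRPN_max = 0.07, CSQN_max = 10.0;
const double Km_CMDN = 0.00238, Km_TRPN = 0.5, Km_CSQN = 0.8;
const double K_Q10 = 3.0;

const int NGATE = 15;
const int NSTATE = 21;

// published resting state
const double INIT[NSTATE] = {
  -81.18, 2.908e-3, 0.9649, 0.9775, 3.043e-2, 0.9992, 4.966e-3, 0.9986,
  3.296e-5, 1.869e-2, 1.367e-4, 0.9996, 0.7755, 0.0, 1.0, 0.9992,
  11.17, 139.0, 1.013e-4, 1.488, 1.488
};

struct Rates {
  double Iion;                 // pA/pF, sum of all membrane currents
  double xinf[NGATE], tau[NGATE];
  double dconc[5];             // dNai, dKi, dCai, dCaup, dCarel (mM/ms)
};

inline double safe_div(double num, double den, double lim) {
  return std::fabs(den) < 1e-10 ? lim : num / den;
}

// all voltage- and state-dependent quantities for one cell
void compute(const double* s, Rates& r) {
  const double V = s[0];
  const double m = s[1], h = s[2], j = s[3], oa = s[4], oi = s[5];
  const double ua = s[6], ui = s[7], xr = s[8], xs = s[9];
  const double d = s[10], f = s[11], fca = s[12];
  const double u = s[13], v = s[14], w = s[15];
  const double Nai = s[16], Ki = s[17], Cai = s[18];
  const double Caup = s[19], Carel = s[20];
  const double RTF = R * T / F;

  const double E_Na = RTF * std::log(Na_o / Nai);
  const double E_K  = RTF * std::log(K_o / Ki);
  const double E_Ca = 0.5 * RTF * std::log(Ca_o / Cai);

  const double i_Na = g_Na * m * m * m * h * j * (V - E_Na);
  const double i_K1 = g_K1 * (V - E_K) / (1.0 + std::exp(0.07 * (V + 80.0)));
  const double i_to = g_to * oa * oa * oa * oi * (V - E_K);
  const double g_Kur = 0.005 + 0.05 / (1.0 + std::exp(-(V - 15.0) / 13.0));
  const double i_Kur = g_Kur * ua * ua * ua * ui * (V - E_K);
  const double i_Kr = g_Kr * xr * (V - E_K) / (1.0 + std::exp((V + 15.0) / 22.4));
  const double i_Ks = g_Ks * xs * xs * (V - E_K);
  const double i_Ca_L = g_Ca_L * d * f * fca * (V - 65.0);

  const double sigma = (std::exp(Na_o / 67.3) - 1.0) / 7.0;
  const double f_NaK = 1.0 / (1.0 + 0.1245 * std::exp(-0.1 * V / RTF)
                              + 0.0365 * sigma * std::exp(-V / RTF));
  const double i_NaK = i_NaK_max * f_NaK * (K_o / (K_o + Km_K_o))
      / (1.0 + std::pow(Km_Na_i / Nai, 1.5));
  const double eg  = std::exp(gamma_ * V / RTF);
  const double eg1 = std::exp((gamma_ - 1.0) * V / RTF);
  const double i_NaCa = I_NaCa_max
      * (eg * Nai * Nai * Nai * Ca_o - eg1 * Na_o * Na_o * Na_o * Cai)
      / ((K_mNa * K_mNa * K_mNa + Na_o * Na_o * Na_o) * (K_mCa + Ca_o)
         * (1.0 + K_sat * eg1));
  const double i_B_Na = g_B_Na * (V - E_Na);
  const double i_B_Ca = g_B_Ca * (V - E_Ca);
  const double i_p_Ca = i_CaP_max * Cai / (0.0005 + Cai);

  r.Iion = i_Na + i_K1 + i_to + i_Kur + i_Kr + i_Ks + i_B_Na + i_B_Ca
         + i_NaK + i_p_Ca + i_NaCa + i_Ca_L;

  // --- gates -----------------------------------------------------------
  double a, b;
  // m
  a = safe_div(0.32 * (V + 47.13), 1.0 - std::exp(-0.1 * (V + 47.13)), 3.2);
  b = 0.08 * std::exp(-V / 11.0);
  r.tau[0] = 1.0 / (a + b); r.xinf[0] = a * r.tau[0];
  // h, j
  if (V >= -40.0) {
    a = 0.0;
    b = 1.0 / (0.13 * (1.0 + std::exp(-(V + 10.66) / 11.1)));
    r.tau[1] = 1.0 / (a + b); r.xinf[1] = a * r.tau[1];
    a = 0.0;
    b = 0.3 * std::exp(-2.535e-7 * V) / (1.0 + std::exp(-0.1 * (V + 32.0)));
    r.tau[2] = 1.0 / (a + b); r.xinf[2] = a * r.tau[2];
  } else {
    a = 0.135 * std::exp(-(V + 80.0) / 6.8);
    b = 3.56 * std::exp(0.079 * V) + 3.1e5 * std::exp(0.35 * V);
    r.tau[1] = 1.0 / (a + b); r.xinf[1] = a * r.tau[1];
    a = (-1.2714e5 * std::exp(0.2444 * V) - 3.474e-5 * std::exp(-0.04391 * V))
        * (V + 37.78) / (1.0 + std::exp(0.311 * (V + 79.23)));
    b = 0.1212 * std::exp(-0.01052 * V) / (1.0 + std::exp(-0.1378 * (V + 40.14)));
    r.tau[2] = 1.0 / (a + b); r.xinf[2] = a * r.tau[2];
  }
  // oa, ua share rate shapes
  const double a_oa = 0.65 / (std::exp(-(V + 10.0) / 8.5) + std::exp(-(V - 30.0) / 59.0));
  const double b_oa = 0.65 / (2.5 + std::exp((V + 82.0) / 17.0));
  r.tau[3] = 1.0 / ((a_oa + b_oa) * K_Q10);
  r.xinf[3] = 1.0 / (1.0 + std::exp(-(V + 20.47) / 17.54));
  a = 1.0 / (18.53 + std::exp((V + 113.7) / 10.95));
  b = 1.0 / (35.56 + std::exp(-(V + 1.26) / 7.44));
  r.tau[4] = 1.0 / ((a + b) * K_Q10);
  r.xinf[4] = 1.0 / (1.0 + std::exp((V + 43.1) / 5.3));
  r.tau[5] = r.tau[3];
  r.xinf[5] = 1.0 / (1.0 + std::exp(-(V + 30.3) / 9.6));
  a = 1.0 / (21.0 + std::exp(-(V - 185.0) / 28.0));
  b = std::exp((V - 158.0) / 16.0);
  r.tau[6] = 1.0 / ((a + b) * K_Q10);
  r.xinf[6] = 1.0 / (1.0 + std::exp((V - 99.45) / 27.48));
  // xr, xs
  a = safe_div(0.0003 * (V + 14.1), 1.0 - std::exp(-(V + 14.1) / 5.0), 0.0015);
  b = safe_div(7.3898e-5 * (V - 3.3328),
               std::exp((V - 3.3328) / 5.1237) - 1.0, 3.7864e-4);
  r.tau[7] = 1.0 / (a + b);
  r.xinf[7] = 1.0 / (1.0 + std::exp(-(V + 14.1) / 6.5));
  a = safe_div(4e-5 * (V - 19.9), 1.0 - std::exp(-(V - 19.9) / 17.0), 6.8e-4);
  b = safe_div(3.5e-5 * (V - 19.9),
               std::exp((V - 19.9) / 9.0) - 1.0, 3.15e-4);
  r.tau[8] = 0.5 / (a + b);
  r.xinf[8] = 1.0 / std::sqrt(1.0 + std::exp(-(V - 19.9) / 12.7));
  // d, f, fCa
  {
    const double ed = std::exp(-(V + 10.0) / 6.24);
    r.tau[9] = safe_div((1.0 - ed), 0.035 * (V + 10.0) * (1.0 + ed),
                        1.0 / (0.035 * 6.24 * 2.0));
    r.xinf[9] = 1.0 / (1.0 + std::exp(-(V + 10.0) / 8.0));
  }
  r.tau[10] = 9.0 / (0.0197 * std::exp(-0.0337 * 0.0337 * (V + 10.0) * (V + 10.0)) + 0.02);
  r.xinf[10] = 1.0 / (1.0 + std::exp((V + 28.0) / 6.9));
  r.tau[11] = 2.0;
  r.xinf[11] = 1.0 / (1.0 + Cai / 0.00035);
  // Ca release gates u, v, w driven by Fn
  const double i_rel = K_rel * u * u * v * w * (Carel - Cai);
  const double Fn = 1e3 * (1e-15 * V_rel * i_rel
      - 1e-15 / (2.0 * F) * (0.5 * i_Ca_L * Cm_cell - 0.2 * i_NaCa * Cm_cell));
  const double uv_gate = 1.0 / (1.0 + std::exp(-(Fn - 3.4175e-13) / 13.67e-16));
  r.tau[12] = 8.0;
  r.xinf[12] = uv_gate;
  r.tau[13] = 1.91 + 2.09 * uv_gate;
  r.xinf[13] = 1.0 - 1.0 / (1.0 + std::exp(-(Fn - 6.835e-14) / 13.67e-16));
  {
    const double ew = std::exp(-(V - 7.9) / 5.0);
    r.tau[14] = safe_div(6.0 * (1.0 - ew), (1.0 + 0.3 * ew) * (V - 7.9),
                         6.0 / (5.0 * 1.3));
    r.xinf[14] = 1.0 - 1.0 / (1.0 + std::exp(-(V - 40.0) / 17.0));
  }

  // --- concentrations --------------------------------------------------
  const double i_up = I_up_max / (1.0 + K_up / Cai);
  const double i_up_leak = I_up_max * Caup / Ca_up_max;
  const double i_tr = (Caup - Carel) / tau_tr;
  r.dconc[0] = (-3.0 * i_NaK - (3.0 * i_NaCa + i_B_Na + i_Na)) * Cm_cell / (F * V_i);
  r.dconc[1] = (2.0 * i_NaK - (i_K1 + i_to + i_Kur + i_Kr + i_Ks)) * Cm_cell / (F * V_i);
  const double B1 = (2.0 * i_NaCa - (i_p_Ca + i_Ca_L + i_B_Ca)) * Cm_cell
      / (2.0 * F * V_i) + (V_up * (i_up_leak - i_up) + i_rel * V_rel) / V_i;
  const double B2 = 1.0 + TRPN_max * Km_TRPN / ((Cai + Km_TRPN) * (Cai + Km_TRPN))
      + CMDN_max * Km_CMDN / ((Cai + Km_CMDN) * (Cai + Km_CMDN));
  r.dconc[2] = B1 / B2;
  r.dconc[3] = i_up - (i_up_leak + i_tr * V_rel / V_up);
  r.dconc[4] = (i_tr - i_rel)
      / (1.0 + CSQN_max * Km_CSQN / ((Carel + Km_CSQN) * (Carel + Km_CSQN)));
}

// Rush-Larsen gate update + forward-Euler Vm/concentration update in place.
// istim depolarizing-positive pA/pF; diff is the diffusion term dVm/dt
// contribution (mV/ms).  Returns Iion (pA/pF).
inline double step_cell(double* s, double dt, double istim, double diff) {
  Rates r;
  compute(s, r);
  s[0] += dt * (-r.Iion + istim + diff);
  for (int g = 0; g < NGATE; ++g) {
    const double e = std::exp(-dt / r.tau[g]);
    s[1 + g] = r.xinf[g] + (s[1 + g] - r.xinf[g]) * e;
  }
  for (int c = 0; c < 5; ++c) s[16 + c] += dt * r.dconc[c];
  return r.Iion;
}

} // namespace cm

// [[Rcpp::export(name = ".cm_initial_state")]]
Rcpp::NumericVector cm_initial_state() {
  Rcpp::NumericVector out(cm::NSTATE);
  for (int i = 0; i < cm::NSTATE; ++i) out[i] = cm::INIT[i];
  return out;
}

// Full right-hand side: derivatives of all 21 states plus total Iion.
// istim depolarizing-positive pA/pF.
// [[Rcpp::export(name = ".cm_rhs")]]
Rcpp::List cm_rhs(Rcpp::NumericVector state, double istim) {
  if (state.size() != cm::NSTATE) Rcpp::stop("state must have 21 entries");
  cm::Rates r;
  std::vector<double> s(state.begin(), state.end());
  cm::compute(s.data(), r);
  Rcpp::NumericVector d(cm::NSTATE);
  d[0] = -r.Iion + istim;
  for (int g = 0; g < cm::NGATE; ++g)
    d[1 + g] = (r.xinf[g] - s[1 + g]) / r.tau[g];
  for (int c = 0; c < 5; ++c) d[16 + c] = r.dconc[c];
  return Rcpp::List::create(Rcpp::Named("dstate") = d,
                            Rcpp::Named("Iion") = r.Iion);
}

// One Rush-Larsen/Euler step for a single cell.
// [[Rcpp::export(name = ".cm_step")]]
Rcpp::NumericVector cm_step(Rcpp::NumericVector state, double dt, double istim) {
  if (state.size() != cm::NSTATE) Rcpp::stop("state must have 21 entries");
  Rcpp::NumericVector out = Rcpp::clone(state);
  cm::step_cell(REAL(out), dt, istim, 0.0);
  return out;
}

// Explicit monodomain time loop on the tagged mesh.
//
// state:      21 x n matrix (modified copy returned)
// kp,ki,kx:   CSR of the stiffness matrix K (mS), 0-based indices; rows of
//             inactive nodes must be empty
// inv_chicm_m: per-node 1/(chi * Cm * Mvol_i)  [1/uF]; 0 for inactive nodes
// active:     0-based indices of active nodes
// stim_nodes/amp/start/dur: one entry per stimulus protocol; nodes is a list
// dt (ms), n_steps, out_every: n_steps must be divisible by out_every
// cm_surf:    Cm per unit area (uF/cm^2), used to convert Im to uA/cm^2
// ionic:      FALSE runs pure diffusion (conservation checks)
// [[Rcpp::export(name = ".monodomain_run")]]
Rcpp::List monodomain_run(Rcpp::NumericMatrix state,
                          Rcpp::IntegerVector kp, Rcpp::IntegerVector ki,
                          Rcpp::NumericVector kx,
                          Rcpp::NumericVector inv_chicm_m,
                          Rcpp::IntegerVector active,
                          Rcpp::List stim_nodes,
                          Rcpp::NumericVector stim_amp,
                          Rcpp::NumericVector stim_start,
                          Rcpp::NumericVector stim_dur,
                          double dt, int n_steps, int out_every,
                          double cm_surf, bool ionic) {
  const int n = state.ncol();
  if (state.nrow() != cm::NSTATE) Rcpp::stop("state must be 21 x n");
  if (n_steps % out_every != 0) Rcpp::stop("n_steps must be divisible by out_every");
  const int n_out = n_steps / out_every + 1;
  const int n_act = active.size();
  const int n_prot = stim_nodes.size();

  Rcpp::NumericMatrix S = Rcpp::clone(state);
  double* sp = REAL(S);

  Rcpp::NumericMatrix vm_out(n, n_out), im_out(n, n_out);
  std::fill(vm_out.begin(), vm_out.end(), NA_REAL);
  std::fill(im_out.begin(), im_out.end(), NA_REAL);
  Rcpp::NumericVector times(n_out);

  std::vector<double> kv(n, 0.0), istim(n, 0.0);
  std::vector<std::vector<int> > prot(n_prot);
  for (int p = 0; p < n_prot; ++p) {
    Rcpp::IntegerVector nd = stim_nodes[p];
    prot[p].assign(nd.begin(), nd.end());
  }

  double max_abs_v = 0.0;
  for (int step = 0; step <= n_steps; ++step) {
    const double t = step * dt;
    // diffusion term at current state
    for (int a = 0; a < n_act; ++a) {
      const int i = active[a];
      double acc = 0.0;
      for (int q = kp[i]; q < kp[i + 1]; ++q) acc += kx[q] * sp[ki[q] * cm::NSTATE];
      kv[i] = acc;
    }
    if (step % out_every == 0) {
      const int k = step / out_every;
      times[k] = t;
      for (int a = 0; a < n_act; ++a) {
        const int i = active[a];
        vm_out(i, k) = sp[i * cm::NSTATE];
        // Im = -(K V)_i / (chi * Mvol_i) = -kv * Cm * inv_chicm_m  [uA/cm^2]
        im_out(i, k) = -kv[i] * cm_surf * inv_chicm_m[i];
      }
      if (step == n_steps) break;
    }
    if (step == n_steps) break;
    // stimulus currents active in [start, start + dur)
    std::fill(istim.begin(), istim.end(), 0.0);
    for (int p = 0; p < n_prot; ++p) {
      if (t >= stim_start[p] && t < stim_start[p] + stim_dur[p]) {
        const std::vector<int>& nd = prot[p];
        for (size_t q = 0; q < nd.size(); ++q) istim[nd[q]] += stim_amp[p];
      }
    }
    for (int a = 0; a < n_act; ++a) {
      const int i = active[a];
      const double diff = -kv[i] * inv_chicm_m[i];
      double* cell = sp + i * cm::NSTATE;
      if (ionic) {
        cm::step_cell(cell, dt, istim[i], diff);
      } else {
        cell[0] += dt * (istim[i] + diff);
      }
      const double v = cell[0];
      if (!R_FINITE(v)) {
        Rcpp::stop("monodomain solution became non-finite at t = %.3f ms (step %d), max |Vm| so far %.1f mV",
                   t, step, max_abs_v);
      }
      if (std::fabs(v) > max_abs_v) max_abs_v = std::fabs(v);
    }
  }

  return Rcpp::List::create(Rcpp::Named("vm") = vm_out,
                            Rcpp::Named("im") = im_out,
                            Rcpp::Named("times") = times,
                            Rcpp::Named("state") = S);
}
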