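// Core numerical kernels: Courtemanche-Ramirez-Nattel (CRN) human atrial
// ionic model with temperature-scaled gating kinetics, plus forward-Euler
// single-cell and monodomain tissue steppers.
//
// Voltage-dependent rate functions are tabulated on a fine voltage grid and
// linearly interpolated (gate lookup table, "LUT"); correctness against
// direct evaluation is enforced by tests on the R side.  Thermodynamic
// voltage factors (Na/K pump, Na/Ca exchanger Boltzmann terms) depend on
// absolute temperature and are tabulated per distinct temperature group.
#include <Rcpp.h>
#include <cmath>
#include <cstring>
using namespace Rcpp;

// ---- fixed CRN constants (units: mV, ms, mM, pA/pF, pF, um^3) ----
static const double F_CONST = 96.4867;  // C/mmol
static const double R_GAS   = 8.3143;   // J/(mol K)
static const double CM      = 100.0;    // pF
static const double V_I     = 13668.0;  // um^3 intracellular
static const double V_UP    = 1109.52;
static const double V_REL   = 96.48;
static const double NA_O    = 140.0;    // mM
static const double K_O     = 5.4;
static const double CA_O    = 1.8;
static const double KM_NAI  = 10.0;
static const double KM_KO   = 1.5;
static const double KM_NA   = 87.5;
static const double KM_CA   = 1.38;
static const double K_SAT   = 0.1;
static const double GAMMA_X = 0.35;
static const double K_UP    = 0.00092;
static const double CA_UP_MAX = 15.0;
static const double TAU_TR  = 180.0;
static const double CMDN_MAX = 0.05,  KM_CMDN = 0.00238;
static const double TRPN_MAX = 0.07,  KM_TRPN = 0.0005;
static const double CSQN_MAX = 10.0,  KM_CSQN = 0.8;
static const double KQ10 = 3.0;       // CRN's own 37C K+ gate tau divisor

// state vector layout (21 entries per node)
// 0:V 1:m 2:h 3:j 4:oa 5:oi 6:ua 7:ui 8:xr 9:xs 10:d 11:f 12:fca
// 13:u 14:v 15:w 16:Nai 17:Ki 18:Cai 19:Caup 20:Carel
static const int NSTATE = 21;

// kernel conductance/parameter block, filled from an R named vector
struct KParams {
  double gNa, gK1, gto, gKr, gKs, gCaL, gbNa, gbCa;
  double INaKmax, IpCamax, INaCamax, krel, Iupmax;
};

static KParams unpackParams(const NumericVector& p) {
  KParams k;
  k.gNa = p["g_Na"];   k.gK1 = p["g_K1"];   k.gto = p["g_to"];
  k.gKr = p["g_Kr"];   k.gKs = p["g_Ks"];   k.gCaL = p["g_CaL"];
  k.gbNa = p["g_bNa"]; k.gbCa = p["g_bCa"];
  k.INaKmax = p["i_NaK_max"]; k.IpCamax = p["i_pCa_max"];
  k.INaCamax = p["i_NaCa_max"]; k.krel = p["k_rel"]; k.Iupmax = p["i_up_max"];
  return k;
}

// ---------------------------------------------------------------------------
// Rate functions at 37 C (voltage in mV, rates in 1/ms).  Singular points are
// handled by their analytic limits.
// ---------------------------------------------------------------------------
static inline double safe_div(double num, double den, double lim) {
  return std::fabs(den) < 1e-10 ? lim : num / den;
}

static void gateInfTau(double V, int g, double& inf, double& tau) {
  switch (g) {
  case 0: { // m
    double am = safe_div(0.32 * (V + 47.13),
                         1.0 - std::exp(-0.1 * (V + 47.13)), 3.2);
    double bm = 0.08 * std::exp(-V / 11.0);
    inf = am / (am + bm); tau = 1.0 / (am + bm); break;
  }
  case 1: { // h
    double ah, bh;
    if (V >= -40.0) {
      ah = 0.0;
      bh = 1.0 / (0.13 * (1.0 + std::exp(-(V + 10.66) / 11.1)));
    } else {
      ah = 0.135 * std::exp(-(V + 80.0) / 6.8);
      bh = 3.56 * std::exp(0.079 * V) + 3.1e5 * std::exp(0.35 * V);
    }
    inf = ah / (ah + bh); tau = 1.0 / (ah + bh); break;
  }
  case 2: { // j
    double aj, bj;
    if (V >= -40.0) {
      aj = 0.0;
      bj = 0.3 * std::exp(-2.535e-7 * V) / (1.0 + std::exp(-0.1 * (V + 32.0)));
    } else {
      aj = (-127140.0 * std::exp(0.2444 * V) - 3.474e-5 * std::exp(-0.04391 * V))
           * (V + 37.78) / (1.0 + std::exp(0.311 * (V + 79.23)));
      bj = 0.1212 * std::exp(-0.01052 * V) /
           (1.0 + std::exp(-0.1378 * (V + 40.14)));
    }
    inf = aj / (aj + bj); tau = 1.0 / (aj + bj); break;
  }
  case 3: { // oa
    double a = 0.65 / (std::exp(-(V + 10.0) / 8.5) + std::exp(-(V - 30.0) / 59.0));
    double b = 0.65 / (2.5 + std::exp((V + 82.0) / 17.0));
    inf = 1.0 / (1.0 + std::exp(-(V + 20.47) / 17.54));
    tau = 1.0 / ((a + b) * KQ10); break;
  }
  case 4: { // oi
    double a = 1.0 / (18.53 + std::exp((V + 113.7) / 10.95));
    double b = 1.0 / (35.56 + std::exp(-(V + 1.26) / 7.44));
    inf = 1.0 / (1.0 + std::exp((V + 43.1) / 5.3));
    tau = 1.0 / ((a + b) * KQ10); break;
  }
  case 5: { // ua
    double a = 0.65 / (std::exp(-(V + 10.0) / 8.5) + std::exp(-(V - 30.0) / 59.0));
    double b = 0.65 / (2.5 + std::exp((V + 82.0) / 17.0));
    inf = 1.0 / (1.0 + std::exp(-(V + 30.3) / 9.6));
    tau = 1.0 / ((a + b) * KQ10); break;
  }
  case 6: { // ui
    double a = 1.0 / (21.0 + std::exp(-(V - 185.0) / 28.0));
    double b = std::exp((V - 158.0) / 16.0);
    inf = 1.0 / (1.0 + std::exp((V - 99.45) / 27.48));
    tau = 1.0 / ((a + b) * KQ10); break;
  }
  case 7: { // xr
    double a = safe_div(0.0003 * (V + 14.1),
                        1.0 - std::exp(-(V + 14.1) / 5.0), 0.0015);
    double b = safe_div(7.3898e-5 * (V - 3.3328),
                        std::exp((V - 3.3328) / 5.1237) - 1.0, 3.7862e-4);
    inf = 1.0 / (1.0 + std::exp(-(V + 14.1) / 6.5));
    tau = 1.0 / (a + b); break;
  }
  case 8: { // xs
    double a = safe_div(4e-5 * (V - 19.9),
                        1.0 - std::exp(-(V - 19.9) / 17.0), 6.8e-4);
    double b = safe_div(3.5e-5 * (V - 19.9),
                        std::exp((V - 19.9) / 9.0) - 1.0, 3.15e-4);
    inf = 1.0 / std::sqrt(1.0 + std::exp(-(V - 19.9) / 12.7));
    tau = 0.5 / (a + b); break;
  }
  case 9: { // d
    double e = std::exp(-(V + 10.0) / 6.24);
    tau = std::fabs(V + 10.0) < 1e-10
            ? 4.579 / (1.0 + e)
            : (1.0 - e) / (0.035 * (V + 10.0) * (1.0 + e));
    inf = 1.0 / (1.0 + std::exp(-(V + 10.0) / 8.0)); break;
  }
  case 10: { // f
    double x = 0.0337 * (V + 10.0);
    tau = 9.0 / (0.0197 * std::exp(-x * x) + 0.02);
    inf = 1.0 / (1.0 + std::exp((V + 28.0) / 6.9)); break;
  }
  case 11: { // w
    double e = std::exp(-(V - 7.9) / 5.0);
    tau = std::fabs(V - 7.9) < 1e-10
            ? 6.0 * 0.2 / 1.3
            : 6.0 * (1.0 - e) / ((1.0 + 0.3 * e) * (V - 7.9));
    inf = 1.0 - 1.0 / (1.0 + std::exp(-(V - 40.0) / 17.0)); break;
  }
  }
}

// temperature-scaler group per V-dependent gate: 0 INa, 1 Ito, 2 IKur,
// 3 IKr, 4 IKs, 5 ICaL, -1 unscaled (SR release gate w)
static const int GATE_GROUP[12] = {0,0,0, 1,1, 2,2, 3, 4, 5,5, -1};
// state-vector slot of each V-dependent gate (w sits behind fca/u/v)
static const int GATE_SLOT[12] = {1,2,3, 4,5, 6,7, 8, 9, 10,11, 15};
static const int NVGATE = 12;

// ---------------------------------------------------------------------------
// LUT construction.  Gate LUT columns: inf,tau per V-gate (24), then
// IK1 rectification (24), gKur(V) (25), IKr rectification (26).
// Steady-state voltage shifts (cAF remodeling) displace the inf columns only;
// the ICaL activation tau is scaled in place.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
NumericMatrix build_gate_lut_cpp(NumericVector shifts, double tau_d_scale,
                                 double vmin, double vmax, double dv) {
  int nV = (int)std::floor((vmax - vmin) / dv + 0.5) + 1;
  NumericMatrix L(nV, 27);
  // shifts: named h, oa, d steady-state displacements (mV)
  double sh[12] = {0};
  sh[1] = shifts["h"]; sh[3] = shifts["oa"]; sh[9] = shifts["d"];
  for (int i = 0; i < nV; ++i) {
    double V = vmin + i * dv;
    for (int g = 0; g < NVGATE; ++g) {
      double inf, tau;
      gateInfTau(V, g, inf, tau);
      L(i, 2 * g + 1) = (g == 9) ? tau * tau_d_scale : tau;
      if (sh[g] != 0.0) gateInfTau(V - sh[g], g, inf, tau);
      L(i, 2 * g) = inf;
    }
    L(i, 24) = 1.0 / (1.0 + std::exp(0.07 * (V + 80.0)));
    L(i, 25) = 0.005 + 0.05 / (1.0 + std::exp(-(V - 15.0) / 13.0));
    L(i, 26) = 1.0 / (1.0 + std::exp((V + 15.0) / 22.4));
  }
  L.attr("vmin") = vmin; L.attr("dv") = dv;
  return L;
}

// Thermo LUT for one absolute temperature: fNaK factor and the two
// Na/Ca-exchanger Boltzmann terms, as functions of V.
// [[Rcpp::export]]
NumericMatrix build_thermo_lut_cpp(double T_celsius, double vmin, double vmax,
                                   double dv) {
  int nV = (int)std::floor((vmax - vmin) / dv + 0.5) + 1;
  // RT/F in mV: R [J/(mol K)] * T [K] / F [C/mmol -> *1000 C/mol], *1000 mV/V
  double rtf = R_GAS * (273.15 + T_celsius) / F_CONST;
  double sigma = (std::exp(NA_O / 67.3) - 1.0) / 7.0;
  NumericMatrix Th(nV, 3);
  for (int i = 0; i < nV; ++i) {
    double V = vmin + i * dv;
    Th(i, 0) = 1.0 / (1.0 + 0.1245 * std::exp(-0.1 * V / rtf) +
                      0.0365 * sigma * std::exp(-V / rtf));
    Th(i, 1) = std::exp(GAMMA_X * V / rtf);
    Th(i, 2) = std::exp((GAMMA_X - 1.0) * V / rtf);
  }
  Th.attr("rtf") = rtf;
  Th.attr("T") = T_celsius;
  return Th;
}

// Per-gate Rush-Larsen exponential factors exp(-dt/tau_scaled(V)) for one
// temperature group (7-element scaler vector), tabulated over the LUT grid.
// [[Rcpp::export]]
NumericMatrix build_exp_lut_cpp(NumericMatrix gateLut, NumericVector scalers,
                                double dt) {
  int nV = gateLut.nrow();
  NumericMatrix E(nV, NVGATE);
  for (int g = 0; g < NVGATE; ++g) {
    int grp = GATE_GROUP[g];
    double sc = grp >= 0 ? scalers[grp] : 1.0;
    for (int i = 0; i < nV; ++i) {
      double tau = gateLut(i, 2 * g + 1) / sc;
      E(i, g) = std::exp(-dt / tau);
    }
  }
  return E;
}

// ---------------------------------------------------------------------------
// Node kernel: advances gates and concentrations of one node in place and
// returns the total ionic current Iion (pA/pF).  Membrane voltage itself is
// advanced by the caller (which adds diffusion and stimulus).
// ---------------------------------------------------------------------------
// transpose an nV x nc LUT into row-major (one voltage row contiguous)
static std::vector<double> transposeLut(const NumericMatrix& L) {
  int nV = L.nrow(), nc = L.ncol();
  std::vector<double> out((size_t)nV * nc);
  for (int i = 0; i < nV; ++i)
    for (int c = 0; c < nc; ++c) out[(size_t)i * nc + c] = L(i, c);
  return out;
}

// Row-major LUT access: all tabulated quantities for one voltage index sit
// in one contiguous row, so a node's update touches two rows only.
static inline double advanceNode(double* s,
                                 const double* Gt, int sG,
                                 const double* Tht, int sT, int oT,
                                 const double* Et, int sE, int oE,
                                 int nV, double vmin, double invdv,
                                 const double* scal, const KParams& p,
                                 double rtf, double dt, const double* Ern,
                                 long* clamps) {
  double V = s[0];
  double x = (V - vmin) * invdv;
  if (x < 0.0) x = 0.0;
  if (x > (double)(nV - 2)) x = (double)(nV - 2);
  int i0 = (int)x;
  double w = x - i0;
  const double* g0 = Gt + (size_t)i0 * sG;
  const double* g1 = g0 + sG;
  const double* t0 = Tht + (size_t)i0 * sT + oT;
  const double* t1 = t0 + sT;
  const double* e0 = Et ? Et + (size_t)i0 * sE + oE : 0;
  const double* e1 = e0 ? e0 + sE : 0;

  // gate updates: Rush-Larsen exponential step (exact for frozen V), the
  // standard explicit update for gates whose time constants approach dt.
  // Et, when given, tabulates exp(-dt/tau_scaled) per gate for this node's
  // temperature group; otherwise the exponential is evaluated directly.
  for (int g = 0; g < NVGATE; ++g) {
    double inf = g0[2 * g] + w * (g1[2 * g] - g0[2 * g]);
    double fac;
    if (e0) {
      fac = e0[g] + w * (e1[g] - e0[g]);
    } else {
      double tau = g0[2 * g + 1] + w * (g1[2 * g + 1] - g0[2 * g + 1]);
      int grp = GATE_GROUP[g];
      if (grp >= 0) tau /= scal[grp];
      fac = std::exp(-dt / tau);
    }
    int sl = GATE_SLOT[g];
    double xn = inf + (s[sl] - inf) * fac;
    if (xn < 0.0) { xn = 0.0; ++*clamps; }
    else if (xn > 1.0) { xn = 1.0; ++*clamps; }
    s[sl] = xn;
  }

  double m = s[1], h = s[2], j = s[3], oa = s[4], oi = s[5], ua = s[6],
         ui = s[7], xr = s[8], xs = s[9], d = s[10], f = s[11], fca = s[12],
         u = s[13], v = s[14], ww = s[15];
  double Nai = s[16], Ki = s[17], Cai = s[18], Caup = s[19], Carel = s[20];

  double ENa, EK, ECa;
  if (Ern) { ENa = Ern[0]; EK = Ern[1]; ECa = Ern[2]; }
  else {
    ENa = rtf * std::log(NA_O / Nai);
    EK  = rtf * std::log(K_O / Ki);
    ECa = 0.5 * rtf * std::log(CA_O / Cai);
  }

  double INa  = p.gNa * m * m * m * h * j * (V - ENa);
  double IK1  = p.gK1 * (V - EK) * (g0[24] + w * (g1[24] - g0[24]));
  double Ito  = p.gto * oa * oa * oa * oi * (V - EK);
  double IKur = (g0[25] + w * (g1[25] - g0[25])) * ua * ua * ua * ui * (V - EK);
  double IKr  = p.gKr * xr * (V - EK) * (g0[26] + w * (g1[26] - g0[26]));
  double IKs  = p.gKs * xs * xs * (V - EK);
  double ICaL = p.gCaL * d * f * fca * (V - 65.0);
  double fnak = t0[0] + w * (t1[0] - t0[0]);
  double nr = KM_NAI / Nai;  // (KmNai/Nai)^1.5 without pow()
  double INaK = p.INaKmax * fnak * (K_O / (K_O + KM_KO)) /
                (1.0 + nr * std::sqrt(nr));
  double eg  = t0[1] + w * (t1[1] - t0[1]);
  double eg1 = t0[2] + w * (t1[2] - t0[2]);
  double INaCa = p.INaCamax *
      (eg * Nai * Nai * Nai * CA_O - eg1 * NA_O * NA_O * NA_O * Cai) /
      ((KM_NA * KM_NA * KM_NA + NA_O * NA_O * NA_O) * (KM_CA + CA_O) *
       (1.0 + K_SAT * eg1));
  double IbNa = p.gbNa * (V - ENa);
  double IbCa = p.gbCa * (V - ECa);
  double IpCa = p.IpCamax * Cai / (0.0005 + Cai);

  double Iion = INa + IK1 + Ito + IKur + IKr + IKs + IbNa + IbCa + INaK +
                IpCa + INaCa + ICaL;

  // SR calcium handling
  double Irel = p.krel * u * u * v * ww * (Carel - Cai);
  double Itr  = (Caup - Carel) / TAU_TR;
  double Iup  = p.Iupmax / (1.0 + K_UP / Cai);
  double Iupleak = p.Iupmax * Caup / CA_UP_MAX;
  double Fn = 1e-12 * V_REL * Irel -
              (1e-12 / (2.0 * F_CONST)) * (0.5 * ICaL * CM - 0.2 * INaCa * CM);

  // two shared sigmoids of Fn; saturated tails skip the exp (most nodes are
  // diastolic, where both arguments are far negative)
  double za = (Fn - 3.4175e-13) * (1.0 / 1.367e-15);
  double zb = (Fn - 6.835e-14) * (1.0 / 1.367e-15);
  double sa = za > 35.0 ? 1.0 : (za < -35.0 ? 0.0
               : 1.0 / (1.0 + std::exp(-za)));
  double sb = zb > 35.0 ? 1.0 : (zb < -35.0 ? 0.0
               : 1.0 / (1.0 + std::exp(-zb)));
  double uinf = sa;
  double vinf = 1.0 - sb;
  double tauv = 1.91 + 2.09 * sa;
  double fcainf = 1.0 / (1.0 + Cai / 0.00035);
  double taufca = 2.0 / scal[6];  // fCa carries its own scaler slot

  s[13] = u + dt * (uinf - u) / 8.0;
  s[14] = v + dt * (vinf - v) / tauv;
  s[12] = fca + dt * (fcainf - fca) / taufca;
  for (int k = 12; k <= 14; ++k) {
    if (s[k] < 0.0) { s[k] = 0.0; ++*clamps; }
    else if (s[k] > 1.0) { s[k] = 1.0; ++*clamps; }
  }

  double cf = CM / (F_CONST * V_I);
  s[16] = Nai + dt * cf * (-3.0 * INaK - 3.0 * INaCa - IbNa - INa);
  s[17] = Ki  + dt * cf * (2.0 * INaK - IK1 - Ito - IKur - IKr - IKs);
  double B1 = 0.5 * cf * (2.0 * INaCa - IpCa - ICaL - IbCa) +
              (V_UP * (Iupleak - Iup) + Irel * V_REL) / V_I;
  double B2 = 1.0 + TRPN_MAX * KM_TRPN / ((Cai + KM_TRPN) * (Cai + KM_TRPN)) +
              CMDN_MAX * KM_CMDN / ((Cai + KM_CMDN) * (Cai + KM_CMDN));
  s[18] = Cai + dt * B1 / B2;
  s[19] = Caup + dt * (Iup - Iupleak - Itr * V_REL / V_UP);
  s[20] = Carel + dt * (Itr - Irel) /
          (1.0 + CSQN_MAX * KM_CSQN / ((Carel + KM_CSQN) * (Carel + KM_CSQN)));

  return Iion;
}

// ---------------------------------------------------------------------------
// Single-cell forward-Euler run.
// Records (optionally every k-th step): t, V, Cai, and the 12 currents.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cell_run_cpp(NumericVector state0, NumericMatrix gateLut,
                  NumericMatrix thermoLut, NumericVector scalers,
                  NumericVector params, double dt, double t0, int nsteps,
                  NumericVector stim_starts, double stim_dur, double stim_amp,
                  int record_every) {
  KParams p = unpackParams(params);
  int nV = gateLut.nrow();
  double vmin = as<double>(gateLut.attr("vmin"));
  double dv = as<double>(gateLut.attr("dv"));
  double invdv = 1.0 / dv;
  double rtf = as<double>(thermoLut.attr("rtf"));
  double s[NSTATE];
  for (int k = 0; k < NSTATE; ++k) s[k] = state0[k];
  std::vector<double> Gt = transposeLut(gateLut);
  std::vector<double> Tht = transposeLut(thermoLut);
  const double* scal = REAL(scalers);
  long clamps = 0;

  int nrec = record_every > 0 ? nsteps / record_every + 1 : 0;
  NumericMatrix trace(nrec > 0 ? nrec : 1, 3);
  int irec = 0;
  int nstim = stim_starts.size();

  for (int it = 0; it < nsteps; ++it) {
    double t = t0 + it * dt;
    if (record_every > 0 && it % record_every == 0 && irec < nrec) {
      trace(irec, 0) = t; trace(irec, 1) = s[0]; trace(irec, 2) = s[18];
      ++irec;
    }
    double Istim = 0.0;
    for (int q = 0; q < nstim; ++q)
      if (t >= stim_starts[q] && t < stim_starts[q] + stim_dur)
        Istim = stim_amp;
    double Iion = advanceNode(s, Gt.data(), 27, Tht.data(), 3, 0, 0, 0, 0,
                              nV, vmin, invdv, scal, p, rtf, dt, 0, &clamps);
    s[0] += dt * (-(Iion + Istim));
    if (!std::isfinite(s[0]) || std::fabs(s[0]) > 200.0) {
      NumericVector out(NSTATE);
      for (int k = 0; k < NSTATE; ++k) out[k] = s[k];
      return List::create(_["status"] = "unstable", _["t"] = t,
                          _["state"] = out, _["clamps"] = clamps,
                          _["trace"] = trace);
    }
  }
  NumericVector out(NSTATE);
  for (int k = 0; k < NSTATE; ++k) out[k] = s[k];
  if (record_every > 0 && irec < nrec) {
    trace(irec, 0) = t0 + nsteps * dt; trace(irec, 1) = s[0];
    trace(irec, 2) = s[18]; ++irec;
  }
  return List::create(_["status"] = "ok", _["state"] = out,
                      _["clamps"] = clamps, _["trace"] = trace,
                      _["nrec"] = irec);
}

// Single-cell run that records all 12 currents at every recorded sample.
// [[Rcpp::export]]
List cell_run_currents_cpp(NumericVector state0, NumericMatrix gateLut,
                           NumericMatrix thermoLut, NumericVector scalers,
                           NumericVector params, double dt, int nsteps,
                           NumericVector stim_starts, double stim_dur,
                           double stim_amp, int record_every) {
  KParams p = unpackParams(params);
  int nV = gateLut.nrow();
  double vmin = as<double>(gateLut.attr("vmin"));
  double invdv = 1.0 / as<double>(gateLut.attr("dv"));
  double rtf = as<double>(thermoLut.attr("rtf"));
  double s[NSTATE];
  for (int k = 0; k < NSTATE; ++k) s[k] = state0[k];
  std::vector<double> Gt = transposeLut(gateLut);
  std::vector<double> Tht = transposeLut(thermoLut);
  const double* scal = REAL(scalers);
  long clamps = 0;
  int nrec = nsteps / record_every + 1;
  NumericMatrix trace(nrec, 15); // t V Cai + 12 currents
  int irec = 0, nstim = stim_starts.size();

  for (int it = 0; it < nsteps; ++it) {
    double t = it * dt;
    bool rec = (it % record_every == 0 && irec < nrec);
    double Istim = 0.0;
    for (int q = 0; q < nstim; ++q)
      if (t >= stim_starts[q] && t < stim_starts[q] + stim_dur)
        Istim = stim_amp;
    // currents before the step, from the same LUT path
    if (rec) {
      double V = s[0];
      double x = (V - vmin) * invdv;
      if (x < 0) x = 0;
      if (x > nV - 2) x = nV - 2;
      int i0 = (int)x; double w = x - i0;
      const double* g0 = Gt.data() + (size_t)i0 * 27;
      const double* g1 = g0 + 27;
      const double* t0p = Tht.data() + (size_t)i0 * 3;
      const double* t1p = t0p + 3;
      double Nai = s[16], Ki = s[17], Cai = s[18];
      double ENa = rtf * std::log(NA_O / Nai), EK = rtf * std::log(K_O / Ki),
             ECa = 0.5 * rtf * std::log(CA_O / Cai);
      double cur[12];
      cur[0] = p.gNa * s[1]*s[1]*s[1]*s[2]*s[3]*(V - ENa);
      cur[1] = p.gK1 * (V - EK) * (g0[24] + w*(g1[24]-g0[24]));
      cur[2] = p.gto * s[4]*s[4]*s[4]*s[5]*(V - EK);
      cur[3] = (g0[25] + w*(g1[25]-g0[25])) * s[6]*s[6]*s[6]*s[7]*(V - EK);
      cur[4] = p.gKr * s[8]*(V - EK)*(g0[26] + w*(g1[26]-g0[26]));
      cur[5] = p.gKs * s[9]*s[9]*(V - EK);
      cur[6] = p.gbNa * (V - ENa);
      cur[7] = p.gbCa * (V - ECa);
      cur[8] = p.INaKmax * (t0p[0] + w*(t1p[0]-t0p[0])) * (K_O/(K_O+KM_KO)) /
               (1.0 + std::pow(KM_NAI/Nai, 1.5));
      cur[9] = p.IpCamax * Cai / (0.0005 + Cai);
      double eg = t0p[1] + w*(t1p[1]-t0p[1]),
             eg1 = t0p[2] + w*(t1p[2]-t0p[2]);
      cur[10] = p.INaCamax *
        (eg*Nai*Nai*Nai*CA_O - eg1*NA_O*NA_O*NA_O*Cai) /
        ((KM_NA*KM_NA*KM_NA + NA_O*NA_O*NA_O)*(KM_CA+CA_O)*(1.0+K_SAT*eg1));
      cur[11] = p.gCaL * s[10]*s[11]*s[12]*(V - 65.0);
      trace(irec, 0) = t; trace(irec, 1) = V; trace(irec, 2) = s[18];
      for (int c = 0; c < 12; ++c) trace(irec, 3 + c) = cur[c];
      ++irec;
    }
    double Iion = advanceNode(s, Gt.data(), 27, Tht.data(), 3, 0, 0, 0, 0,
                              nV, vmin, invdv, scal, p, rtf, dt, 0, &clamps);
    s[0] += dt * (-(Iion + Istim));
    if (!std::isfinite(s[0]) || std::fabs(s[0]) > 200.0)
      stop("cell run unstable at t=%.2f ms (|V|>200 mV); reduce dt", t);
  }
  NumericVector out(NSTATE);
  for (int k = 0; k < NSTATE; ++k) out[k] = s[k];
  return List::create(_["state"] = out, _["trace"] = trace, _["nrec"] = irec,
                      _["clamps"] = clamps);
}

// ---------------------------------------------------------------------------
// Monodomain tissue runner.
//
// S: NSTATE x N state matrix (column per node; row 0 is V).
// neighbors: 2*ndim x N matrix of 0-based neighbor indices (mirror/no-flux
//            boundaries encoded by pointing back at the node's inner
//            neighbor, prepared on the R side).
// groupIdx: 0-based thermo-group index per node; thermoLuts: nV x (3*nGroups).
// scalers: 7 x N per-node Q10 kinetics multipliers (six currents + fCa).
// stims: list of list(nodes=0-based ints, start=ms, dur=ms, amp=pA/pF).
// Records a V snapshot every snap_every steps (0 = none).
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List tissue_run_cpp(NumericMatrix S, IntegerMatrix neighbors,
                    NumericMatrix gateLut, NumericMatrix thermoLuts,
                    NumericMatrix expLuts, NumericVector rtfByGroup,
                    IntegerVector groupIdx, NumericMatrix scalers,
                    NumericVector params, double D, double dx, double dt,
                    double t0, int nsteps, List stims, int snap_every,
                    int nernst_every) {
  KParams p = unpackParams(params);
  const int N = S.ncol();
  const int nV = gateLut.nrow();
  const double vmin = as<double>(gateLut.attr("vmin"));
  const double invdv = 1.0 / as<double>(gateLut.attr("dv"));
  const int nnb = neighbors.nrow();
  const double ddx2 = D / (dx * dx);
  double* Sp = REAL(S);
  std::vector<double> Gt = transposeLut(gateLut);
  std::vector<double> ThT = transposeLut(thermoLuts);
  std::vector<double> ET = transposeLut(expLuts);
  const int sT = thermoLuts.ncol();
  const int sE = expLuts.ncol();
  const int* nb = INTEGER(neighbors);
  const int* grp = INTEGER(groupIdx);
  const double* scalAll = REAL(scalers);
  long clamps = 0;
  // cached Nernst potentials (concentrations drift slowly; refreshed every
  // nernst_every steps, every step when nernst_every == 1)
  std::vector<double> Ern(3 * (size_t)N);

  // unpack stimuli
  int nstim = stims.size();
  std::vector<std::vector<int> > stimNodes(nstim);
  std::vector<double> stimStart(nstim), stimEnd(nstim), stimAmp(nstim);
  for (int q = 0; q < nstim; ++q) {
    List st = stims[q];
    IntegerVector nd = st["nodes"];
    stimNodes[q] = std::vector<int>(nd.begin(), nd.end());
    stimStart[q] = as<double>(st["start"]);
    stimEnd[q] = stimStart[q] + as<double>(st["dur"]);
    stimAmp[q] = as<double>(st["amp"]);
  }

  std::vector<double> Vbuf(N), Istim(N, 0.0), dV(N);
  int nsnap = snap_every > 0 ? nsteps / snap_every + 1 : 0;
  NumericMatrix snaps(nsnap > 0 ? nsnap : 1, nsnap > 0 ? N : 1);
  NumericVector snapT(nsnap > 0 ? nsnap : 1);
  int isnap = 0;

  for (int it = 0; it < nsteps; ++it) {
    double t = t0 + it * dt;
    if (snap_every > 0 && it % snap_every == 0 && isnap < nsnap) {
      for (int i = 0; i < N; ++i) snaps(isnap, i) = Sp[(size_t)i * NSTATE];
      snapT[isnap] = t;
      ++isnap;
    }
    for (int i = 0; i < N; ++i) Vbuf[i] = Sp[(size_t)i * NSTATE];
    // stimulus field
    bool anyStim = false;
    for (int q = 0; q < nstim; ++q)
      if (t >= stimStart[q] && t < stimEnd[q]) anyStim = true;
    if (anyStim) {
      std::fill(Istim.begin(), Istim.end(), 0.0);
      for (int q = 0; q < nstim; ++q)
        if (t >= stimStart[q] && t < stimEnd[q])
          for (size_t k = 0; k < stimNodes[q].size(); ++k)
            Istim[stimNodes[q][k]] += stimAmp[q];
    }
    // diffusion (centered stencil, mirror boundaries via neighbor table)
    for (int i = 0; i < N; ++i) {
      double lap = 0.0;
      const int* nbi = nb + (size_t)i * nnb;
      for (int k = 0; k < nnb; ++k) lap += Vbuf[nbi[k]];
      lap -= nnb * Vbuf[i];
      dV[i] = ddx2 * lap;
    }
    // Nernst refresh
    if (it % nernst_every == 0) {
      for (int i = 0; i < N; ++i) {
        const double* s = Sp + (size_t)i * NSTATE;
        double rtf = rtfByGroup[grp[i]];
        Ern[3 * (size_t)i]     = rtf * std::log(NA_O / s[16]);
        Ern[3 * (size_t)i + 1] = rtf * std::log(K_O / s[17]);
        Ern[3 * (size_t)i + 2] = 0.5 * rtf * std::log(CA_O / s[18]);
      }
    }
    // reaction
    for (int i = 0; i < N; ++i) {
      double* s = Sp + (size_t)i * NSTATE;
      double Iion = advanceNode(s, Gt.data(), 27, ThT.data(), sT, 3 * grp[i],
                                ET.data(), sE, NVGATE * grp[i],
                                nV, vmin, invdv, scalAll + (size_t)i * 7, p,
                                rtfByGroup[grp[i]], dt,
                                Ern.data() + 3 * (size_t)i, &clamps);
      double Ist = anyStim ? Istim[i] : 0.0;
      s[0] += dt * (dV[i] - Iion - Ist);
      if (!std::isfinite(s[0]) || std::fabs(s[0]) > 200.0)
        return List::create(_["status"] = "unstable", _["t"] = t,
                            _["node"] = i + 1, _["clamps"] = clamps,
                            _["snapshots"] = snaps, _["snap_t"] = snapT,
                            _["nsnap"] = isnap);
    }
    if (it % 5000 == 0) Rcpp::checkUserInterrupt();
  }
  if (snap_every > 0 && isnap < nsnap) {
    for (int i = 0; i < N; ++i) snaps(isnap, i) = Sp[(size_t)i * NSTATE];
    snapT[isnap] = t0 + nsteps * dt;
    ++isnap;
  }
  return List::create(_["status"] = "ok", _["clamps"] = clamps,
                      _["snapshots"] = snaps, _["snap_t"] = snapT,
                      _["nsnap"] = isnap);
}

// Explicit heat-equation step batch on a regular grid (SI units).
// T: field vector (length N), neighbors as above but per-axis spacing may
// differ, so the caller passes per-axis weights kappa*dt/dh^2 and the
// neighbor table is grouped by axis (2 entries per axis).
// dirichletIdx/dirichletVal: nodes re-imposed after every step.
// [[Rcpp::export]]
NumericVector heat_run_cpp(NumericVector Tfield, IntegerMatrix neighbors,
                           NumericVector axisWeight, IntegerVector dirichletIdx,
                           NumericVector dirichletVal, int nsteps) {
  int N = Tfield.size();
  int nnb = neighbors.nrow(); // 2 * ndim
  NumericVector Tcur = clone(Tfield);
  std::vector<double> buf(N);
  const int* nb = INTEGER(neighbors);
  int nd = dirichletIdx.size();
  for (int it = 0; it < nsteps; ++it) {
    for (int i = 0; i < N; ++i) buf[i] = Tcur[i];
    for (int i = 0; i < N; ++i) {
      const int* nbi = nb + (size_t)i * nnb;
      double acc = 0.0;
      for (int a = 0; a < nnb / 2; ++a) {
        acc += axisWeight[a] *
               (buf[nbi[2 * a]] + buf[nbi[2 * a + 1]] - 2.0 * buf[i]);
      }
      Tcur[i] = buf[i] + acc;
    }
    for (int k = 0; k < nd; ++k) Tcur[dirichletIdx[k]] = dirichletVal[k];
  }
  return Tcur;
}
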