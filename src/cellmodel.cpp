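// Spatially discretized atrial myocyte: 18 transversal domains, membrane
// currents on the two outer domains, deterministic mean-field calcium
// release units per domain, linear inter-domain calcium diffusion.
//
// Units: mV, ms, mM, pA/pF. Concentration states are free concentrations;
// rapid (instantaneous-equilibrium) buffering enters as a multiplicative
// attenuation of each compartment's net free-calcium rate.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// --- packed parameter vector layout; must match .param_order in R/params.R ---
enum ParIdx {
  P_NDOM = 0,
  P_GCAL, P_GCAT, P_GNA, P_GTO, P_GKR, P_GKS, P_GK1, P_GCAB, P_GNAB, P_GCLB,
  P_VNCX, P_VNAK, P_VCAP,
  P_VUP, P_KMF, P_KMR, P_HUP,
  P_KREL, P_GLEAK,
  P_KOPEN, P_KCLOSE, P_KI0, P_KIHALF, P_KR, P_KCI, P_KCIHALF,
  P_KSRS, P_HACT, P_KSRLOAD, P_HSR,
  P_TAUXFER, P_TAUSL, P_TAUJ,
  P_GDIFF,
  P_BFC, P_KDFC, P_BSC, P_KDSC,
  P_BCSQ, P_KDCSQ, P_BSRS, P_KDSRS, P_BJ, P_KDJ,
  P_VCYTO, P_VSR, P_VSRS, P_VSL, P_VJ,
  P_CM, P_CAO, P_NAO, P_KO, P_FNAVOL,
  P_ECL, P_KDFCA, P_GSRS, P_TAUSSL,
  N_PAR
};

static const double FDAY = 96485.0;  // C/mol
static const double RTF  = 26.712;   // mV at 310 K

// state layout helpers
#define IDX_V 0
#define IDX_GATE0 1      // m h j d f b g oa oi xr xs  (11 gates)
#define N_GATES 11
#define IDX_NA 12
#define IDX_K  13
#define IDX_DOM0 14      // per domain: Ca_cyto, Ca_SR, Ca_SRS, O, R
#define DOM_STRIDE 5

static inline int idx_dom(int i, int k) { return IDX_DOM0 + DOM_STRIDE * i + k; }
static inline int idx_sl(int n, int which) { return IDX_DOM0 + DOM_STRIDE * n + which; }     // 0,1
static inline int idx_j(int n, int which) { return IDX_DOM0 + DOM_STRIDE * n + 2 + which; }  // 0,1

static inline double sq(double x) { return x * x; }

// instantaneous-buffering attenuation for a compartment; which: 0 cyto/SL
// (fixed high-affinity buffer + scalable low-affinity buffer), 1 SR
// (calsequestrin), 2 SRS, 3 junctional
static double beta_buf(double ca, const double* p, int which) {
  double pow_sum = 0.0;
  switch (which) {
  case 0:
    pow_sum = p[P_BFC] * p[P_KDFC] / sq(p[P_KDFC] + ca)
            + p[P_BSC] * p[P_KDSC] / sq(p[P_KDSC] + ca);
    break;
  case 1:
    pow_sum = p[P_BCSQ] * p[P_KDCSQ] / sq(p[P_KDCSQ] + ca);
    break;
  case 2:
    pow_sum = p[P_BSRS] * p[P_KDSRS] / sq(p[P_KDSRS] + ca);
    break;
  default:
    pow_sum = p[P_BJ] * p[P_KDJ] / sq(p[P_KDJ] + ca);
  }
  return 1.0 / (1.0 + pow_sum);
}

// gating steady states and time constants at voltage V; order:
// m h j d f b g oa oi xr xs
static void gating_tables(double V, double* xinf, double* tau) {
  // INa (Luo-Rudy style)
  double am = (std::fabs(V + 47.13) < 1e-6) ? 3.2
            : 0.32 * (V + 47.13) / (1.0 - std::exp(-0.1 * (V + 47.13)));
  double bm = 0.08 * std::exp(-V / 11.0);
  double ah, bh, aj, bj;
  if (V < -40.0) {
    ah = 0.135 * std::exp((V + 80.0) / -6.8);
    bh = 3.56 * std::exp(0.079 * V) + 3.1e5 * std::exp(0.35 * V);
    aj = (-1.2714e5 * std::exp(0.2444 * V) - 3.474e-5 * std::exp(-0.04391 * V)) *
         (V + 37.78) / (1.0 + std::exp(0.311 * (V + 79.23)));
    bj = 0.1212 * std::exp(-0.01052 * V) / (1.0 + std::exp(-0.1378 * (V + 40.14)));
  } else {
    ah = 0.0;
    bh = 1.0 / (0.13 * (1.0 + std::exp(-(V + 10.66) / 11.1)));
    aj = 0.0;
    bj = 0.3 * std::exp(-2.535e-7 * V) / (1.0 + std::exp(-0.1 * (V + 32.0)));
  }
  xinf[0] = am / (am + bm); tau[0] = 1.0 / (am + bm);
  xinf[1] = (ah + bh > 0) ? ah / (ah + bh) : 0.0; tau[1] = 1.0 / (ah + bh);
  xinf[2] = (aj + bj > 0) ? aj / (aj + bj) : 0.0; tau[2] = 1.0 / (aj + bj);

  // ICaL activation d / voltage inactivation f
  double dv = V + 10.0;
  double dinf = 1.0 / (1.0 + std::exp(-dv / 8.0));
  double taud;
  if (std::fabs(dv) < 1e-6) taud = 4.579 / (1.0 + std::exp(-dv / 6.24));
  else taud = (1.0 - std::exp(-dv / 6.24)) / (0.035 * dv * (1.0 + std::exp(-dv / 6.24)));
  xinf[3] = dinf; tau[3] = taud;
  xinf[4] = 1.0 / (1.0 + std::exp((V + 28.0) / 6.9));
  tau[4]  = 9.0 / (0.0197 * std::exp(-sq(0.0337 * (V + 10.0))) + 0.02);

  // ICaT activation b / inactivation g
  xinf[5] = 1.0 / (1.0 + std::exp(-(V + 48.0) / 7.0));
  tau[5]  = 1.0 + 2.0 / (1.0 + std::exp((V + 30.0) / 10.0));
  xinf[6] = 1.0 / (1.0 + std::exp((V + 66.0) / 6.0));
  tau[6]  = 8.0 + 30.0 / (1.0 + std::exp((V + 60.0) / 10.0));

  // Ito activation oa / inactivation oi (KQ10 = 3)
  double aoa = 0.65 / (std::exp(-(V + 10.0) / 8.5) + std::exp(-(V - 30.0) / 59.0));
  double boa = 0.65 / (2.5 + std::exp((V + 82.0) / 17.0));
  xinf[7] = 1.0 / (1.0 + std::exp(-(V + 20.47) / 17.54));
  tau[7]  = 1.0 / ((aoa + boa) * 3.0);
  double aoi = 1.0 / (18.53 + std::exp((V + 113.7) / 10.95));
  double boi = 1.0 / (35.56 + std::exp(-(V + 1.26) / 7.44));
  xinf[8] = 1.0 / (1.0 + std::exp((V + 43.1) / 5.3));
  tau[8]  = 1.0 / ((aoi + boi) * 3.0);

  // IKr xr
  double vr = V + 14.1;
  double axr = (std::fabs(vr) < 1e-6) ? 0.0015 : 0.0003 * vr / (1.0 - std::exp(-vr / 5.0));
  double vrb = V - 3.3328;
  double bxr = (std::fabs(vrb) < 1e-6) ? 3.7836e-4
             : 7.3898e-5 * vrb / (std::exp(vrb / 5.1237) - 1.0);
  xinf[9] = 1.0 / (1.0 + std::exp(-vr / 6.5));
  tau[9]  = 1.0 / (axr + bxr);

  // IKs xs
  double vs = V - 19.9;
  double axs = (std::fabs(vs) < 1e-6) ? 6.8e-4 : 4e-5 * vs / (1.0 - std::exp(-vs / 17.0));
  double bxs = (std::fabs(vs) < 1e-6) ? 3.15e-4 : 3.5e-5 * vs / (std::exp(vs / 9.0) - 1.0);
  xinf[10] = std::pow(1.0 + std::exp(-vs / 12.7), -0.5);
  tau[10]  = 0.5 / (axs + bxs);
}

struct Currents {
  double ICaL, ICaT, INa, Ito, IKr, IKs, IK1, ICab, INab, IClb, INCX, INaK, ICaP;
  double total() const {
    return ICaL + ICaT + INa + Ito + IKr + IKs + IK1 + ICab + INab + IClb +
           INCX + INaK + ICaP;
  }
};

// Whole-cell membrane currents (pA/pF). Calcium-facing currents use the two
// membrane domains' sub-sarcolemmal / junctional free calcium; each membrane
// domain carries half of each sarcolemmal current.
static Currents membrane_currents(const double* y, const double* p) {
  Currents c;
  const int n = (int)p[P_NDOM];
  const double V = y[IDX_V];
  const double Na = y[IDX_NA], K = y[IDX_K];
  const double Cao = p[P_CAO], Nao = p[P_NAO], Ko = p[P_KO];

  const double ENa = RTF * std::log(Nao / Na);
  const double EK  = RTF * std::log(Ko / K);

  const double m = y[1], h = y[2], jg = y[3], d = y[4], f = y[5];
  const double b = y[6], gt = y[7], oa = y[8], oi = y[9], xr = y[10], xs = y[11];

  c.INa  = p[P_GNA] * m * m * m * h * jg * (V - ENa);
  c.Ito  = p[P_GTO] * oa * oa * oa * oi * (V - EK);
  c.IKr  = p[P_GKR] * xr * (V - EK) / (1.0 + std::exp((V + 15.0) / 22.4));
  c.IKs  = p[P_GKS] * xs * xs * (V - EK);
  c.IK1  = p[P_GK1] * (V - EK) / (1.0 + std::exp(0.07 * (V + 80.0)));
  c.INab = p[P_GNAB] * (V - ENa);
  c.IClb = p[P_GCLB] * (V - p[P_ECL]);
  c.ICaT = p[P_GCAT] * b * gt * (V - 45.0);

  // Na-K pump
  double sigma = (std::exp(Nao / 67.3) - 1.0) / 7.0;
  double fnak = 1.0 / (1.0 + 0.1245 * std::exp(-0.1 * V / RTF) +
                       0.0365 * sigma * std::exp(-V / RTF));
  c.INaK = p[P_VNAK] * fnak * (Ko / (Ko + 1.5)) /
           (1.0 + std::pow(10.0 / Na, 1.5));

  c.ICaL = 0.0; c.INCX = 0.0; c.ICab = 0.0; c.ICaP = 0.0;
  const double ez  = std::exp(0.2 * V / RTF);
  const double ez1 = std::exp(-0.8 * V / RTF);
  for (int w = 0; w < 2; ++w) {
    double casl = y[idx_sl(n, w)];
    double caj  = y[idx_j(n, w)];
    double fca = 1.0 / (1.0 + caj / p[P_KDFCA]);
    c.ICaL += 0.5 * p[P_GCAL] * d * f * fca * (V - 65.0);
    double ECaSL = 0.5 * RTF * std::log(Cao / casl);
    c.ICab += 0.5 * p[P_GCAB] * (V - ECaSL);
    c.ICaP += 0.5 * p[P_VCAP] * casl / (casl + 0.0005);
    double allo = 1.0 / (1.0 + sq(0.00004 / casl));
    double num = ez * Na * Na * Na * Cao - ez1 * Nao * Nao * Nao * casl;
    double den = (87.5 * 87.5 * 87.5 + Nao * Nao * Nao) * (1.38 + Cao) *
                 (1.0 + 0.1 * ez1);
    c.INCX += 0.5 * p[P_VNCX] * allo * num / den;
  }
  return c;
}

// Full right-hand side. stim is the applied stimulus in pA/pF (positive =
// depolarizing; entered with negative sign in the current balance and
// booked as a potassium flux). Optional aux buffers receive per-domain
// fluxes for diagnostics/tests.
static void compute_rhs(const double* y, const double* p, double stim,
                        double* dy, Currents* cur_out,
                        double* aux_jrel, double* aux_jup, double* aux_jleak,
                        double* aux_jdiff) {
  const int n = (int)p[P_NDOM];
  const int ny = IDX_DOM0 + DOM_STRIDE * n + 4;
  for (int i = 0; i < ny; ++i) dy[i] = 0.0;

  const double V = y[IDX_V];
  Currents c = membrane_currents(y, p);
  if (cur_out) *cur_out = c;

  dy[IDX_V] = -(c.total() - stim);

  // gates
  double xinf[N_GATES], tau[N_GATES];
  gating_tables(V, xinf, tau);
  for (int g = 0; g < N_GATES; ++g)
    dy[IDX_GATE0 + g] = (xinf[g] - y[IDX_GATE0 + g]) / tau[g];

  // bulk ions
  const double vmyo = n * p[P_VCYTO];
  const double cm = p[P_CM];
  dy[IDX_NA] = -(c.INa + c.INab + 3.0 * c.INCX + 3.0 * c.INaK) * cm /
               (FDAY * vmyo * p[P_FNAVOL]);
  dy[IDX_K] = -(c.Ito + c.IKr + c.IKs + c.IK1 - 2.0 * c.INaK - stim) * cm /
              (FDAY * vmyo);

  const double vc = p[P_VCYTO], vsr = p[P_VSR], vsrs = p[P_VSRS];
  const double vsl = p[P_VSL], vj = p[P_VJ];
  const double hup = p[P_HUP];

  for (int i = 0; i < n; ++i) {
    const double ca   = y[idx_dom(i, 0)];
    const double casr = y[idx_dom(i, 1)];
    const double cass = y[idx_dom(i, 2)];
    const double O    = y[idx_dom(i, 3)];
    const double R    = y[idx_dom(i, 4)];

    // SERCA (reversible Hill), cytosolic frame
    double fwd = std::pow(ca / p[P_KMF], hup);
    double rev = std::pow(casr / p[P_KMR], hup);
    double jup = p[P_VUP] * (fwd - rev) / (1.0 + fwd + rev);

    // RyR release (SRS frame) and passive SR leak (cytosolic frame)
    double jrel = p[P_KREL] * O * (casr - cass);
    double jleak = p[P_GLEAK] * (casr - ca);

    // SRS <-> cytosol transfer (SRS frame)
    double jxfer = (cass - ca) / p[P_TAUXFER];

    // inter-domain diffusion (cytosolic frame; equal cytosolic volumes)
    double jdiff = 0.0;
    if (i > 0)     jdiff += p[P_GDIFF] * (y[idx_dom(i - 1, 0)] - ca);
    if (i < n - 1) jdiff += p[P_GDIFF] * (y[idx_dom(i + 1, 0)] - ca);

    // sub-SR space network: released calcium also spreads laterally at
    // high concentration between neighboring domains' sub-SR spaces
    double jdsrs = 0.0;
    if (i > 0)     jdsrs += p[P_GSRS] * (y[idx_dom(i - 1, 2)] - cass);
    if (i < n - 1) jdsrs += p[P_GSRS] * (y[idx_dom(i + 1, 2)] - cass);

    double jc_net = jleak - jup + jdiff + jxfer * (vsrs / vc);
    double jss_net = jrel - jxfer + jdsrs;

    // membrane domains: SL and junctional sub-spaces + sarcolemmal Ca fluxes
    int w = (i == 0) ? 0 : (i == n - 1) ? 1 : -1;
    if (w >= 0) {
      double casl = y[idx_sl(n, w)];
      double caj  = y[idx_j(n, w)];
      double jslx = (casl - ca) / p[P_TAUSL];         // SL frame
      double jjx  = (caj - cass) / p[P_TAUJ];          // junctional frame
      jc_net  += jslx * (vsl / vc);
      jss_net += jjx * (vj / vsrs);

      // halves of the sarcolemmal Ca currents for this membrane domain;
      // reverse-mode NCX (outward current) imports Ca, one Ca per net charge
      double icab = 0.5 * c.ICab, icap = 0.5 * c.ICaP, incx = 0.5 * c.INCX;
      double icat = 0.5 * c.ICaT;
      double ical = 0.5 * c.ICaL;
      double jsl_cur = (incx / FDAY -
                        (icab + icat + icap) / (2.0 * FDAY)) * cm / vsl;
      double jj_cur = -ical * cm / (2.0 * FDAY * vj);
      // weak coupling of the SL space to the release microdomain: the SL
      // space sees a few-uM post-release signal that drives forward NCX
      double jslsrs = (cass - casl) / p[P_TAUSSL];
      jss_net -= jslsrs * (vsl / vsrs);

      dy[idx_sl(n, w)] = beta_buf(casl, p, 0) * (jsl_cur + jslsrs - jslx);
      dy[idx_j(n, w)]  = beta_buf(caj, p, 3) * (jj_cur - jjx);
    }

    dy[idx_dom(i, 0)] = beta_buf(ca, p, 0) * jc_net;
    dy[idx_dom(i, 2)] = beta_buf(cass, p, 2) * jss_net;
    dy[idx_dom(i, 1)] = beta_buf(casr, p, 1) *
      (-jrel * (vsrs / vsr) + (jup - jleak) * (vc / vsr));

    // mean-field CRU gating
    double act, phi;
    if (p[P_HACT] == 4.0) {
      double c4 = sq(sq(cass)), k4 = sq(sq(p[P_KSRS]));
      act = c4 / (c4 + k4);
    } else {
      double ch = std::pow(cass, p[P_HACT]);
      act = ch / (ch + std::pow(p[P_KSRS], p[P_HACT]));
    }
    if (p[P_HSR] == 4.0) {
      double s4 = sq(sq(casr)), q4 = sq(sq(p[P_KSRLOAD]));
      phi = s4 / (s4 + q4);
    } else {
      double sh = std::pow(casr, p[P_HSR]);
      phi = sh / (sh + std::pow(p[P_KSRLOAD], p[P_HSR]));
    }
    double kopen = p[P_KOPEN] * act * phi;
    double ki = p[P_KI0] * cass / (cass + p[P_KIHALF]);
    double cin = p[P_KCI] * sq(cass) / (sq(cass) + sq(p[P_KCIHALF]));
    double avail = 1.0 - O - R;
    dy[idx_dom(i, 3)] = kopen * avail - p[P_KCLOSE] * O - ki * O;
    dy[idx_dom(i, 4)] = ki * O + cin * avail - p[P_KR] * R;

    if (aux_jrel)  aux_jrel[i]  = jrel;
    if (aux_jup)   aux_jup[i]   = jup;
    if (aux_jleak) aux_jleak[i] = jleak;
    if (aux_jdiff) aux_jdiff[i] = jdiff;
  }
}

// [[Rcpp::export(name = ".cw_n_params")]]
int cw_n_params() { return (int)N_PAR; }

// [[Rcpp::export(name = ".cw_rhs")]]
List cw_rhs(NumericVector y, NumericVector p, double stim = 0.0) {
  const int n = (int)p[P_NDOM];
  const int ny = IDX_DOM0 + DOM_STRIDE * n + 4;
  if (y.size() != ny) stop("state vector has wrong length");
  for (int i = 0; i < ny; ++i)
    if (!std::isfinite(y[i])) stop("invalid state: non-finite value at index %d", i + 1);
  NumericVector dy(ny);
  NumericVector jrel(n), jup(n), jleak(n), jdiff(n);
  Currents c;
  compute_rhs(REAL(y), REAL(p), stim, REAL(dy), &c,
              REAL(jrel), REAL(jup), REAL(jleak), REAL(jdiff));
  NumericVector cur = NumericVector::create(
    _["ICaL"] = c.ICaL, _["ICaT"] = c.ICaT, _["INa"] = c.INa, _["Ito1"] = c.Ito,
    _["IKr"] = c.IKr, _["IKs"] = c.IKs, _["IK1"] = c.IK1, _["ICab"] = c.ICab,
    _["INab"] = c.INab, _["IClb"] = c.IClb, _["INCX"] = c.INCX,
    _["INaK"] = c.INaK, _["ICaP"] = c.ICaP);
  return List::create(_["dy"] = dy, _["currents"] = cur, _["Jrel"] = jrel,
                      _["Jup"] = jup, _["Jleak"] = jleak, _["Jdiff"] = jdiff);
}

// [[Rcpp::export(name = ".cw_rhs_dy")]]
NumericVector cw_rhs_dy(NumericVector y, NumericVector p, double stim = 0.0) {
  const int n = (int)p[P_NDOM];
  const int ny = IDX_DOM0 + DOM_STRIDE * n + 4;
  NumericVector dy(ny);
  compute_rhs(REAL(y), REAL(p), stim, REAL(dy), nullptr,
              nullptr, nullptr, nullptr, nullptr);
  return dy;
}

// [[Rcpp::export(name = ".cw_currents")]]
NumericVector cw_currents(NumericVector y, NumericVector p) {
  Currents c = membrane_currents(REAL(y), REAL(p));
  return NumericVector::create(
    _["ICaL"] = c.ICaL, _["ICaT"] = c.ICaT, _["INa"] = c.INa, _["Ito1"] = c.Ito,
    _["IKr"] = c.IKr, _["IKs"] = c.IKs, _["IK1"] = c.IK1, _["ICab"] = c.ICab,
    _["INab"] = c.INab, _["IClb"] = c.IClb, _["INCX"] = c.INCX,
    _["INaK"] = c.INaK, _["ICaP"] = c.ICaP);
}

// [[Rcpp::export(name = ".cw_beta")]]
double cw_beta(double ca, NumericVector p, int which) {
  return beta_buf(ca, REAL(p), which);
}

// [[Rcpp::export(name = ".cw_gating_inf")]]
NumericVector cw_gating_inf(double V) {
  double xinf[N_GATES], tau[N_GATES];
  gating_tables(V, xinf, tau);
  NumericVector out(N_GATES);
  for (int g = 0; g < N_GATES; ++g) out[g] = xinf[g];
  return out;
}

// Fixed-step operator-split integrator: Rush-Larsen exponential updates for
// the Hodgkin-Huxley gates, forward Euler for voltage, concentrations and
// CRU states. Integrates n_beats cycles of length cl with a square stimulus
// pulse at the start of each cycle; records every output_dt from
// record_from_beat (0-based) onward.
// [[Rcpp::export(name = ".cw_integrate")]]
List cw_integrate(NumericVector y0, NumericVector p, int n_beats, double cl,
                  double stim_amp, double stim_dur, double dt,
                  double output_dt, int record_from_beat) {
  const int n = (int)p[P_NDOM];
  const int ny = IDX_DOM0 + DOM_STRIDE * n + 4;
  if (y0.size() != ny) stop("state vector has wrong length");
  const double* pp = REAL(p);

  std::vector<double> y(REAL(y0), REAL(y0) + ny), dy(ny);

  const int steps_per_beat = (int)std::lround(cl / dt);
  const int rec_stride = std::max(1, (int)std::lround(output_dt / dt));
  const int rec_beats = n_beats - record_from_beat;
  const int nt = (rec_beats > 0) ? (rec_beats * steps_per_beat) / rec_stride + 1 : 0;

  NumericVector tout(std::max(nt, 0)), Vout(std::max(nt, 0)),
      Naout(std::max(nt, 0)), SRout(std::max(nt, 0));
  NumericMatrix camat(n, std::max(nt, 0));

  double xinf[N_GATES], tau[N_GATES];
  int it = 0;
  bool failed = false;
  double t_fail = NA_REAL;

  long step_global = 0;
  for (int beat = 0; beat < n_beats && !failed; ++beat) {
    for (int s = 0; s < steps_per_beat; ++s, ++step_global) {
      double tb = s * dt;
      double t = beat * cl + tb;

      // record state before the step, aligned to the recording grid
      if (beat >= record_from_beat) {
        long local = (long)(beat - record_from_beat) * steps_per_beat + s;
        if (local % rec_stride == 0 && it < nt) {
          tout[it] = t; Vout[it] = y[IDX_V]; Naout[it] = y[IDX_NA];
          double srm = 0.0;
          for (int i = 0; i < n; ++i) {
            camat(i, it) = y[idx_dom(i, 0)];
            srm += y[idx_dom(i, 1)];
          }
          SRout[it] = srm / n;
          ++it;
        }
      }

      double stim = (tb < stim_dur) ? stim_amp : 0.0;
      compute_rhs(y.data(), pp, stim, dy.data(), nullptr,
                  nullptr, nullptr, nullptr, nullptr);

      // Rush-Larsen gates
      gating_tables(y[IDX_V], xinf, tau);
      for (int g = 0; g < N_GATES; ++g) {
        int k = IDX_GATE0 + g;
        y[k] = xinf[g] + (y[k] - xinf[g]) * std::exp(-dt / tau[g]);
      }
      // Euler for everything else
      y[IDX_V] += dt * dy[IDX_V];
      y[IDX_NA] += dt * dy[IDX_NA];
      y[IDX_K] += dt * dy[IDX_K];
      for (int k = IDX_DOM0; k < ny; ++k) {
        y[k] += dt * dy[k];
        if (y[k] < 0.0) y[k] = 0.0;  // concentrations and CRU fractions
      }

      if (s % 50 == 0) {
        if (!std::isfinite(y[IDX_V]) || std::fabs(y[IDX_V]) > 300.0) {
          failed = true; t_fail = t; break;
        }
      }
    }
  }

  // final grid point at the end of the run
  if (!failed && rec_beats > 0 && it < nt) {
    tout[it] = n_beats * cl; Vout[it] = y[IDX_V]; Naout[it] = y[IDX_NA];
    double srm = 0.0;
    for (int i = 0; i < n; ++i) { camat(i, it) = y[idx_dom(i, 0)]; srm += y[idx_dom(i, 1)]; }
    SRout[it] = srm / n;
    ++it;
  }

  NumericVector yfin(ny);
  for (int i = 0; i < ny; ++i) yfin[i] = y[i];

  return List::create(_["t"] = tout, _["V"] = Vout, _["Na_i"] = Naout,
                      _["Ca_SR_mean"] = SRout, _["Ca_cyto"] = camat,
                      _["n_recorded"] = it, _["state"] = yfin,
                      _["failed"] = failed, _["t_fail"] = t_fail);
}
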