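// Reduced human ventricular myocyte engine.
//
// 21 state variables: V, m, h, j, hL, d, f, fca, r, s, xr1, xr2, xs,
// Cai, CaSR, Nai, Rbar, Ften, m18, h18, grel.
// SR release is d-gate triggered (CICR surrogate), terminated by a fast
// Ca-dependent gate grel and modulated by a slow refractoriness variable
// Rbar whose incomplete recovery at short diastolic intervals produces
// calcium-transient alternans.
// Hodgkin-Huxley gating with Rush-Larsen updates; GHK-style L-type Ca
// driving force; load-dependent SR release with a refractoriness gate
// (enables Ca-transient alternans); Ca-driven active tension; optional
// Nav1.8 current with right-shifted Boltzmann gating.
//
// Voltage-dependent gate steady states, Rush-Larsen factors and current
// prefactors are precomputed on a uniform V lookup table (built per run
// from the configuration), which keeps a population trial tractable.
// Fixed-step integration: a fine step inside a window after each stimulus
// (upstroke), a coarse step elsewhere; fully deterministic.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

const double VMIN = -130.0, VMAX = 90.0, DV = 0.05;
const int NROW = (int)((VMAX - VMIN) / DV) + 2;

// table column indices
enum {
  C_MINF, C_HINF, C_JINF, C_DINF, C_FINF, C_RINF, C_SINF,
  C_XR1INF, C_XR2INF, C_XSINF, C_HLINF, C_MLINF, C_M18INF, C_H18INF,
  C_XK1, C_E1, C_E2, C_INAKF, C_COLA, C_COLB,
  C_RLF0,                 // 10 fine rlf columns start here
  C_RLC0 = C_RLF0 + 10,   // 10 coarse rlf columns
  NCOL = C_RLC0 + 10
};

struct Consts {
  double gNa, gNaL, gto, kCaL, gKr, gKs, gK1, kNaCa, PNaK;
  double GpCa, KpCa, gbCa, gbNa;
  double Vmaxup, Kup, Vrel, arel, brel, brelH, crel, k2c, k4, powRbar,
         Vleak, vratio;
  double tauGrelInact, tauGrelRec, KgrelCa, Krefill;
  double Bufc, Kbufc, Bufsr, Kbufsr;
  double kCa, kNa;
  double Nao, Cao, Ko, Ki;
  double tauhL, taufca, fcaFloor, KfCa;
  double Ca50, hillT, tauF;
  double dMid, dSlope, fMid, fSlope, fFloor, fSlowAmp, fPlateau, fDepolAmp,
         fRestAmp;
  double n18actMid, n18actSlope, n18inactMid, n18inactSlope, n18p,
         tauM18, tauH18;
  double stimAmp, stimDur, dtFine, dtCoarse, fineMs, recordDt;
  double rtf;
};

double getc(const List& cfg, const char* nm) {
  if (!cfg.containsElementNamed(nm))
    stop("engine config is missing constant '%s'", nm);
  return as<double>(cfg[nm]);
}

Consts readConsts(const List& cfg) {
  Consts c;
  c.gNa = getc(cfg, "gNa"); c.gNaL = getc(cfg, "gNaL");
  c.gto = getc(cfg, "gto"); c.kCaL = getc(cfg, "kCaL");
  c.gKr = getc(cfg, "gKr"); c.gKs = getc(cfg, "gKs");
  c.gK1 = getc(cfg, "gK1"); c.kNaCa = getc(cfg, "kNaCa");
  c.PNaK = getc(cfg, "PNaK");
  c.GpCa = getc(cfg, "GpCa"); c.KpCa = getc(cfg, "KpCa");
  c.gbCa = getc(cfg, "gbCa"); c.gbNa = getc(cfg, "gbNa");
  c.Vmaxup = getc(cfg, "Vmaxup"); c.Kup = getc(cfg, "Kup");
  c.Vrel = getc(cfg, "Vrel");
  c.arel = getc(cfg, "arel"); c.brel = getc(cfg, "brel");
  c.brelH = getc(cfg, "brelH"); c.crel = getc(cfg, "crel");
  c.tauGrelInact = getc(cfg, "tauGrelInact");
  c.tauGrelRec = getc(cfg, "tauGrelRec");
  c.KgrelCa = getc(cfg, "KgrelCa");
  c.Krefill = getc(cfg, "Krefill");
  c.k2c = getc(cfg, "k2c"); c.k4 = getc(cfg, "k4");
  c.powRbar = getc(cfg, "powRbar");
  c.Vleak = getc(cfg, "Vleak"); c.vratio = getc(cfg, "vratio");
  c.Bufc = getc(cfg, "Bufc"); c.Kbufc = getc(cfg, "Kbufc");
  c.Bufsr = getc(cfg, "Bufsr"); c.Kbufsr = getc(cfg, "Kbufsr");
  c.kCa = getc(cfg, "kCa"); c.kNa = getc(cfg, "kNa");
  c.Nao = getc(cfg, "Nao"); c.Cao = getc(cfg, "Cao");
  c.Ko = getc(cfg, "Ko"); c.Ki = getc(cfg, "Ki");
  c.tauhL = getc(cfg, "tauhL"); c.taufca = getc(cfg, "taufca");
  c.fcaFloor = getc(cfg, "fcaFloor"); c.KfCa = getc(cfg, "KfCa");
  c.Ca50 = getc(cfg, "Ca50"); c.hillT = getc(cfg, "hillT");
  c.tauF = getc(cfg, "tauF");
  c.dMid = getc(cfg, "dMid"); c.dSlope = getc(cfg, "dSlope");
  c.fMid = getc(cfg, "fMid"); c.fSlope = getc(cfg, "fSlope");
  c.fFloor = getc(cfg, "fFloor");
  c.fSlowAmp = getc(cfg, "fSlowAmp"); c.fPlateau = getc(cfg, "fPlateau");
  c.fDepolAmp = getc(cfg, "fDepolAmp");
  c.fRestAmp = getc(cfg, "fRestAmp");
  c.n18actMid = getc(cfg, "nav18ActMid");
  c.n18actSlope = getc(cfg, "nav18ActSlope");
  c.n18inactMid = getc(cfg, "nav18InactMid");
  c.n18inactSlope = getc(cfg, "nav18InactSlope");
  c.n18p = getc(cfg, "nav18Power");
  c.tauM18 = getc(cfg, "nav18TauM"); c.tauH18 = getc(cfg, "nav18TauH");
  c.stimAmp = getc(cfg, "stimAmplitude");
  c.stimDur = getc(cfg, "stimDuration");
  c.dtFine = getc(cfg, "dtFine"); c.dtCoarse = getc(cfg, "dtCoarse");
  c.fineMs = getc(cfg, "fineWindowMs");
  c.recordDt = getc(cfg, "recordDt");
  c.rtf = getc(cfg, "rtf");
  return c;
}

inline double boltz(double V, double mid, double slope) {
  // ascending sigmoid for positive slope
  return 1.0 / (1.0 + std::exp(-(V - mid) / slope));
}

void buildTable(const Consts& c, std::vector<double>& tab) {
  tab.assign((size_t)NROW * NCOL, 0.0);
  const double EK = c.rtf * std::log(c.Ko / c.Ki);
  double tau[10]; // V-dependent taus: m h j d f r s xr1 xr2 xs
  for (int i = 0; i < NROW; ++i) {
    double V = VMIN + i * DV;
    double* row = &tab[(size_t)i * NCOL];
    // INa gates
    row[C_MINF] = boltz(V, -40.0, 6.5);
    tau[0] = 0.10 + 0.40 / (1.0 + std::exp((V + 50.0) / 8.0));
    row[C_HINF] = 1.0 / (1.0 + std::exp((V + 70.0) / 6.5));
    tau[1] = 0.25 + 12.0 / (1.0 + std::exp((V + 60.0) / 7.0));
    row[C_JINF] = row[C_HINF];
    tau[2] = 4.0 + 50.0 / (1.0 + std::exp((V + 60.0) / 7.0));
    // ICaL gates
    row[C_DINF] = boltz(V, c.dMid, c.dSlope);
    tau[3] = 0.6 + 5.0 * std::exp(-std::pow((V + 10.0) / 20.0, 2));
    row[C_FINF] = c.fFloor + (1.0 - c.fFloor) /
                  (1.0 + std::exp((V - c.fMid) / c.fSlope));
    tau[4] = c.fSlowAmp * std::exp(-std::pow(V + 27.0, 2) / 240.0) +
             c.fPlateau +
             c.fDepolAmp / (1.0 + std::exp((25.0 - V) / 10.0)) +
             c.fRestAmp / (1.0 + std::exp((V + 65.0) / 8.0));
    // Ito gates
    row[C_RINF] = boltz(V, 20.0, 6.0);
    tau[5] = 9.5 * std::exp(-std::pow(V + 40.0, 2) / 1800.0) + 0.8;
    row[C_SINF] = 1.0 / (1.0 + std::exp((V + 20.0) / 5.0));
    tau[6] = 85.0 * std::exp(-std::pow(V + 45.0, 2) / 320.0) +
             5.0 / (1.0 + std::exp((V - 20.0) / 5.0)) + 3.0;
    // IKr gates
    row[C_XR1INF] = boltz(V, -26.0, 7.0);
    tau[7] = (450.0 / (1.0 + std::exp((-45.0 - V) / 10.0))) *
             (6.0 / (1.0 + std::exp((V + 30.0) / 11.5)));
    row[C_XR2INF] = 1.0 / (1.0 + std::exp((V + 88.0) / 24.0));
    tau[8] = (3.0 / (1.0 + std::exp((-60.0 - V) / 20.0))) *
             (1.12 / (1.0 + std::exp((V - 60.0) / 20.0)));
    // IKs gate
    row[C_XSINF] = boltz(V, -5.0, 14.0);
    tau[9] = (1100.0 / std::sqrt(1.0 + std::exp((-10.0 - V) / 6.0))) *
             (1.0 / (1.0 + std::exp((V - 60.0) / 20.0)));
    // INaL
    row[C_HLINF] = 1.0 / (1.0 + std::exp((V + 80.0) / 7.5));
    row[C_MLINF] = boltz(V, -42.85, 5.264);
    // Nav1.8
    row[C_M18INF] = boltz(V, c.n18actMid, c.n18actSlope);
    row[C_H18INF] = 1.0 / (1.0 + std::exp((V - c.n18inactMid) / c.n18inactSlope));
    // IK1 rectification
    {
      double vk = V - EK;
      double a = 0.1 / (1.0 + std::exp(0.06 * (vk - 200.0)));
      double b = (3.0 * std::exp(0.0002 * (vk + 100.0)) +
                  std::exp(0.1 * (vk - 10.0))) /
                 (1.0 + std::exp(-0.5 * vk));
      row[C_XK1] = a / (a + b);
    }
    // INaCa exponentials
    row[C_E1] = std::exp(0.35 * V / c.rtf);
    row[C_E2] = std::exp(-0.65 * V / c.rtf);
    // INaK voltage factor
    row[C_INAKF] = 1.0 / (1.0 + 0.1245 * std::exp(-0.1 * V / c.rtf) +
                          0.0353 * std::exp(-V / c.rtf));
    // GHK-style ICaL prefactors: ICaL = kCaL*d*f*fca*(Cai*colA - Cao*colB)
    {
      double q = 2.0 * V / c.rtf;
      double colA, colB;
      if (std::fabs(q) < 1e-4) {
        colA = 2.0; colB = 0.682;
      } else {
        double eq = std::exp(q);
        double pref = (4.0 / c.rtf) * V / (eq - 1.0);
        colA = pref * eq;
        colB = pref * 0.341;
      }
      row[C_COLA] = colA;
      row[C_COLB] = colB;
    }
    for (int g = 0; g < 10; ++g) {
      row[C_RLF0 + g] = 1.0 - std::exp(-c.dtFine / tau[g]);
      row[C_RLC0 + g] = 1.0 - std::exp(-c.dtCoarse / tau[g]);
    }
  }
}

inline double clamp01(double x) {
  return x < 0.0 ? 0.0 : (x > 1.0 ? 1.0 : x);
}

} // namespace

// [[Rcpp::export(name = ".engine_run")]]
List engine_run(NumericVector state0, NumericVector mult, List cfg,
                double cl, int nBeats, int recordLastN,
                bool recordCurrents) {
  if (state0.size() != 21) stop("state vector must have 21 elements");
  if (mult.size() != 13) stop("multiplier vector must have 13 elements");
  if (nBeats < 1) stop("nBeats must be >= 1");
  if (recordLastN < 0 || recordLastN > nBeats)
    stop("recordLastN must be in [0, nBeats]");

  Consts c = readConsts(cfg);
  std::vector<double> tab;
  buildTable(c, tab);

  // multipliers (camkii folded in upstream): conductance scalings
  const double mNa = mult[0], mNaL = mult[1], mto = mult[2], mCaL = mult[3],
               mKr = mult[4], mKs = mult[5], mK1 = mult[6], mNaCa = mult[7],
               mNaK = mult[8], mjup = mult[9], mjrel = mult[10],
               mjleak = mult[11], gNav18 = mult[12];

  const double EK = c.rtf * std::log(c.Ko / c.Ki);
  const double sqko = std::sqrt(c.Ko / 5.4);
  const double KmNai = 87.5, KmCa = 1.38, ksat = 0.1, alpha = 2.5;
  const double nacaDen0 = (std::pow(KmNai, 3) + std::pow(c.Nao, 3)) *
                          (KmCa + c.Cao);
  const double Nao3 = std::pow(c.Nao, 3);

  // state
  double V = state0[0], m = state0[1], h = state0[2], j = state0[3],
         hL = state0[4], d = state0[5], f = state0[6], fca = state0[7],
         r = state0[8], s = state0[9], xr1 = state0[10], xr2 = state0[11],
         xs = state0[12], Cai = state0[13], CaSR = state0[14],
         Nai = state0[15], Rbar = state0[16], Ften = state0[17],
         m18 = state0[18], h18 = state0[19], grel = state0[20];

  // recording setup
  const int firstRec = nBeats - recordLastN; // 0-based beat index
  const int nPerBeat = (recordLastN > 0)
      ? (int)std::floor(cl / c.recordDt + 1e-9)
      : 0;
  const long nRec = (long)nPerBeat * recordLastN;
  NumericVector rT(nRec), rV(nRec), rCai(nRec), rCaSR(nRec), rNai(nRec),
      rF(nRec);
  NumericMatrix rCur(recordCurrents ? nRec : 0, 5); // ICaL IKr INa INaL INav18
  IntegerVector beatStarts(recordLastN);
  NumericVector stimTimes(recordLastN);

  // const-tau Rush-Larsen factors for both dt levels
  const double rlfHL[2] = {1.0 - std::exp(-c.dtFine / c.tauhL),
                           1.0 - std::exp(-c.dtCoarse / c.tauhL)};
  const double rlfFca[2] = {1.0 - std::exp(-c.dtFine / c.taufca),
                            1.0 - std::exp(-c.dtCoarse / c.taufca)};
  const double rlfM18[2] = {1.0 - std::exp(-c.dtFine / c.tauM18),
                            1.0 - std::exp(-c.dtCoarse / c.tauM18)};
  const double rlfH18[2] = {1.0 - std::exp(-c.dtFine / c.tauH18),
                            1.0 - std::exp(-c.dtCoarse / c.tauH18)};
  const double rlfFt[2] = {1.0 - std::exp(-c.dtFine / c.tauF),
                           1.0 - std::exp(-c.dtCoarse / c.tauF)};

  double maxAbsINa = 0.0, maxAbsINav18 = 0.0;
  int errorBeat = -1;
  long recIdx = 0;

  const double inv_dv = 1.0 / DV;

  // integer step bookkeeping: fine phase after stimulus, coarse for the rest
  const long sFine = std::lround(c.fineMs / c.dtFine);
  const long sCoarse = std::lround((cl - c.fineMs) / c.dtCoarse);
  const long kF = std::lround(c.recordDt / c.dtFine);
  const long kC = std::lround(c.recordDt / c.dtCoarse);
  const long stepsTotal = sFine + sCoarse;

  for (int beat = 0; beat < nBeats && errorBeat < 0; ++beat) {
    const bool rec = (beat >= firstRec);
    if (rec) {
      int bi = beat - firstRec;
      beatStarts[bi] = (int)((long)bi * nPerBeat) + 1; // 1-based
      stimTimes[bi] = (double)beat * cl;
    }
    // latch the load-release gain at beat start: release is a (steep)
    // fraction of the *initial* SR load, not of the instantaneous load,
    // preserving beat-to-beat load memory
    const double lr0 = std::pow(CaSR / c.brel, c.brelH);
    const double SloadBeat = lr0 / (1.0 + lr0);
    for (long is = 0; is < stepsTotal; ++is) {
      const bool fine = (is < sFine);
      const double dt = fine ? c.dtFine : c.dtCoarse;
      const int lev = fine ? 0 : 1;
      const double tb = fine ? is * c.dtFine
                             : c.fineMs + (is - sFine) * c.dtCoarse;
      const bool doRec = rec && (fine ? (is % kF == 0)
                                      : ((is - sFine) % kC == 0));

      // record before stepping so the t=0 sample is pre-stimulus
      if (doRec) {
        rT[recIdx] = beat * cl + tb;
        rV[recIdx] = V; rCai[recIdx] = Cai; rCaSR[recIdx] = CaSR;
        rNai[recIdx] = Nai; rF[recIdx] = Ften;
        // currents filled below once computed
      }

      // table interpolation
      double vq = (V - VMIN) * inv_dv;
      if (vq < 0.0) vq = 0.0;
      if (vq > NROW - 2) vq = NROW - 2;
      int i0 = (int)vq;
      double w = vq - i0;
      const double* r0 = &tab[(size_t)i0 * NCOL];
      const double* r1 = r0 + NCOL;
      #define TL(k) (r0[k] + w * (r1[k] - r0[k]))

      const double ENa = c.rtf * std::log(c.Nao / Nai);
      const double EKs = c.rtf * std::log((c.Ko + 0.03 * c.Nao) /
                                          (c.Ki + 0.03 * Nai));
      const double ECa = 0.5 * c.rtf * std::log(c.Cao / Cai);

      // currents
      const double INa = c.gNa * mNa * m * m * m * h * j * (V - ENa);
      const double INaL = c.gNaL * mNaL * TL(C_MLINF) * hL * (V - ENa);
      const double Ito = c.gto * mto * r * s * (V - EK);
      const double IKr = c.gKr * mKr * sqko * xr1 * xr2 * (V - EK);
      const double IKs = c.gKs * mKs * xs * xs * (V - EKs);
      const double IK1 = c.gK1 * mK1 * sqko * TL(C_XK1) * (V - EK);
      const double e1 = TL(C_E1), e2 = TL(C_E2);
      const double INaCa = c.kNaCa * mNaCa *
          (e1 * Nai * Nai * Nai * c.Cao - e2 * Nao3 * Cai * alpha) /
          (nacaDen0 * (1.0 + ksat * e2));
      const double INaK = c.PNaK * mNaK * TL(C_INAKF) *
          (c.Ko / (c.Ko + 1.0)) * (Nai / (Nai + 40.0));
      const double IpCa = c.GpCa * Cai / (Cai + c.KpCa);
      const double IbCa = c.gbCa * (V - ECa);
      const double IbNa = c.gbNa * (V - ENa);
      const double ICaL = c.kCaL * mCaL * d * f * fca *
          (Cai * TL(C_COLA) - c.Cao * TL(C_COLB));
      double INav18 = 0.0;
      if (gNav18 > 0.0) {
        double mp = m18;
        for (int p = 1; p < (int)c.n18p; ++p) mp *= m18;
        INav18 = gNav18 * mp * h18 * (V - ENa);
      }

      if (doRec) {
        if (recordCurrents) {
          rCur(recIdx, 0) = ICaL; rCur(recIdx, 1) = IKr;
          rCur(recIdx, 2) = INa; rCur(recIdx, 3) = INaL;
          rCur(recIdx, 4) = INav18;
        }
        ++recIdx;
      }
      if (rec) {
        double aINa = std::fabs(INa);
        if (aINa > maxAbsINa) maxAbsINa = aINa;
        double a18 = std::fabs(INav18);
        if (a18 > maxAbsINav18) maxAbsINav18 = a18;
      }

      const double Istim = (tb < c.stimDur) ? c.stimAmp : 0.0;
      const double Iion = INa + INaL + Ito + IKr + IKs + IK1 + INaCa +
                          INaK + IpCa + IbCa + IbNa + ICaL + INav18;

      // Ca fluxes: d-gated SR release with steep load dependence, fast Ca
      // termination (grel) and slow refill-gated refractoriness (Rbar)
      // cooperative dependence on RyR availability: steep enough that
      // partial Ca-driven inactivation can sustain period-2 alternation
      const double rbp = std::pow(Rbar, c.powRbar);
      const double Jrel = mjrel * c.Vrel * d * grel * rbp *
                          (c.arel * SloadBeat + c.crel) *
                          (CaSR > Cai ? (CaSR - Cai) / 3.0 : 0.0);
      const double Jup = mjup * c.Vmaxup * Cai * Cai /
                         (Cai * Cai + c.Kup * c.Kup);
      const double Jleak = mjleak * c.Vleak * (CaSR - Cai);
      const double bc = 1.0 / (1.0 + c.Bufc * c.Kbufc /
                               std::pow(Cai + c.Kbufc, 2));
      const double bsr = 1.0 / (1.0 + c.Bufsr * c.Kbufsr /
                                std::pow(CaSR + c.Kbufsr, 2));

      // Euler updates (non-gate states)
      V += dt * (-(Iion + Istim));
      Cai += dt * bc * (-(ICaL + IbCa + IpCa - 2.0 * INaCa) * c.kCa +
                        Jrel + Jleak - Jup);
      CaSR += dt * bsr * (Jup - Jrel - Jleak) * c.vratio;
      Nai += dt * (-(INa + INaL + IbNa + 3.0 * INaCa + 3.0 * INaK + INav18) *
                   c.kNa);
      {
        // RyR availability: inactivated by cytosolic Ca, recovery gated by
        // SR refill (links SERCA function to alternans vulnerability)
        double refill = CaSR * CaSR /
                        (CaSR * CaSR + c.Krefill * c.Krefill);
        Rbar += dt * (-c.k2c * Cai * Rbar + c.k4 * (1.0 - Rbar) * refill);
      }

      // Rush-Larsen gate updates
      const int rl = fine ? C_RLF0 : C_RLC0;
      m += (TL(C_MINF) - m) * TL(rl + 0);
      h += (TL(C_HINF) - h) * TL(rl + 1);
      j += (TL(C_JINF) - j) * TL(rl + 2);
      d += (TL(C_DINF) - d) * TL(rl + 3);
      f += (TL(C_FINF) - f) * TL(rl + 4);
      r += (TL(C_RINF) - r) * TL(rl + 5);
      s += (TL(C_SINF) - s) * TL(rl + 6);
      xr1 += (TL(C_XR1INF) - xr1) * TL(rl + 7);
      xr2 += (TL(C_XR2INF) - xr2) * TL(rl + 8);
      xs += (TL(C_XSINF) - xs) * TL(rl + 9);
      hL += (TL(C_HLINF) - hL) * rlfHL[lev];
      {
        // Ca-dependent ICaL inactivation, tracking instantaneous Cai
        double ratio = Cai / c.KfCa;
        double fcainf = c.fcaFloor +
                        (1.0 - c.fcaFloor) / (1.0 + ratio * ratio);
        fca += (fcainf - fca) * rlfFca[lev];
      }
      if (gNav18 > 0.0) {
        m18 += (TL(C_M18INF) - m18) * rlfM18[lev];
        h18 += (TL(C_H18INF) - h18) * rlfH18[lev];
      }
      {
        // release refractoriness gate: inactivates while depolarized,
        // recovers slowly during diastole, so the releasable fraction is a
        // steep function of the preceding diastolic interval (the substrate
        // of calcium-transient alternans)
        if (V > -60.0) {
          grel += (0.0 - grel) * (1.0 - std::exp(-dt / c.tauGrelInact));
        } else {
          // recovery stalls while diastolic Ca remains elevated, so the
          // effective release restitution depends on SERCA function
          double cr = Cai / c.KgrelCa;
          double cr2 = cr * cr;
          double gate = 1.0 / (1.0 + cr2 * cr2);
          grel += (1.0 - grel) *
                  (1.0 - std::exp(-dt * gate / c.tauGrelRec));
        }
      }
      {
        double cah = std::pow(Cai, c.hillT);
        double finf = cah / (cah + std::pow(c.Ca50, c.hillT));
        Ften += (finf - Ften) * rlfFt[lev];
      }
      #undef TL

      // clamps & sanity
      m = clamp01(m); h = clamp01(h); j = clamp01(j); d = clamp01(d);
      f = clamp01(f); fca = clamp01(fca); r = clamp01(r); s = clamp01(s);
      xr1 = clamp01(xr1); xr2 = clamp01(xr2); xs = clamp01(xs);
      hL = clamp01(hL); m18 = clamp01(m18); h18 = clamp01(h18);
      Rbar = clamp01(Rbar); grel = clamp01(grel);
      if (Ften < 0.0) Ften = 0.0;
      if (Cai < 1e-7) Cai = 1e-7;
      if (CaSR < 1e-4) CaSR = 1e-4;
      if (Nai < 0.5) Nai = 0.5;
      if (Nai > 60.0) Nai = 60.0;
      if (!std::isfinite(V) || V < -150.0 || V > 200.0) {
        errorBeat = beat;
        break;
      }
    }
  }

  NumericVector finalState = NumericVector::create(
      V, m, h, j, hL, d, f, fca, r, s, xr1, xr2, xs, Cai, CaSR, Nai,
      Rbar, Ften, m18, h18, grel);

  List out = List::create(
      _["time"] = rT, _["V"] = rV, _["Cai"] = rCai, _["CaSR"] = rCaSR,
      _["Nai"] = rNai, _["tension"] = rF,
      _["beatStarts"] = beatStarts, _["stimTimes"] = stimTimes,
      _["finalState"] = finalState,
      _["maxAbsINa"] = maxAbsINa, _["maxAbsINav18"] = maxAbsINav18,
      _["errorBeat"] = errorBeat + 1); // 1-based; 0 = no error
  if (recordCurrents) out["currents"] = rCur;
  return out;
}
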