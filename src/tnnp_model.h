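#ifndef VTMECH_TNNP_MODEL_H
#define VTMECH_TNNP_MODEL_H
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace tnnp {

const double Ko = 5.4, Cao = 2.0, Nao = 140.0;
const double Vc = 0.016404, Vsr = 0.001094, Vss = 0.00005468;
const double Bufc = 0.2, Kbufc = 0.001, Bufsr = 10.0, Kbufsr = 0.3;
const double Bufss = 0.4, Kbufss = 0.00025;
const double Vmaxup = 0.006375, Kup = 0.00025, Vrel = 0.102;
const double k1p = 0.15, k2p = 0.045, k3 = 0.060, k4 = 0.005;
const double EC = 1.5, maxsr = 2.5, minsr = 1.0;
const double Vleak = 0.00036, Vxfer = 0.0038;
const double Rgas = 8314.472, Frdy = 96485.3415, Temp = 310.0;
const double RTONF = Rgas * Temp / Frdy;
const double CAP = 0.185;          // cell capacitance scale for flux conversion
const double pKNa = 0.03;
const double GK1 = 5.405, GNa = 14.838, GbNa = 0.00029;
const double KmK = 1.0, KmNa = 40.0, knak = 2.724;
const double GCaL = 0.00003980, GbCa = 0.000592;
const double knaca = 1000.0, KmNai = 87.5, KmCa = 1.38, ksat = 0.1, nexp = 0.35;
const double GpCa = 0.1238, KpCa = 0.0005, GpK = 0.0146, Gkr = 0.153;

struct Params {
  double gNa, gK1, gto, gKr, gKs, gCaL;
  double s_naca, s_nak, s_pca, s_pk, s_bna, s_bca; // exchanger/pump/background scales
  int variant;   // 0 epi, 1 M, 2 endo
};

inline Params params_from_list(const List& p) {
  Params P;
  int variant = as<int>(p["variant"]);
  // transmural heterogeneity enters through g_to and g_Ks
  double gks_base = as<double>(p["gKs"]);      // already the baseline for the variant
  double gto_base = as<double>(p["gto"]);
  P.variant = variant;
  P.gNa  = as<double>(p["gNa"]);
  P.gK1  = as<double>(p["gK1"]);
  P.gto  = gto_base;
  P.gKr  = as<double>(p["gKr"]);
  P.gKs  = gks_base * as<double>(p["gKs_mult"]);
  P.gCaL = as<double>(p["gCaL"]);
  P.s_naca = as<double>(p["s_naca"]); P.s_nak = as<double>(p["s_nak"]);
  P.s_pca  = as<double>(p["s_pca"]);  P.s_pk  = as<double>(p["s_pk"]);
  P.s_bna  = as<double>(p["s_bna"]);  P.s_bca = as<double>(p["s_bca"]);
  return P;
}

// One reaction step. method: 0 = Rush-Larsen gates, 1 = forward Euler gates.
inline void step(double* S, double dt, double Istim, const Params& P, int method) {
  double V = S[0];
  double m = S[1], h = S[2], j = S[3], xr1 = S[4], xr2 = S[5], xs = S[6];
  double r = S[7], s = S[8], d = S[9], f = S[10], f2 = S[11], fcass = S[12];
  double Cai = S[13], CaSR = S[14], CaSS = S[15], Rbar = S[16];
  double Nai = S[17], Ki = S[18];

  const double FVRT = V * Frdy / (Rgas * Temp);
  double Ek  = RTONF * std::log(Ko / Ki);
  double Ena = RTONF * std::log(Nao / Nai);
  double Eks = RTONF * std::log((Ko + pKNa * Nao) / (Ki + pKNa * Nai));
  double Eca = 0.5 * RTONF * std::log(Cao / Cai);

  double Ak1 = 0.1 / (1.0 + std::exp(0.06 * (V - Ek - 200.0)));
  double Bk1 = (3.0 * std::exp(0.0002 * (V - Ek + 100.0)) +
                std::exp(0.1 * (V - Ek - 10.0))) /
               (1.0 + std::exp(-0.5 * (V - Ek)));
  double IK1 = P.gK1 * Ak1 / (Ak1 + Bk1) * (V - Ek);

  double INa = P.gNa * m * m * m * h * j * (V - Ena);
  double IbNa = P.s_bna * GbNa * (V - Ena);

  double expv = std::exp(2.0 * (V - 15.0) * Frdy / (Rgas * Temp));
  double ICaL = P.gCaL * d * f * f2 * fcass * 4.0 * (V - 15.0) *
                (Frdy * Frdy / (Rgas * Temp)) *
                (0.25 * expv * CaSS - Cao) / (expv - 1.0);
  double IbCa = P.s_bca * GbCa * (V - Eca);

  double Ito = P.gto * r * s * (V - Ek);
  double IKr = P.gKr * std::sqrt(Ko / 5.4) * xr1 * xr2 * (V - Ek);
  double IKs = P.gKs * xs * xs * (V - Eks);

  double INaCa = P.s_naca * knaca * (1.0 / (KmNai * KmNai * KmNai + Nao * Nao * Nao)) *
                 (1.0 / (KmCa + Cao)) *
                 (1.0 / (1.0 + ksat * std::exp((nexp - 1.0) * FVRT))) *
                 (std::exp(nexp * FVRT) * Nai * Nai * Nai * Cao -
                  std::exp((nexp - 1.0) * FVRT) * Nao * Nao * Nao * Cai * 2.5);
  double INaK = P.s_nak * knak * (Ko / (Ko + KmK)) * (Nai / (Nai + KmNa)) /
                (1.0 + 0.1245 * std::exp(-0.1 * FVRT) + 0.0353 * std::exp(-FVRT));
  double IpCa = P.s_pca * GpCa * Cai / (KpCa + Cai);
  double IpK  = P.s_pk * GpK * (V - Ek) / (1.0 + std::exp((25.0 - V) / 5.98));

  double Itot = IK1 + Ito + IKr + IKs + ICaL + INaK + INa + IbNa + INaCa + IbCa +
                IpK + IpCa + Istim;

  // gate kinetics
  double M_INF = 1.0 / std::pow(1.0 + std::exp((-56.86 - V) / 9.03), 2.0);
  double AM = 1.0 / (1.0 + std::exp((-60.0 - V) / 5.0));
  double BM = 0.1 / (1.0 + std::exp((V + 35.0) / 5.0)) +
              0.10 / (1.0 + std::exp((V - 50.0) / 200.0));
  double TAU_M = AM * BM;
  double H_INF = 1.0 / std::pow(1.0 + std::exp((V + 71.55) / 7.43), 2.0);
  double AH, BH;
  if (V >= -40.0) { AH = 0.0; BH = 0.77 / (0.13 * (1.0 + std::exp(-(V + 10.66) / 11.1))); }
  else { AH = 0.057 * std::exp(-(V + 80.0) / 6.8);
         BH = 2.7 * std::exp(0.079 * V) + 3.1e5 * std::exp(0.3485 * V); }
  double TAU_H = 1.0 / (AH + BH);
  double J_INF = H_INF;
  double AJ, BJ;
  if (V >= -40.0) { AJ = 0.0;
    BJ = 0.6 * std::exp(0.057 * V) / (1.0 + std::exp(-0.1 * (V + 32.0))); }
  else {
    AJ = (-2.5428e4 * std::exp(0.2444 * V) - 6.948e-6 * std::exp(-0.04391 * V)) *
         (V + 37.78) / (1.0 + std::exp(0.311 * (V + 79.23)));
    BJ = 0.02424 * std::exp(-0.01052 * V) / (1.0 + std::exp(-0.1378 * (V + 40.14)));
  }
  double TAU_J = 1.0 / (AJ + BJ);
  double Xr1_INF = 1.0 / (1.0 + std::exp((-26.0 - V) / 7.0));
  double TAU_Xr1 = 450.0 / (1.0 + std::exp((-45.0 - V) / 10.0)) *
                   6.0 / (1.0 + std::exp((V + 30.0) / 11.5));
  double Xr2_INF = 1.0 / (1.0 + std::exp((V + 88.0) / 24.0));
  double TAU_Xr2 = 3.0 / (1.0 + std::exp((-60.0 - V) / 20.0)) *
                   1.12 / (1.0 + std::exp((V - 60.0) / 20.0));
  double Xs_INF = 1.0 / (1.0 + std::exp((-5.0 - V) / 14.0));
  double TAU_Xs = 1400.0 / std::sqrt(1.0 + std::exp((5.0 - V) / 6.0)) *
                  1.0 / (1.0 + std::exp((V - 35.0) / 15.0)) + 80.0;
  double R_INF = 1.0 / (1.0 + std::exp((20.0 - V) / 6.0));
  double TAU_R = 9.5 * std::exp(-(V + 40.0) * (V + 40.0) / 1800.0) + 0.8;
  double S_INF, TAU_S;
  if (P.variant == 2) {  // endo
    S_INF = 1.0 / (1.0 + std::exp((V + 28.0) / 5.0));
    TAU_S = 1000.0 * std::exp(-(V + 67.0) * (V + 67.0) / 1000.0) + 8.0;
  } else {
    S_INF = 1.0 / (1.0 + std::exp((V + 20.0) / 5.0));
    TAU_S = 85.0 * std::exp(-(V + 45.0) * (V + 45.0) / 320.0) +
            5.0 / (1.0 + std::exp((V - 20.0) / 5.0)) + 3.0;
  }
  double D_INF = 1.0 / (1.0 + std::exp((-8.0 - V) / 7.5));
  double TAU_D = (1.4 / (1.0 + std::exp((-35.0 - V) / 13.0)) + 0.25) *
                 1.4 / (1.0 + std::exp((V + 5.0) / 5.0)) +
                 1.0 / (1.0 + std::exp((50.0 - V) / 20.0));
  double F_INF = 1.0 / (1.0 + std::exp((V + 20.0) / 7.0));
  double TAU_F = 1102.5 * std::exp(-(V + 27.0) * (V + 27.0) / 225.0) +
                 200.0 / (1.0 + std::exp((13.0 - V) / 10.0)) +
                 180.0 / (1.0 + std::exp((V + 30.0) / 10.0)) + 20.0;
  double F2_INF = 0.67 / (1.0 + std::exp((V + 35.0) / 7.0)) + 0.33;
  double TAU_F2 = 600.0 * std::exp(-(V + 25.0) * (V + 25.0) / 170.0) +
                  31.0 / (1.0 + std::exp((25.0 - V) / 10.0)) +
                  16.0 / (1.0 + std::exp((V + 30.0) / 10.0));
  double FCaSS_INF = 0.6 / (1.0 + (CaSS / 0.05) * (CaSS / 0.05)) + 0.4;
  double TAU_FCaSS = 80.0 / (1.0 + (CaSS / 0.05) * (CaSS / 0.05)) + 2.0;

  if (method == 0) {  // Rush-Larsen: exact exponential update toward steady state
    S[1] = M_INF - (M_INF - m) * std::exp(-dt / TAU_M);
    S[2] = H_INF - (H_INF - h) * std::exp(-dt / TAU_H);
    S[3] = J_INF - (J_INF - j) * std::exp(-dt / TAU_J);
    S[4] = Xr1_INF - (Xr1_INF - xr1) * std::exp(-dt / TAU_Xr1);
    S[5] = Xr2_INF - (Xr2_INF - xr2) * std::exp(-dt / TAU_Xr2);
    S[6] = Xs_INF - (Xs_INF - xs) * std::exp(-dt / TAU_Xs);
    S[7] = R_INF - (R_INF - r) * std::exp(-dt / TAU_R);
    S[8] = S_INF - (S_INF - s) * std::exp(-dt / TAU_S);
    S[9] = D_INF - (D_INF - d) * std::exp(-dt / TAU_D);
    S[10] = F_INF - (F_INF - f) * std::exp(-dt / TAU_F);
    S[11] = F2_INF - (F2_INF - f2) * std::exp(-dt / TAU_F2);
    S[12] = FCaSS_INF - (FCaSS_INF - fcass) * std::exp(-dt / TAU_FCaSS);
  } else {
    S[1] = m + dt * (M_INF - m) / TAU_M;
    S[2] = h + dt * (H_INF - h) / TAU_H;
    S[3] = j + dt * (J_INF - j) / TAU_J;
    S[4] = xr1 + dt * (Xr1_INF - xr1) / TAU_Xr1;
    S[5] = xr2 + dt * (Xr2_INF - xr2) / TAU_Xr2;
    S[6] = xs + dt * (Xs_INF - xs) / TAU_Xs;
    S[7] = r + dt * (R_INF - r) / TAU_R;
    S[8] = s + dt * (S_INF - s) / TAU_S;
    S[9] = d + dt * (D_INF - d) / TAU_D;
    S[10] = f + dt * (F_INF - f) / TAU_F;
    S[11] = f2 + dt * (F2_INF - f2) / TAU_F2;
    S[12] = fcass + dt * (FCaSS_INF - fcass) / TAU_FCaSS;
  }

  // calcium subsystem (total-calcium balance with instantaneous buffering)
  double kCaSR = maxsr - (maxsr - minsr) / (1.0 + (EC / CaSR) * (EC / CaSR));
  double k1 = k1p / kCaSR, k2 = k2p * kCaSR;
  S[16] = Rbar + dt * (k4 * (1.0 - Rbar) - k2 * CaSS * Rbar);
  double sOO = k1 * CaSS * CaSS * Rbar / (k3 + k1 * CaSS * CaSS);
  double Irel = Vrel * sOO * (CaSR - CaSS);
  double Ileak = Vleak * (CaSR - Cai);
  double Iup = Vmaxup / (1.0 + (Kup * Kup) / (Cai * Cai));
  double Ixfer = Vxfer * (CaSS - Cai);

  double CaCSQN = Bufsr * CaSR / (CaSR + Kbufsr);
  double dCaSR = dt * (Iup - Irel - Ileak);
  double bjsr = Bufsr - CaCSQN - dCaSR - CaSR + Kbufsr;
  double cjsr = Kbufsr * (CaCSQN + dCaSR + CaSR);
  S[14] = (std::sqrt(bjsr * bjsr + 4.0 * cjsr) - bjsr) / 2.0;

  double CaSSBuf = Bufss * CaSS / (CaSS + Kbufss);
  double dCaSS = dt * (-Ixfer * (Vc / Vss) + Irel * (Vsr / Vss) -
                       ICaL * CAP / (2.0 * Vss * Frdy));
  double bcss = Bufss - CaSSBuf - dCaSS - CaSS + Kbufss;
  double ccss = Kbufss * (CaSSBuf + dCaSS + CaSS);
  S[15] = (std::sqrt(bcss * bcss + 4.0 * ccss) - bcss) / 2.0;

  double CaBuf = Bufc * Cai / (Cai + Kbufc);
  double dCai = dt * (-(IbCa + IpCa - 2.0 * INaCa) * CAP / (2.0 * Vc * Frdy) -
                      (Iup - Ileak) * (Vsr / Vc) + Ixfer);
  double bc = Bufc - CaBuf - dCai - Cai + Kbufc;
  double cc = Kbufc * (CaBuf + dCai + Cai);
  S[13] = (std::sqrt(bc * bc + 4.0 * cc) - bc) / 2.0;

  S[17] = Nai + dt * (-(INa + IbNa + 3.0 * INaK + 3.0 * INaCa) * CAP / (Vc * Frdy));
  S[18] = Ki + dt * (-(Istim + IK1 + Ito + IKr + IKs - 2.0 * INaK + IpK) *
                     CAP / (Vc * Frdy));
  S[0] = V - dt * Itot;
}

} // namespace tnnp
#endif
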