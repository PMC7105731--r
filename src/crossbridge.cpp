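// Reduced four-state cross-bridge chain driven by the calcium transient:
//   N_xb <-> P_xb <-> XB_PreR <-> XB_PostR
// with regulatory rates K_np * TCa_Tot^7.5 (forward) and K_pn * TCa_Tot^-7.5
// (backward), where TCa_Tot is the troponin-bound calcium fraction from a
// single-site binding ODE. Active tension T = T_max * (XB_PreR + XB_PostR).
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// ca: frames x nodes calcium movie (mM); times in ms (uniform).
// Occupancies are renormalized to sum to 1 every sub-step.
// [[Rcpp::export]]
NumericMatrix cpp_crossbridge(NumericMatrix ca, NumericVector times, List params) {
  const int nt = ca.nrow(), nn = ca.ncol();
  if (nt < 2) stop("calcium movie needs at least 2 frames");
  const double kon = as<double>(params["kon"]);      // 1/(mM*ms)
  const double koff = as<double>(params["koff"]);    // 1/ms
  const double Knp = as<double>(params["Knp"]);      // 1/ms
  const double Kpn = as<double>(params["Kpn"]);      // 1/ms
  const double coop = as<double>(params["coop"]);    // cooperativity exponent (7.5)
  const double f_aapT = as<double>(params["f_aapT"]);
  const double g_aapT = as<double>(params["g_aapT"]);
  const double h_fT = as<double>(params["h_fT"]);
  const double h_bT = as<double>(params["h_bT"]);
  const double g_xbT = as<double>(params["g_xbT"]);
  const double Tmax = as<double>(params["Tmax"]);    // kPa
  const double dt = as<double>(params["dt"]);        // sub-step, ms
  const double tca_floor = as<double>(params["tca_floor"]);
  const double rate_cap = 0.5 / dt;                  // explicit-step safety cap

  NumericMatrix tension(nt, nn);
  for (int j = 0; j < nn; ++j) {
    double TCa = 0.0, N = 1.0, P = 0.0, XBpre = 0.0, XBpost = 0.0;
    tension(0, j) = 0.0;
    for (int f = 0; f < nt - 1; ++f) {
      double span = times[f + 1] - times[f];
      int nsub = std::max(1, (int)std::llround(span / dt));
      double dts = span / nsub;
      double c0 = ca(f, j), c1 = ca(f + 1, j);
      if (c0 < 0 || c1 < 0) stop("negative calcium input at frame %d", f + 1);
      for (int s = 0; s < nsub; ++s) {
        double cai = c0 + (c1 - c0) * ((s + 0.5) / nsub);
        TCa += dts * (kon * cai * (1.0 - TCa) - koff * TCa);
        if (TCa < 0) TCa = 0; else if (TCa > 1) TCa = 1;
        double tca = std::max(TCa, tca_floor);
        double knp = std::min(Knp * std::pow(tca, coop), rate_cap);
        double kpn = std::min(Kpn * std::pow(tca, -coop), rate_cap);
        double dN = kpn * P - knp * N;
        double dP = knp * N + g_aapT * XBpre + g_xbT * XBpost -
                    (kpn + f_aapT) * P;
        double dPre = f_aapT * P + h_bT * XBpost - (g_aapT + h_fT) * XBpre;
        double dPost = h_fT * XBpre - (h_bT + g_xbT) * XBpost;
        N += dts * dN; P += dts * dP; XBpre += dts * dPre; XBpost += dts * dPost;
        if (N < 0) N = 0; if (P < 0) P = 0;
        if (XBpre < 0) XBpre = 0; if (XBpost < 0) XBpost = 0;
        double tot = N + P + XBpre + XBpost;
        N /= tot; P /= tot; XBpre /= tot; XBpost /= tot;
      }
      tension(f + 1, j) = Tmax * (XBpre + XBpost);
    }
  }
  return tension;
}
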