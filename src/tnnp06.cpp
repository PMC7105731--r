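// Detailed human ventricular myocyte kinetics (ten Tusscher-Panfilov 2006 class),
// epicardial / mid-myocardial / endocardial variants, with a multiplier on the
// slow delayed-rectifier conductance g_Ks. State layout (19 variables):
//  0 V, 1 m, 2 h, 3 j, 4 xr1, 5 xr2, 6 xs, 7 r, 8 s, 9 d, 10 f, 11 f2,
// 12 fcass, 13 Cai, 14 CaSR, 15 CaSS, 16 Rbar, 17 Nai, 18 Ki
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

#include "tnnp_model.h"


// [[Rcpp::export]]
NumericVector cpp_tnnp_init() {
  NumericVector s = NumericVector::create(
    -86.2, 0.0, 0.75, 0.75, 0.0, 1.0, 0.0, 0.0, 1.0, 0.0,
    1.0, 1.0, 1.0, 0.00007, 1.3, 0.00007, 1.0, 7.67, 138.3);
  return s;
}

static void check_finite(const double* S, double t) {
  static const char* nm[19] = {"V", "m", "h", "j", "xr1", "xr2", "xs", "r", "s",
                               "d", "f", "f2", "fcass", "Cai", "CaSR", "CaSS",
                               "Rbar", "Nai", "Ki"};
  for (int k = 0; k < 19; ++k)
    if (!R_finite(S[k]))
      stop("integration failure: state variable '%s' became non-finite at t = %g ms",
           nm[k], t);
}

// Paced (or unpaced) run of the detailed model.
// stim_times: onset of each stimulus (ms); recording every record_dt ms.
// [[Rcpp::export]]
List cpp_tnnp_run(NumericVector state0, List params, double duration, double dt,
                  NumericVector stim_times, double stim_dur, double stim_amp,
                  double record_dt, int method = 0, bool freeze_fluxes = false) {
  tnnp::Params P = tnnp::params_from_list(params);
  double S[19];
  for (int k = 0; k < 19; ++k) S[k] = state0[k];
  int nstep = (int)std::llround(duration / dt);
  int rec_every = std::max(1, (int)std::llround(record_dt / dt));
  int nrec = nstep / rec_every + 1;
  NumericVector tv(nrec), vm(nrec), cai(nrec);
  tv[0] = 0.0; vm[0] = S[0]; cai[0] = S[13];
  int ir = 1;
  int ns = stim_times.size();
  // freeze_fluxes: zero every transmembrane Ca pathway (pumps, exchanger,
  // background, L-type) so that total cell calcium is an exact invariant
  if (freeze_fluxes) {
    P.s_naca = P.s_nak = P.s_pca = P.s_pk = P.s_bna = P.s_bca = 0.0;
    P.gCaL = 0.0;
  }
  for (int i = 0; i < nstep; ++i) {
    double t = i * dt;
    double Istim = 0.0;
    for (int q = 0; q < ns; ++q)
      if (t >= stim_times[q] && t < stim_times[q] + stim_dur) { Istim = stim_amp; break; }
    tnnp::step(S, dt, Istim, P, method);
    if ((i + 1) % rec_every == 0 && ir < nrec) {
      tv[ir] = (i + 1) * dt; vm[ir] = S[0]; cai[ir] = S[13]; ++ir;
    }
    if ((i & 1023) == 0) check_finite(S, t);
  }
  check_finite(S, duration);
  NumericVector sf(19);
  for (int k = 0; k < 19; ++k) sf[k] = S[k];
  return List::create(_["time"] = tv, _["vm"] = vm, _["cai"] = cai,
                      _["state"] = sf);
}
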