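// Three-variable phenomenological excitable model for large tissue runs:
// a two-current (fast inward / slow outward) membrane with one recovery gate,
// plus a first-order calcium-release proxy that drives the cross-bridge
// surrogate. APD is controlled monotonically by tau_close (scaled by
// tau_scale, the repolarization knob mapped from the g_Ks multiplier).
// State layout (3 variables): 0 Vm (mV), 1 hgate (recovery, [0,1]),
// 2 casig (normalized release signal, [0,1]).
#ifndef VTMECH_FK_MODEL_H
#define VTMECH_FK_MODEL_H
#include <cmath>

namespace fkm {

struct Params {
  double tau_in, tau_out, tau_open, tau_close;
  double u_gate;
  double tau_scale;            // scales tau_close: the APD control knob
  double tau_ca_on, tau_ca_off;
  double v_rest, v_amp;        // map u in [0,1] to Vm = v_rest + v_amp * u
};

inline void init_state(double* S, const Params& P) {
  S[0] = P.v_rest; S[1] = 1.0; S[2] = 0.0;
}

inline void step(double* S, double dt, double Istim, const Params& P) {
  double u = (S[0] - P.v_rest) / P.v_amp;
  double hg = S[1], s = S[2];
  double du = hg * u * u * (1.0 - u) / P.tau_in - u / P.tau_out;
  bool exc = u >= P.u_gate;
  double dh = exc ? -hg / (P.tau_close * P.tau_scale) : (1.0 - hg) / P.tau_open;
  S[0] += dt * (du * P.v_amp - Istim);
  S[1] = hg + dt * dh;
  if (S[1] < 0.0) S[1] = 0.0; else if (S[1] > 1.0) S[1] = 1.0;
  S[2] = s + dt * (exc ? (1.0 - s) / P.tau_ca_on : -s / P.tau_ca_off);
}

} // namespace fkm
#endif
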