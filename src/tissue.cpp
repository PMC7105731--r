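// Monodomain reaction-diffusion engine on regular 2D sheets / 3D slabs with
// no-flux boundaries. Operator splitting: reaction (cell model) then explicit
// central-difference diffusion of Vm. Supports the reduced (kind 0) and the
// detailed (kind 1) cell model, timed stimuli over node sets, and an
// auto-triggered S2 that fires when the monitor node repolarizes below a
// threshold after the last S1 upstroke.
#include <Rcpp.h>
#include <cmath>
#include <vector>
#include "tnnp_model.h"
#include "fk_model.h"
using namespace Rcpp;

static fkm::Params fk_params_from_list(const List& p) {
  fkm::Params P;
  P.tau_in = as<double>(p["tau_in"]);     P.tau_out = as<double>(p["tau_out"]);
  P.tau_open = as<double>(p["tau_open"]); P.tau_close = as<double>(p["tau_close"]);
  P.u_gate = as<double>(p["u_gate"]);
  P.tau_scale = as<double>(p["tau_scale"]);
  P.tau_ca_on = as<double>(p["tau_ca_on"]);
  P.tau_ca_off = as<double>(p["tau_ca_off"]);
  P.v_rest = as<double>(p["v_rest"]); P.v_amp = as<double>(p["v_amp"]);
  return P;
}

// [[Rcpp::export]]
NumericVector cpp_fk_init(List params) {
  fkm::Params P = fk_params_from_list(params);
  NumericVector s(3);
  double S[3]; fkm::init_state(S, P);
  for (int k = 0; k < 3; ++k) s[k] = S[k];
  return s;
}

// Single-cell run of the reduced model (mirror of cpp_tnnp_run).
// [[Rcpp::export]]
List cpp_fk_run(NumericVector state0, List params, double duration, double dt,
                NumericVector stim_times, double stim_dur, double stim_amp,
                double record_dt, double ca0, double ca_amp) {
  fkm::Params P = fk_params_from_list(params);
  double S[3];
  for (int k = 0; k < 3; ++k) S[k] = state0[k];
  int nstep = (int)std::llround(duration / dt);
  int rec_every = std::max(1, (int)std::llround(record_dt / dt));
  int nrec = nstep / rec_every + 1;
  NumericVector tv(nrec), vm(nrec), cai(nrec);
  tv[0] = 0.0; vm[0] = S[0]; cai[0] = ca0 + ca_amp * S[2];
  int ir = 1, ns = stim_times.size();
  for (int i = 0; i < nstep; ++i) {
    double t = i * dt, Istim = 0.0;
    for (int q = 0; q < ns; ++q)
      if (t >= stim_times[q] && t < stim_times[q] + stim_dur) { Istim = stim_amp; break; }
    fkm::step(S, dt, Istim, P);
    if ((i + 1) % rec_every == 0 && ir < nrec) {
      tv[ir] = (i + 1) * dt; vm[ir] = S[0]; cai[ir] = ca0 + ca_amp * S[2]; ++ir;
    }
  }
  NumericVector sf(3);
  for (int k = 0; k < 3; ++k) sf[k] = S[k];
  return List::create(_["time"] = tv, _["vm"] = vm, _["cai"] = cai, _["state"] = sf);
}

// Full monodomain run.
//   state0   : nvar x nnode matrix (nvar 4 or 19)
//   stimuli  : list of list(nodes = 0-based ints, start, dur, amp)
//   s2auto   : NULL or list(nodes, amp, dur, monitor (0-based), threshold,
//              after_upstrokes) - fires once
// Returns frames of Vm and Cai at frame_dt cadence, final state (checkpoint),
// and the S2 firing time (NA if never fired).
// [[Rcpp::export]]
List cpp_tissue_run(int kind, NumericMatrix state0, List params,
                    IntegerVector dims, double h, NumericVector D,
                    LogicalVector mask, List stimuli, Nullable<List> s2auto,
                    double duration, double dt, double frame_dt,
                    bool ionic_off = false, double t0 = 0.0) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int nnode = nx * ny * nz;
  const int nvar = state0.nrow();
  if (state0.ncol() != nnode) stop("checkpoint/grid shape mismatch: state has %d nodes, grid has %d", state0.ncol(), nnode);
  const double h2 = h * h;
  const double Dx = D[0], Dy = D[1], Dz = D[2];
  // explicit diffusion stability
  double lam = 2.0 * dt * (Dx + Dy + (nz > 1 ? Dz : 0.0)) / h2;
  if (lam > 1.0)
    stop("explicit diffusion unstable: dt = %g ms exceeds h^2/(2*dim*D)", dt);

  tnnp::Params PT; fkm::Params PF;
  if (kind == 1) PT = tnnp::params_from_list(params); else PF = fk_params_from_list(params);
  double ca0 = 0.0, ca_amp = 1.0;
  if (kind == 0) { ca0 = as<double>(params["ca0"]); ca_amp = as<double>(params["ca_amp"]); }

  // neighbor tables with no-flux closure (self-reference outside domain/mask)
  std::vector<int> nb(6 * nnode);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int i = x + nx * (y + ny * z);
        int xm = (x > 0) ? i - 1 : i, xp = (x < nx - 1) ? i + 1 : i;
        int ym = (y > 0) ? i - nx : i, yp = (y < ny - 1) ? i + nx : i;
        int zm = (z > 0) ? i - nx * ny : i, zp = (z < nz - 1) ? i + nx * ny : i;
        if (!mask[xm]) xm = i; if (!mask[xp]) xp = i;
        if (!mask[ym]) ym = i; if (!mask[yp]) yp = i;
        if (!mask[zm]) zm = i; if (!mask[zp]) zp = i;
        nb[6 * i] = xm; nb[6 * i + 1] = xp; nb[6 * i + 2] = ym;
        nb[6 * i + 3] = yp; nb[6 * i + 4] = zm; nb[6 * i + 5] = zp;
      }

  std::vector<double> S(state0.begin(), state0.end()); // column-major: node i at S[nvar*i]
  std::vector<double> V(nnode), Vnew(nnode);

  // stimulus bookkeeping
  int nstim = stimuli.size();
  std::vector<std::vector<int>> stim_nodes(nstim);
  std::vector<double> stim_t0(nstim), stim_dur(nstim), stim_amp(nstim);
  for (int q = 0; q < nstim; ++q) {
    List st = stimuli[q];
    IntegerVector nd = st["nodes"];
    stim_nodes[q] = std::vector<int>(nd.begin(), nd.end());
    stim_t0[q] = as<double>(st["start"]);
    stim_dur[q] = as<double>(st["dur"]);
    stim_amp[q] = as<double>(st["amp"]);
  }
  bool has_s2 = s2auto.isNotNull();
  std::vector<int> s2_nodes; double s2_amp = 0, s2_dur = 0, s2_thresh = -70;
  int s2_monitor = 0, s2_after = 3;
  double s2_time = NA_REAL; bool s2_armed = false, s2_fired = false;
  int upstrokes = 0; double vmon_prev = 0.0;
  if (has_s2) {
    List s2(s2auto);
    IntegerVector nd = s2["nodes"];
    s2_nodes = std::vector<int>(nd.begin(), nd.end());
    s2_amp = as<double>(s2["amp"]); s2_dur = as<double>(s2["dur"]);
    s2_monitor = as<int>(s2["monitor"]); s2_thresh = as<double>(s2["threshold"]);
    s2_after = as<int>(s2["after_upstrokes"]);
    vmon_prev = S[(size_t)nvar * s2_monitor];
  }

  const int nstep = (int)std::llround(duration / dt);
  const int rec_every = std::max(1, (int)std::llround(frame_dt / dt));
  const int nrec = nstep / rec_every + 1;
  NumericMatrix frames_v(nrec, nnode), frames_ca(nrec, nnode);
  NumericVector times(nrec);
  auto record = [&](int ir, double t) {
    times[ir] = t;
    for (int i = 0; i < nnode; ++i) {
      const double* Si = &S[(size_t)nvar * i];
      frames_v(ir, i) = Si[0];
      frames_ca(ir, i) = (kind == 1) ? Si[13] : ca0 + ca_amp * Si[2];
    }
  };
  record(0, t0);
  int ir = 1;

  std::vector<double> Istim(nnode, 0.0);
  for (int step = 0; step < nstep; ++step) {
    double t = t0 + step * dt;
    // assemble stimulus currents for this step
    bool any = false;
    std::fill(Istim.begin(), Istim.end(), 0.0);
    for (int q = 0; q < nstim; ++q)
      if (t >= stim_t0[q] && t < stim_t0[q] + stim_dur[q]) {
        for (int idx : stim_nodes[q]) Istim[idx] += stim_amp[q];
        any = true;
      }
    if (s2_fired && t >= s2_time && t < s2_time + s2_dur) {
      for (int idx : s2_nodes) Istim[idx] += s2_amp;
      any = true;
    }
    (void)any;

    if (!ionic_off) {
      if (kind == 1) {
        for (int i = 0; i < nnode; ++i)
          if (mask[i]) tnnp::step(&S[(size_t)nvar * i], dt, Istim[i], PT, 0);
      } else {
        for (int i = 0; i < nnode; ++i)
          if (mask[i]) fkm::step(&S[(size_t)nvar * i], dt, Istim[i], PF);
      }
    } else {
      // with ionic currents disabled the stimulus still enters as -Istim
      for (int i = 0; i < nnode; ++i)
        if (mask[i] && Istim[i] != 0.0) S[(size_t)nvar * i] -= dt * Istim[i];
    }

    // diffusion of Vm
    for (int i = 0; i < nnode; ++i) V[i] = S[(size_t)nvar * i];
    for (int i = 0; i < nnode; ++i) {
      if (!mask[i]) { Vnew[i] = V[i]; continue; }
      const int* n6 = &nb[6 * i];
      double lap = Dx * (V[n6[0]] + V[n6[1]] - 2.0 * V[i]) +
                   Dy * (V[n6[2]] + V[n6[3]] - 2.0 * V[i]);
      if (nz > 1) lap += Dz * (V[n6[4]] + V[n6[5]] - 2.0 * V[i]);
      Vnew[i] = V[i] + dt * lap / h2;
    }
    for (int i = 0; i < nnode; ++i) S[(size_t)nvar * i] = Vnew[i];

    // S2 trigger: after the required number of S1 upstrokes at the monitor
    // node, fire the moment it repolarizes below threshold
    if (has_s2 && !s2_fired) {
      double vm = S[(size_t)nvar * s2_monitor];
      if (vmon_prev < -40.0 && vm >= -40.0) {
        ++upstrokes;
        if (upstrokes >= s2_after) s2_armed = true;
      }
      if (s2_armed && vm < s2_thresh) { s2_fired = true; s2_time = t + dt; }
      vmon_prev = vm;
    }

    if ((step + 1) % rec_every == 0 && ir < nrec) record(ir++, t0 + (step + 1) * dt);
    if ((step & 255) == 0) {
      double v0 = S[0];
      if (!R_finite(v0)) stop("integration failure: non-finite Vm at t = %g ms", t);
    }
  }

  NumericMatrix sf(nvar, nnode);
  std::copy(S.begin(), S.end(), sf.begin());
  return List::create(_["times"] = times, _["frames_v"] = frames_v,
                      _["frames_ca"] = frames_ca, _["state"] = sf,
                      _["s2_time"] = s2_time);
}
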