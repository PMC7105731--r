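## Cell-level electrophysiology: the detailed human ventricular myocyte model
## (19-state, transmural variants, g_Ks multiplier) and the reduced 3-variable
## excitable model used for large tissue runs; pacing and APD90 measurement.

#' The g_Ks multiplier ladder used for the tachyarrhythmia grid
#'
#' Conductance of the slow delayed-rectifier potassium current is scaled by
#' these factors from its baseline (0.392 x 1.3 mS/uF) to span conditions from
#' normal repolarization to extreme APD shortening.
#' @export
gks_grid <- function() c(1, 2, 4, 6, 8, 10, 20, 30, 40, 60, 80, 100)

#' Cell model parameters
#'
#' Builds the parameter set for either the detailed human ventricular myocyte
#' model (`"detailed"`) or the reduced 3-variable phenomenological model
#' (`"reduced"`). The detailed model carries the full conductance inventory
#' (I_Na, I_K1, I_to, I_Kr, I_Ks, I_CaL plus exchanger/pump/background scale
#' factors) with transmural heterogeneity in g_to and g_Ks; `gKs_mult` scales
#' g_Ks from its baseline of 0.392 x 1.3 mS/uF (epi/endo; the mid-myocardial
#' baseline is 0.098 x 1.3). The reduced model maps `gKs_mult` onto its
#' repolarization time scale so that its APD90 spans roughly 250 ms (x1) down
#' to 74 ms (x100) — the range observed across the multiplier ladder.
#'
#' @param model `"detailed"` or `"reduced"`.
#' @param variant transmural variant, `"epi"`, `"M"` or `"endo"` (detailed
#'   model only; heterogeneity enters through g_to and g_Ks).
#' @param gKs_mult positive multiplier on the baseline g_Ks.
#' @param stim_amp stimulus current amplitude (uA/uF; negative depolarizes).
#' @param stim_dur stimulus duration (ms).
#' @param dt default integration step (ms): 0.02 detailed, 0.1 reduced.
#' @param ... overrides for any named parameter (absolute values win).
#' @return an object of class `cell_params`.
#' @export
cell_params <- function(model = c("detailed", "reduced"),
                        variant = c("epi", "M", "endo"),
                        gKs_mult = 1, stim_amp = -52, stim_dur = 1,
                        dt = NULL, ...) {
  model <- match.arg(model)
  variant <- match.arg(variant)
  if (!is.numeric(gKs_mult) || length(gKs_mult) != 1 || gKs_mult <= 0)
    stop("gKs_mult must be a single positive number")
  if (model == "detailed") {
    gks_base <- if (variant == "M") 0.098 * 1.3 else 0.392 * 1.3
    gto_base <- if (variant == "endo") 0.073 else 0.294
    p <- list(
      model = "detailed", variant = variant,
      C_m = 2.0,                     # uF/cm^2, monodomain surface capacitance
      gNa = 14.838, gK1 = 5.405, gto = gto_base, gKr = 0.153,
      gKs = gks_base, gCaL = 3.98e-5,
      s_naca = 1, s_nak = 1, s_pca = 1, s_pk = 1, s_bna = 1, s_bca = 1,
      gKs_mult = gKs_mult,
      stim_amp = stim_amp, stim_dur = stim_dur,
      dt = if (is.null(dt)) 0.02 else dt)
  } else {
    p <- list(
      model = "reduced", variant = variant,
      # fast-inward / slow-outward membrane with one recovery gate (ms)
      tau_in = 0.3, tau_out = 6, tau_open = 120, tau_close = 150,
      u_gate = 0.13,
      tau_scale = reduced_tau_scale(gKs_mult),
      tau_ca_on = 15, tau_ca_off = 60,     # calcium-release proxy (ms)
      ca0 = 1e-4, ca_amp = 1e-3,           # mM: diastolic level and amplitude
      v_rest = -86, v_amp = 120,
      gKs_mult = gKs_mult,
      stim_amp = stim_amp, stim_dur = stim_dur,
      dt = if (is.null(dt)) 0.1 else dt)
  }
  over <- list(...)
  bad <- setdiff(names(over), names(p))
  if (length(bad)) stop("unknown cell parameter(s): ", paste(bad, collapse = ", "))
  p[names(over)] <- over
  if (p$model == "detailed") {
    g <- unlist(p[c("gNa", "gK1", "gto", "gKr", "gKs", "gCaL")])
    if (any(g < 0)) stop("all conductances must be >= 0")
  }
  structure(p, class = "cell_params")
}

# Maps the g_Ks multiplier onto the reduced model's repolarization scale.
# Power law calibrated once against single-cell APD90 of the reduced model so
# that APD90(x1) ~ 250 ms and APD90(x100) ~ 74 ms.
reduced_tau_scale <- function(gKs_mult) {
  .red_tau_s1 * gKs_mult^(-.red_tau_alpha)
}
.red_tau_s1 <- 0.884
.red_tau_alpha <- 0.326

#' @export
print.cell_params <- function(x, ...) {
  cat("<cell_params>", x$model, "model")
  if (x$model == "detailed") cat(",", x$variant, "variant")
  cat(", gKs_mult =", x$gKs_mult, "\n")
  invisible(x)
}

.tnnp_clist <- function(p) {
  list(variant = switch(p$variant, epi = 0L, M = 1L, endo = 2L),
       gNa = p$gNa, gK1 = p$gK1, gto = p$gto, gKr = p$gKr, gKs = p$gKs,
       gCaL = p$gCaL, s_naca = p$s_naca, s_nak = p$s_nak, s_pca = p$s_pca,
       s_pk = p$s_pk, s_bna = p$s_bna, s_bca = p$s_bca, gKs_mult = p$gKs_mult)
}
.fk_clist <- function(p) {
  p[c("tau_in", "tau_out", "tau_open", "tau_close", "u_gate", "tau_scale",
      "tau_ca_on", "tau_ca_off", "ca0", "ca_amp", "v_rest", "v_amp")]
}

#' Resting initial state for a cell model
#' @param params a [cell_params()] object.
#' @return numeric state vector (19 variables detailed, 4 reduced).
#' @export
cell_state_init <- function(params) {
  if (params$model == "detailed") cpp_tnnp_init() else cpp_fk_init(.fk_clist(params))
}

#' Advance a cell state by one or more ionic steps
#'
#' Integrates the membrane and calcium balance equations for `n` steps of
#' length `dt` under a constant stimulus current. Gating variables of the
#' detailed model use Rush-Larsen exponential updates; `method = "euler"`
#' switches to forward Euler (used as an independent integration oracle; needs
#' dt <= 0.001 ms for the sodium activation gate).
#'
#' @param state numeric state vector from [cell_state_init()] or a previous call.
#' @param params [cell_params()].
#' @param dt step (ms); detailed model requires dt in (0, 0.1].
#' @param n number of steps.
#' @param istim stimulus current held during the whole span (uA/uF).
#' @param method `"rush-larsen"` (default) or `"euler"` (detailed model only).
#' @param freeze_ca_fluxes zero all transmembrane calcium pathways (detailed
#'   model) so total cell calcium is conserved; used for bookkeeping checks.
#' @return advanced state vector.
#' @export
step_ionic <- function(state, params, dt, n = 1, istim = 0,
                       method = c("rush-larsen", "euler"),
                       freeze_ca_fluxes = FALSE) {
  method <- match.arg(method)
  if (params$model == "detailed") {
    if (dt <= 0 || dt > 0.1) stop("detailed model requires dt in (0, 0.1] ms")
    r <- cpp_tnnp_run(state, .tnnp_clist(params), n * dt, dt,
                      if (istim != 0) 0 else numeric(0), n * dt, istim,
                      n * dt, method = if (method == "euler") 1L else 0L,
                      freeze_fluxes = freeze_ca_fluxes)
  } else {
    r <- cpp_fk_run(state, .fk_clist(params), n * dt, dt,
                    if (istim != 0) 0 else numeric(0), n * dt, istim,
                    n * dt, params$ca0, params$ca_amp)
  }
  r$state
}

#' Pace a single cell and record the action potential trace
#'
#' Applies `n_beats` stimuli at cycle length `bcl` and records membrane
#' potential and cytosolic calcium.
#'
#' @param params [cell_params()].
#' @param bcl basic cycle length (ms), >= 200.
#' @param n_beats number of paced beats, >= 1.
#' @param record_dt output sampling interval (ms).
#' @param dt integration step override (ms).
#' @return an `ap_trace`: list with `time`, `vm`, `cai`, `bcl` and the final
#'   model state in attribute `"state"`.
#' @export
run_paced <- function(params, bcl, n_beats, record_dt = 0.5, dt = NULL) {
  if (bcl < 200) stop("bcl must be >= 200 ms")
  if (n_beats < 1) stop("n_beats must be >= 1")
  dt <- if (is.null(dt)) params$dt else dt
  stim_times <- seq(0, by = bcl, length.out = n_beats)
  s0 <- cell_state_init(params)
  if (params$model == "detailed") {
    r <- cpp_tnnp_run(s0, .tnnp_clist(params), n_beats * bcl, dt, stim_times,
                      params$stim_dur, params$stim_amp, record_dt)
  } else {
    r <- cpp_fk_run(s0, .fk_clist(params), n_beats * bcl, dt, stim_times,
                    params$stim_dur, params$stim_amp, record_dt,
                    params$ca0, params$ca_amp)
  }
  ups <- detect_upstrokes(r$time, r$vm)
  if (length(ups) < 1)
    stop("no capture: no upstroke detected after stimulus")
  structure(list(time = r$time, vm = r$vm, cai = r$cai, bcl = bcl),
            state = r$state, n_upstrokes = length(ups), class = "ap_trace")
}

#' @export
print.ap_trace <- function(x, ...) {
  cat("<ap_trace> ", length(x$time), " samples over ", max(x$time), " ms, bcl ",
      x$bcl %||% NA, " ms, ", attr(x, "n_upstrokes") %||% "?", " upstrokes\n",
      sep = "")
  invisible(x)
}

#' @export
plot.ap_trace <- function(x, ...) {
  plot(x$time, x$vm, type = "l", xlab = "time (ms)", ylab = "Vm (mV)", ...)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Detect upstroke times in a voltage trace
#'
#' Upward crossings of -40 mV (the conventional beat-segmentation threshold),
#' linearly interpolated between samples.
#' @param time,vm time grid (ms) and membrane potential (mV).
#' @param threshold crossing level (mV).
#' @return numeric vector of crossing times (ms).
#' @export
detect_upstrokes <- function(time, vm, threshold = -40) {
  below <- vm < threshold
  idx <- which(below[-length(vm)] & !below[-1])
  if (!length(idx)) return(numeric(0))
  frac <- (threshold - vm[idx]) / (vm[idx + 1] - vm[idx])
  time[idx] + frac * (time[idx + 1] - time[idx])
}

# APD90 of one segmented beat. Onset = right endpoint of the steepest upstroke
# interval; end = linearly interpolated falling crossing of
# Vrest + 0.1 (Vpeak - Vrest); Vrest is the pre-upstroke level of the segment.
.apd90_one <- function(tt, vv) {
  if (length(tt) < 3) return(NA_real_)
  iu <- which.max(diff(vv)) + 1L
  # resting level: minimum before the upstroke, robust to a first sample
  # that lands inside the stimulus ramp
  vrest <- min(vv[seq_len(iu)])
  ip <- which.max(vv)
  vpeak <- vv[ip]
  if (vpeak - vrest < 10) return(NA_real_)   # no real activation
  thr <- vrest + 0.1 * (vpeak - vrest)
  after <- seq(ip, length(vv))
  j <- which(vv[after] < thr)[1]
  if (is.na(j)) return(NA_real_)             # censored: never repolarizes to 90%
  j <- after[j]
  tc <- if (j == 1) tt[1] else
    tt[j - 1] + (thr - vv[j - 1]) / (vv[j] - vv[j - 1]) * (tt[j] - tt[j - 1])
  tc - tt[iu]
}

#' Action potential duration at 90% repolarization
#'
#' Time from depolarization onset (maximum upstroke dV/dt) to the falling-limb
#' crossing of `Vrest + 0.1 (Vpeak - Vrest)`, linearly interpolated between
#' samples. Beats are segmented by the trace's cycle length when available,
#' otherwise by -40 mV upstroke crossings.
#'
#' @param trace an `ap_trace` (or list with `time`, `vm`, optional `bcl`).
#' @param beat_index which beat (1-based).
#' @return APD90 in ms.
#' @export
apd90 <- function(trace, beat_index = 1) {
  tt <- trace$time; vv <- trace$vm
  if (!is.null(trace$bcl)) {
    t0 <- (beat_index - 1) * trace$bcl; t1 <- beat_index * trace$bcl
    # include a 5 ms diastolic look-back so the segment always contains a
    # true resting sample even when the recording grid drifts and the first
    # in-cycle sample lands on the stimulus ramp
    sel <- tt >= t0 - 5 & tt < t1
    if (!any(tt >= t0 & tt < t1)) stop("trace does not contain beat ", beat_index)
    a <- .apd90_one(tt[sel], vv[sel])
  } else {
    ups <- detect_upstrokes(tt, vv)
    if (beat_index > length(ups)) stop("trace does not contain beat ", beat_index)
    t0 <- if (beat_index == 1) tt[1] else ups[beat_index] - 10
    t1 <- if (beat_index < length(ups)) ups[beat_index + 1] else max(tt) + 1
    sel <- tt >= t0 & tt < t1
    a <- .apd90_one(tt[sel], vv[sel])
  }
  if (is.na(a)) stop("censored APD: beat ", beat_index,
                     " never repolarizes to 90% within its cycle")
  a
}

#' Write / read an action potential trace as CSV
#'
#' Columns `time_ms`, `vm_mV`, `cai_mM`.
#' @param trace an `ap_trace`.
#' @param path file path.
#' @export
write_ap_trace <- function(trace, path) {
  write.csv(data.frame(time_ms = trace$time, vm_mV = trace$vm,
                       cai_mM = trace$cai), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ap_trace
#' @param bcl pacing cycle length to attach (ms), if known.
#' @export
read_ap_trace <- function(path, bcl = NULL) {
  d <- read.csv(path)
  structure(list(time = d$time_ms, vm = d$vm_mV, cai = d$cai_mM, bcl = bcl),
            class = "ap_trace")
}
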