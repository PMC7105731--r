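## One-way electromechanical coupling: calcium-driven cross-bridge tension per
## node, a global activation signal, and the time-varying-compliance lumped
## circulation producing left-ventricular volume, stroke volume and the
## tension-amplitude contractility surrogate.

#' Cross-bridge model parameters
#'
#' Four-state chain N_xb <-> P_xb <-> XB_PreR <-> XB_PostR with
#' calcium-cooperative regulatory rates `Knp TCa^7.5` / `Kpn TCa^-7.5`,
#' where TCa is the troponin-bound calcium fraction from a single-site
#' binding ODE (`kon`, `koff`). Transition-rate magnitudes follow published
#' reduced myofilament parameterizations; `Tmax` is the tension of a fully
#' recruited population (the kPa scale), of which a twitch under a
#' physiological calcium transient recruits a few percent - giving
#' tension-amplitude values on the sub-kPa scale observed in
#' tachyarrhythmia simulations.
#'
#' @param ... overrides for any named rate (1/ms), `Tmax` (kPa), `kon`
#'   (1/(mM ms)), `coop`, sub-step `dt` (ms) or `tca_floor`.
#' @return an object of class `crossbridge_params`.
#' @export
crossbridge_params <- function(...) {
  p <- list(kon = 40, koff = 0.04,
            Knp = 5, Kpn = 0.05, coop = 7.5,
            f_aapT = 0.5, g_aapT = 0.07, h_fT = 2.0, h_bT = 0.4, g_xbT = 0.07,
            Tmax = 12.5, dt = 0.25, tca_floor = 0.05)
  over <- list(...)
  bad <- setdiff(names(over), names(p))
  if (length(bad)) stop("unknown cross-bridge parameter(s): ",
                        paste(bad, collapse = ", "))
  p[names(over)] <- over
  if (any(unlist(p[c("Knp", "Kpn", "f_aapT", "g_aapT", "h_fT", "h_bT",
                     "g_xbT")]) < 0)) stop("rates must be >= 0")
  structure(p, class = "crossbridge_params")
}

#' Per-node active tension from a calcium movie
#'
#' Integrates the four-state cross-bridge chain independently at every node,
#' driven by linear interpolation of the node's calcium transient; occupancies
#' are renormalized to sum to one at every sub-step. Tension is
#' `Tmax (XB_PreR + XB_PostR)`.
#'
#' @param ca_movie a [voltage_movie()] carrying `$ca`, or a list with `ca`
#'   (frames x nodes matrix, mM) and `times` (ms).
#' @param params [crossbridge_params()].
#' @return a `tension_field`: list with `tension` (frames x nodes, kPa),
#'   `times`.
#' @export
run_crossbridge <- function(ca_movie, params = crossbridge_params()) {
  ca <- ca_movie$ca; times <- ca_movie$times
  if (is.null(ca)) stop("input carries no calcium data")
  if (any(ca < 0)) stop("negative calcium input")
  tens <- cpp_crossbridge(ca, times, unclass(params))
  structure(list(tension = tens, times = times), class = "tension_field")
}

#' @export
print.tension_field <- function(x, ...) {
  cat("<tension_field> ", ncol(x$tension), " nodes x ", nrow(x$tension),
      " frames, peak ", signif(max(x$tension), 4), " kPa\n", sep = "")
  invisible(x)
}

#' Tension amplitude (ampTens)
#'
#' The contractility surrogate: mean over nodes of the per-node temporal
#' standard deviation of active tension (population SD, divisor n).
#'
#' @param field a `tension_field` (or plain frames x nodes matrix).
#' @return ampTens in kPa.
#' @export
amp_tens <- function(field) {
  m <- if (inherits(field, "tension_field")) field$tension else field
  if (nrow(m) < 2) stop("undefined SD: need at least 2 frames")
  mu <- colMeans(m)
  mean(sqrt(colMeans(sweep(m, 2, mu)^2)))
}

#' Ventricular activation signal from a tension field
#'
#' `y_v(t)` = spatial mean tension at each frame, min-max normalized to
#' [0, 1] over the run; constant fields map to 0.
#'
#' @param field a `tension_field`.
#' @return list with `yv` and `times`.
#' @export
activation_from_tension <- function(field) {
  m <- if (inherits(field, "tension_field")) field$tension else field
  if (!nrow(m)) stop("empty tension field")
  s <- rowMeans(m)
  rng <- range(s)
  yv <- if (diff(rng) < 1e-12) rep(0, length(s)) else (s - rng[1]) / diff(rng)
  list(yv = yv, times = field$times)
}

#' Lumped circulation parameters
#'
#' Resistances (mmHg s/mL) and compliances (mL/mmHg) of the eight-compartment
#' closed loop (LV -> systemic artery -> systemic vein -> RA -> RV ->
#' pulmonary artery -> pulmonary vein -> LA -> LV) with diode valves at the
#' mitral, aortic, tricuspid and pulmonary positions. Ventricular compliance
#' interpolates between the passive value `c_passive` (C_Min, y_v = 0) and
#' the active value `c_active` (C_Max, y_v = 1); the activated ventricle is
#' stiffer, so `c_active < c_passive`. Rest volumes interpolate between
#' diastolic and systolic values; `literal_eq11 = TRUE` selects the printed
#' variant that mixes the right-ventricular diastolic rest volume into the
#' systolic vector.
#'
#' @param ... overrides for any named parameter.
#' @return an object of class `circulation_params`.
#' @export
circulation_params <- function(...) {
  p <- list(
    R_MI = 0.005, R_AO = 0.006, R_SA = 1.0, R_SV = 0.02,
    R_TR = 0.005, R_PU = 0.006, R_PA = 0.08, R_PV = 0.01,
    C_SA = 1.6, C_SV = 60, C_RA = 15, C_PA = 5, C_PV = 15, C_LA = 15,
    # ventricles: passive (C_Min) and active (C_Max) compliances
    CL_passive = 12, CL_active = 0.8, CR_passive = 20, CR_active = 4,
    C_LR = 0, C_RL = 0,
    VL_rest_d = 10, VL_rest_s = 5, VR_rest_d = 10, VR_rest_s = 5,
    # rest volumes of passive compartments (unstressed volumes)
    V0_SA = 300, V0_SV = 500, V0_RA = 30, V0_PA = 50, V0_PV = 60, V0_LA = 60,
    literal_eq11 = FALSE)
  over <- list(...)
  bad <- setdiff(names(over), names(p))
  if (length(bad)) stop("unknown circulation parameter(s): ",
                        paste(bad, collapse = ", "))
  p[names(over)] <- over
  num <- unlist(p[setdiff(names(p), "literal_eq11")])
  if (any(num[grep("^R_|^C|V0_", names(num))] < 0))
    stop("resistances, compliances and rest volumes must be positive")
  structure(p, class = "circulation_params")
}

#' Initial circulation state
#'
#' Volumes (mL) of all eight compartments at physiological resting pressures.
#' @param params [circulation_params()].
#' @return named numeric vector of class `circulation_state`.
#' @export
circulation_state_init <- function(params = circulation_params()) {
  p <- params
  v <- c(V_LV = 120, V_SA = p$V0_SA + 80 * p$C_SA, V_SV = p$V0_SV + 5 * p$C_SV,
         V_RA = p$V0_RA + 3 * p$C_RA, V_RV = 120,
         V_PA = p$V0_PA + 15 * p$C_PA, V_PV = p$V0_PV + 8 * p$C_PV,
         V_LA = p$V0_LA + 8 * p$C_LA)
  structure(v, class = "circulation_state")
}

# pressures of every compartment given volumes and activation
.circ_pressures <- function(v, p, yv) {
  CL <- yv * (p$CL_active - p$CL_passive) + p$CL_passive
  CR <- yv * (p$CR_active - p$CR_passive) + p$CR_passive
  if (p$literal_eq11) {
    # printed variant: second vector [VL_rest_s; VR_rest_d]
    VrestL <- (1 - yv) * (p$VL_rest_d - p$VL_rest_s) + p$VL_rest_s
    VrestR <- (1 - yv) * (p$VR_rest_d - p$VR_rest_s) + p$VR_rest_d
  } else {
    VrestL <- (1 - yv) * (p$VL_rest_d - p$VL_rest_s) + p$VL_rest_s
    VrestR <- (1 - yv) * (p$VR_rest_d - p$VR_rest_s) + p$VR_rest_s
  }
  if (p$C_LR == 0 && p$C_RL == 0) {
    pL <- (v[["V_LV"]] - VrestL) / CL
    pR <- (v[["V_RV"]] - VrestR) / CR
  } else {
    Cm <- matrix(c(CL, p$C_LR, p$C_RL, CR), 2, 2, byrow = TRUE)
    pv <- solve(Cm, c(v[["V_LV"]] - VrestL, v[["V_RV"]] - VrestR))
    pL <- pv[1]; pR <- pv[2]
  }
  c(P_LV = pL,
    P_SA = (v[["V_SA"]] - p$V0_SA) / p$C_SA,
    P_SV = (v[["V_SV"]] - p$V0_SV) / p$C_SV,
    P_RA = (v[["V_RA"]] - p$V0_RA) / p$C_RA,
    P_RV = pR,
    P_PA = (v[["V_PA"]] - p$V0_PA) / p$C_PA,
    P_PV = (v[["V_PV"]] - p$V0_PV) / p$C_PV,
    P_LA = (v[["V_LA"]] - p$V0_LA) / p$C_LA)
}

#' Advance the circulation by one step
#'
#' Compliances and rest volumes are interpolated by the activation `yv`,
#' ventricular pressures follow `P = C^-1(t) (V - Vrest(t))`, flows are
#' pressure differences over resistances with diode valves (flow only when
#' upstream pressure exceeds downstream), and volumes update by flow balance.
#'
#' @param state a `circulation_state` (named volume vector).
#' @param params [circulation_params()].
#' @param yv activation in [0, 1].
#' @param dt step (ms), <= 1.
#' @return advanced state; attribute `"pressures"` holds compartment
#'   pressures (mmHg) and `"flows"` the flows (mL/s).
#' @export
step_circulation <- function(state, params, yv, dt = 0.5) {
  if (dt > 1) stop("dt must be <= 1 ms")
  p <- params
  P <- .circ_pressures(state, p, yv)
  valve <- function(dp, r) if (dp > 0) dp / r else 0   # mL/s
  q <- c(
    Q_MI = valve(P[["P_LA"]] - P[["P_LV"]], p$R_MI),
    Q_AO = valve(P[["P_LV"]] - P[["P_SA"]], p$R_AO),
    Q_SA = (P[["P_SA"]] - P[["P_SV"]]) / p$R_SA,
    Q_SV = (P[["P_SV"]] - P[["P_RA"]]) / p$R_SV,
    Q_TR = valve(P[["P_RA"]] - P[["P_RV"]], p$R_TR),
    Q_PU = valve(P[["P_RV"]] - P[["P_PA"]], p$R_PU),
    Q_PA = (P[["P_PA"]] - P[["P_PV"]]) / p$R_PA,
    Q_PV = (P[["P_PV"]] - P[["P_LA"]]) / p$R_PV)
  dms <- dt / 1000   # flows are mL/s, step is ms
  new <- state
  new[["V_LV"]] <- state[["V_LV"]] + dms * (q[["Q_MI"]] - q[["Q_AO"]])
  new[["V_SA"]] <- state[["V_SA"]] + dms * (q[["Q_AO"]] - q[["Q_SA"]])
  new[["V_SV"]] <- state[["V_SV"]] + dms * (q[["Q_SA"]] - q[["Q_SV"]])
  new[["V_RA"]] <- state[["V_RA"]] + dms * (q[["Q_SV"]] - q[["Q_TR"]])
  new[["V_RV"]] <- state[["V_RV"]] + dms * (q[["Q_TR"]] - q[["Q_PU"]])
  new[["V_PA"]] <- state[["V_PA"]] + dms * (q[["Q_PU"]] - q[["Q_PA"]])
  new[["V_PV"]] <- state[["V_PV"]] + dms * (q[["Q_PA"]] - q[["Q_PV"]])
  new[["V_LA"]] <- state[["V_LA"]] + dms * (q[["Q_PV"]] - q[["Q_MI"]])
  if (any(new < 0)) {
    bad <- names(new)[which(new < 0)[1]]
    stop("circulation instability: negative volume in compartment ", bad)
  }
  attr(new, "pressures") <- P
  attr(new, "flows") <- q
  new
}

#' Run the closed-loop circulation driven by an activation signal
#'
#' @param yv activation samples in [0, 1].
#' @param times sample times of `yv` (ms); linear interpolation in between.
#' @param params [circulation_params()].
#' @param state initial `circulation_state`.
#' @param dt integration step (ms).
#' @param record_dt output cadence (ms).
#' @return a `circulation_trace`: list with `time`, `vlv`, `plv`, `vrv`,
#'   `prv`, `qao` (aortic flow, mL/s), `total_volume`, `yv`.
#' @export
run_circulation <- function(yv, times, params = circulation_params(),
                            state = circulation_state_init(params),
                            dt = 0.5, record_dt = 10) {
  yfun <- stats::approxfun(times, yv, rule = 2)
  t_end <- max(times)
  nstep <- floor((t_end - times[1]) / dt)
  rec_every <- max(1L, round(record_dt / dt))
  nrec <- nstep %/% rec_every + 1L
  out <- list(time = numeric(nrec), vlv = numeric(nrec), plv = numeric(nrec),
              vrv = numeric(nrec), prv = numeric(nrec), qao = numeric(nrec),
              total_volume = numeric(nrec), yv = numeric(nrec))
  s <- state
  ir <- 1L
  rec <- function(t, s, P, q) {
    out$time[ir] <<- t; out$vlv[ir] <<- s[["V_LV"]]; out$plv[ir] <<- P[["P_LV"]]
    out$vrv[ir] <<- s[["V_RV"]]; out$prv[ir] <<- P[["P_RV"]]
    out$qao[ir] <<- q[["Q_AO"]]; out$total_volume[ir] <<- sum(s)
    out$yv[ir] <<- yfun(t); ir <<- ir + 1L
  }
  P0 <- .circ_pressures(s, params, yfun(times[1]))
  rec(times[1], s, P0, c(Q_AO = 0))
  for (i in seq_len(nstep)) {
    t <- times[1] + (i - 1) * dt
    s <- step_circulation(s, params, yfun(t), dt)
    if (i %% rec_every == 0)
      rec(times[1] + i * dt, s, attr(s, "pressures"), attr(s, "flows"))
  }
  structure(out[lapply(out, length) > 0], class = "circulation_trace")
}

#' @export
print.circulation_trace <- function(x, ...) {
  cat("<circulation_trace> ", length(x$time), " samples over ",
      diff(range(x$time)), " ms; V_LV range ",
      paste(signif(range(x$vlv), 4), collapse = "-"), " mL\n", sep = "")
  invisible(x)
}

# local extrema by sign change of differences, with a prominence filter
.local_extrema <- function(v, prominence) {
  d <- sign(diff(v))
  d <- d[d != 0]
  # indices of strict direction changes in the original series
  dv <- diff(v)
  idx_max <- integer(0); idx_min <- integer(0)
  last_dir <- 0; last_i <- 1
  for (i in seq_along(dv)) {
    dir <- sign(dv[i])
    if (dir == 0) next
    if (last_dir > 0 && dir < 0) idx_max <- c(idx_max, i)
    if (last_dir < 0 && dir > 0) idx_min <- c(idx_min, i)
    last_dir <- dir
  }
  list(max = idx_max, min = idx_min)
}

#' Stroke volume from a ventricular volume trace
#'
#' Detects fill-eject cycles inside the meaningful period (intervals where
#' aortic-valve flow is positive, extended to the enclosing local-maximum ->
#' local-minimum volume excursion). End-diastolic volume is the local maximum
#' right before the volume falls, end-systolic volume the subsequent local
#' minimum; SV is the mean of EDV - ESV over detected cycles. When no cycle
#' exceeds the prominence threshold the function returns SV = 0 with the
#' `no_ejection` flag set.
#'
#' @param vlv left-ventricular volume series (mL).
#' @param times sample times (ms).
#' @param aortic_flow optional aortic flow series (mL/s) aligned with `vlv`;
#'   cycles without positive aortic flow are discarded.
#' @param prominence minimum EDV - ESV excursion to count as a cycle (mL).
#' @return list with `sv` (mL), `cycles` (data frame `t_edv, edv, t_esv,
#'   esv`), `no_ejection` flag.
#' @export
stroke_volume <- function(vlv, times, aortic_flow = NULL, prominence = 1) {
  ex <- .local_extrema(vlv, prominence)
  cycles <- list()
  for (im in ex$max) {
    nxt <- ex$min[ex$min > im]
    if (!length(nxt)) next
    imn <- nxt[1]
    if (vlv[im] - vlv[imn] < prominence) next
    if (!is.null(aortic_flow) &&
        !any(aortic_flow[im:imn] > 0)) next
    cycles[[length(cycles) + 1]] <-
      data.frame(t_edv = times[im], edv = vlv[im],
                 t_esv = times[imn], esv = vlv[imn])
  }
  if (!length(cycles))
    return(list(sv = 0, cycles = NULL, no_ejection = TRUE))
  cyc <- do.call(rbind, cycles)
  list(sv = mean(cyc$edv - cyc$esv), cycles = cyc, no_ejection = FALSE)
}
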