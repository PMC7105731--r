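## Monodomain tissue: regular 2D sheets and 3D slabs with no-flux boundaries,
## conduction-velocity calibration against a 1D cable, and the two-phase
## S1-S2 reentry-generation / reentry-maintenance protocol.

#' Tissue grid
#'
#' Regular grid with node-centered coordinates `x_mm = ix * h` and per-axis
#' effective diffusion coefficients (mm^2/ms) absorbing the monodomain
#' 1/(rho S C_m) factors.
#'
#' @param nx,ny,nz grid dimensions (nz = 1 for sheets).
#' @param h spacing (mm).
#' @param D per-axis diffusion, recycled to length 3 (mm^2/ms).
#' @param mask logical vector (length nx ny nz) of tissue nodes; default all.
#' @return an object of class `tissue_grid`.
#' @export
tissue_grid <- function(nx, ny = nx, nz = 1, h = 0.25, D = 0.1, mask = NULL) {
  stopifnot(h > 0, all(D >= 0))
  if (nx < 3 || (ny > 1 && ny < 3))
    stop("grid must be a 1D cable (ny = 1) or at least 3x3 for the diffusion stencil")
  D <- rep(D, length.out = 3)
  n <- nx * ny * nz
  if (is.null(mask)) mask <- rep(TRUE, n)
  stopifnot(length(mask) == n, any(mask))
  structure(list(dims = as.integer(c(nx, ny, nz)), h = h, D = D, mask = mask),
            class = "tissue_grid")
}

#' @export
print.tissue_grid <- function(x, ...) {
  cat("<tissue_grid> ", paste(x$dims, collapse = "x"), " @ h = ", x$h,
      " mm, D = (", paste(signif(x$D, 3), collapse = ", "), ") mm^2/ms\n",
      sep = "")
  invisible(x)
}

# 0-based node indices of a named S2 region
s2_region_nodes <- function(grid, site) {
  d <- grid$dims
  ix <- rep(0:(d[1] - 1), times = d[2] * d[3])
  iy <- rep(rep(0:(d[2] - 1), each = d[1]), times = d[3])
  half_x <- d[1] / 2; half_y <- d[2] / 2
  sel <- switch(site,
    LEFT_HALF = ix < half_x,
    LOWER_LEFT_QUADRANT = ix < half_x & iy < half_y,
    RIGHT_HALF = ix >= half_x,
    LOWER_RIGHT_QUADRANT = ix >= half_x & iy < half_y,
    stop("unknown S2 site: ", site))
  which(sel & grid$mask) - 1L
}

#' S1-S2 stimulus protocol
#'
#' Three S1 pulses 600 ms apart over a planar strip, and an S2 region chosen
#' from the four site analogues (left half, lower-left quadrant, right half,
#' lower-right quadrant of the sheet/slab). S2 fires automatically the first
#' time the mid-line monitor node repolarizes below the trigger threshold
#' after the third S1 upstroke (the "wave tail reaches the middle" rule).
#'
#' @param s2_site one of `"LEFT_HALF"`, `"LOWER_LEFT_QUADRANT"`,
#'   `"RIGHT_HALF"`, `"LOWER_RIGHT_QUADRANT"`.
#' @param s1_times onset times of the S1 pulses (ms); exactly 3.
#' @param s1_width width of the S1 strip at the y = 0 edge, in nodes.
#' @param amp,dur stimulus current (uA/uF) and duration (ms).
#' @param s2_threshold trigger threshold (mV).
#' @return an object of class `stimulus_protocol`.
#' @export
stimulus_protocol <- function(s2_site = "LOWER_LEFT_QUADRANT",
                              s1_times = c(0, 600, 1200), s1_width = 3,
                              amp = -52, dur = 2, s2_threshold = -70) {
  if (length(s1_times) != 3) stop("exactly 3 S1 pulses are required")
  if (!s2_site %in% .vt_sites)
    stop("unknown s2_site; expected one of: ", paste(.vt_sites, collapse = ", "))
  structure(list(s2_site = s2_site, s1_times = s1_times, s1_width = s1_width,
                 amp = amp, dur = dur, s2_threshold = s2_threshold),
            class = "stimulus_protocol")
}

#' Two-phase plan for reentry generation and maintenance
#'
#' @param gen_cv,maint_cv target conduction velocities (cm/s).
#' @param gen_duration,maint_duration phase durations (ms).
#' @export
phase_plan <- function(gen_cv = 20, gen_duration = 10000,
                       maint_cv = 68.5, maint_duration = 20000) {
  stopifnot(gen_cv > 0, maint_cv > 0, gen_duration > 0, maint_duration > 0)
  structure(list(gen_cv = gen_cv, gen_duration = gen_duration,
                 maint_cv = maint_cv, maint_duration = maint_duration),
            class = "phase_plan")
}

# model kind code for the C++ engine
.model_kind <- function(params) if (params$model == "detailed") 1L else 0L
.model_clist <- function(params)
  if (params$model == "detailed") .tnnp_clist(params) else .fk_clist(params)

#' Low-level monodomain run
#'
#' Advances the tissue from `state` (or rest) for `duration` ms under a list
#' of stimuli, recording voltage and calcium frames every `frame_dt` ms.
#'
#' @param grid [tissue_grid()].
#' @param params [cell_params()].
#' @param duration run length (ms).
#' @param state optional nvar x nnode state matrix (checkpoint).
#' @param stimuli list of `list(nodes = 0-based ints, start, dur, amp)`.
#' @param s2auto optional auto-trigger spec (see [run_s1s2()]).
#' @param dt integration step override (ms).
#' @param frame_dt frame cadence (ms), the standard output resolution is 10.
#' @param ionic_off disable ionic currents (diffusion-only runs).
#' @param t0 time origin for the recorded frames (ms).
#' @return list with `movie` ([voltage_movie()] carrying `$ca`),
#'   `checkpoint` (full state), `s2_time`.
#' @export
run_monodomain <- function(grid, params, duration, state = NULL,
                           stimuli = list(), s2auto = NULL, dt = NULL,
                           frame_dt = 10, ionic_off = FALSE, t0 = 0) {
  dt <- if (is.null(dt)) params$dt else dt
  n <- prod(grid$dims)
  if (is.null(state)) {
    s0 <- cell_state_init(params)
    state <- matrix(rep(s0, n), nrow = length(s0))
  }
  r <- cpp_tissue_run(.model_kind(params), state, .model_clist(params),
                      grid$dims, grid$h, grid$D, grid$mask, stimuli,
                      s2auto, duration, dt, frame_dt, ionic_off, t0)
  movie <- voltage_movie(r$frames_v, r$times, grid$dims, grid$h,
                         ca = r$frames_ca,
                         provenance = list(model = params$model,
                                           gKs_mult = params$gKs_mult,
                                           dt = dt, D = grid$D))
  list(movie = movie,
       checkpoint = structure(list(state = r$state, dims = grid$dims,
                                   model = params$model, t = t0 + duration),
                              class = "tissue_checkpoint"),
       s2_time = r$s2_time)
}

#' Conduction velocity of a planar wave
#'
#' CV = distance between two sampling planes divided by the difference of
#' their earliest -40 mV upcrossing times (linearly interpolated between
#' frames), converted to cm/s.
#'
#' @param movie a [voltage_movie()] containing a single planar wave.
#' @param axis propagation axis (`"x"` or `"y"`).
#' @param planes fractional positions of the two sampling planes.
#' @param threshold crossing level (mV).
#' @return conduction velocity (cm/s).
#' @export
measure_cv <- function(movie, axis = "x", planes = c(0.25, 0.75),
                       threshold = -40) {
  d <- movie$dims
  nax <- if (axis == "x") d[1] else d[2]
  i1 <- max(1L, round(planes[1] * nax)); i2 <- min(nax, round(planes[2] * nax))
  plane_nodes <- function(i) {
    if (axis == "x") node_index(movie, i - 1L, 0:(d[2] - 1), 0)
    else node_index(movie, 0:(d[1] - 1), i - 1L, 0)
  }
  first_cross <- function(nodes) {
    tmin <- Inf
    for (nd in nodes) {
      cr <- detect_upstrokes(movie$times, movie$frames[, nd], threshold)
      if (length(cr)) tmin <- min(tmin, cr[1])
    }
    tmin
  }
  t1 <- first_cross(plane_nodes(i1)); t2 <- first_cross(plane_nodes(i2))
  if (!is.finite(t2) || !is.finite(t1))
    stop("no propagation: wave never reaches the sampling plane(s)")
  dist_mm <- abs(i2 - i1) * movie$h
  dt_ms <- abs(t2 - t1)
  if (dt_ms == 0) stop("no propagation: equal activation times at both planes")
  100 * dist_mm / dt_ms   # mm/ms -> cm/s
}

#' Calibrate the diffusion coefficient to a target conduction velocity
#'
#' Bisection on D using planar-wave CV measured on a 1D cable with the given
#' cell model; the classic sqrt(D) scaling provides the initial bracket. The
#' returned D reproduces the target CV within 2%.
#'
#' @param params [cell_params()].
#' @param target_cv target conduction velocity (cm/s).
#' @param h node spacing (mm).
#' @param n_nodes cable length in nodes.
#' @param dt integration step override (ms).
#' @param tol relative CV tolerance for the bisection exit.
#' @return calibrated D (mm^2/ms); attributes record the achieved CV.
#' @export
calibrate_diffusion <- function(params, target_cv, h = 0.25, n_nodes = 120,
                                dt = NULL, tol = 0.005) {
  stopifnot(target_cv > 0)
  cable_cv <- function(D) {
    g <- tissue_grid(n_nodes, 1, 1, h = h, D = c(D, 0, 0))
    dur <- (n_nodes * h) / (target_cv / 100) * 1.5 + 60
    r <- run_monodomain(g, params, duration = dur,
                        stimuli = list(list(nodes = 0:2, start = 0, dur = 2,
                                            amp = params$stim_amp)),
                        dt = dt, frame_dt = 1)
    tryCatch(measure_cv(r$movie, "x"), error = function(e) NA_real_)
  }
  D0 <- 0.05
  cv0 <- cable_cv(D0)
  if (!is.finite(cv0)) { D0 <- 0.2; cv0 <- cable_cv(D0) }
  if (!is.finite(cv0)) stop("calibration failure: no propagation at probe D")
  D_guess <- D0 * (target_cv / cv0)^2
  lo <- D_guess / 4; hi <- D_guess * 4
  cv_lo <- cable_cv(lo); cv_hi <- cable_cv(hi)
  if (!is.finite(cv_lo)) cv_lo <- 0
  if (!(cv_lo <= target_cv && cv_hi >= target_cv))
    stop(sprintf(paste0("calibration failure: target %g cm/s not bracketed ",
                        "(measured %.3g at D = %.3g, %.3g at D = %.3g)"),
                 target_cv, cv_lo, lo, cv_hi, hi))
  for (i in 1:40) {
    mid <- sqrt(lo * hi)
    cv_mid <- cable_cv(mid)
    if (is.finite(cv_mid) && abs(cv_mid - target_cv) / target_cv < tol) {
      return(structure(mid, achieved_cv = cv_mid))
    }
    if (!is.finite(cv_mid) || cv_mid < target_cv) lo <- mid else hi <- mid
  }
  mid <- sqrt(lo * hi)
  structure(mid, achieved_cv = cable_cv(mid))
}

#' Run the S1-S2 reentry-generation phase
#'
#' Three S1 pulses drive planar waves from the y = 0 edge; S2 covers the
#' protocol's region and fires automatically when the mid-line monitor node
#' repolarizes below the trigger threshold after the third S1 upstroke. The
#' grid's diffusion should be calibrated to the plan's generation CV
#' beforehand (see [calibrate_diffusion()]).
#'
#' @param grid [tissue_grid()] (D at the generation-phase value).
#' @param params [cell_params()].
#' @param protocol [stimulus_protocol()].
#' @param plan [phase_plan()].
#' @param seed provenance stamp only - the simulation is deterministic.
#' @param dt,frame_dt integration step and frame cadence (ms).
#' @return list with `movie`, `checkpoint` (state at the end of the phase),
#'   `s2_time` (ms).
#' @export
run_s1s2 <- function(grid, params, protocol = stimulus_protocol(),
                     plan = phase_plan(), seed = NULL, dt = NULL,
                     frame_dt = 10) {
  d <- grid$dims
  # S1: strip along y = 0 .. s1_width-1 (planar wave in +y)
  ix <- rep(0:(d[1] - 1), times = d[2] * d[3])
  iy <- rep(rep(0:(d[2] - 1), each = d[1]), times = d[3])
  s1_nodes <- which(iy < protocol$s1_width & grid$mask) - 1L
  stimuli <- lapply(protocol$s1_times, function(t0)
    list(nodes = s1_nodes, start = t0, dur = protocol$dur,
         amp = protocol$amp))
  monitor <- center_node(list(dims = d)) - 1L
  s2auto <- list(nodes = s2_region_nodes(grid, protocol$s2_site),
                 amp = protocol$amp, dur = protocol$dur,
                 monitor = monitor, threshold = protocol$s2_threshold,
                 after_upstrokes = 3L)
  r <- run_monodomain(grid, params, duration = plan$gen_duration,
                      stimuli = stimuli, s2auto = s2auto, dt = dt,
                      frame_dt = frame_dt)
  if (is.na(r$s2_time))
    stop("protocol failure: S2 trigger condition never met within ",
         plan$gen_duration, " ms")
  r$movie$provenance <- c(r$movie$provenance,
                          list(protocol = protocol$s2_site, seed = seed,
                               s2_time = r$s2_time))
  r
}

#' Continue a checkpointed run (reentry maintenance)
#'
#' Restarts integration from a saved tissue state with no stimuli, typically
#' after recalibrating the grid's diffusion to the maintenance CV.
#'
#' @param checkpoint checkpoint from [run_s1s2()] / [run_monodomain()].
#' @param grid [tissue_grid()] (D at the maintenance-phase value).
#' @param params [cell_params()].
#' @param duration maintenance length (ms).
#' @param dt,frame_dt integration step and frame cadence (ms).
#' @return list with `movie` and `checkpoint`.
#' @export
run_maintenance <- function(checkpoint, grid, params, duration = 20000,
                            dt = NULL, frame_dt = 10) {
  if (!identical(as.integer(checkpoint$dims), grid$dims))
    stop("incompatible checkpoint: state dims ",
         paste(checkpoint$dims, collapse = "x"), " vs grid ",
         paste(grid$dims, collapse = "x"))
  if (!identical(checkpoint$model, params$model))
    stop("incompatible checkpoint: model mismatch")
  run_monodomain(grid, params, duration = duration, state = checkpoint$state,
                 dt = dt, frame_dt = frame_dt, t0 = checkpoint$t)
}
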