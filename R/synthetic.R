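## Ground-truth generators: analytic spiral/scroll wavefields with known
## singularity locations, plane waves with known conduction velocity, and
## multivariate-normal feature tables with a prescribed correlation matrix.
## Every generator emits the same containers as the simulator, so downstream
## code is oblivious to the data's origin.

#' Analytic spiral-wave voltage movie with known phase-singularity ground truth
#'
#' Builds `V(x, y, t) = V0 + A cos(phi(x, y) - 2 pi t / T)` where the spatial
#' phase superposes one Archimedean-spiral phase per vortex:
#' `phi = sum_i [chi_i atan2(y - y0_i, x - x0_i) + k r_i]` (phases, not
#' voltages, are superposed). The singularity ground truth is the set of core
#' trajectories. The default amplitude/offset keep the synthetic "voltage" in
#' [-86, +34] mV so APD-style thresholds stay meaningful.
#'
#' @param dims grid `c(nx, ny)`.
#' @param h spacing (mm).
#' @param cores data frame with columns `x0`, `y0` (mm) and `chirality`
#'   (+1 or -1), one row per vortex.
#' @param period rotation period T (ms).
#' @param k spatial wavenumber (rad/mm).
#' @param A,V0 amplitude and offset (mV).
#' @param drift core drift velocity `c(vx, vy)` (mm/s).
#' @param duration total duration (ms), at least `2 * period`.
#' @param frame_dt frame cadence (ms).
#' @return list with `movie` (a [voltage_movie()]) and `ps_truth` (data frame
#'   `frame`, `time_ms`, `x_mm`, `y_mm`, `chirality`).
#' @export
gen_spiral_movie <- function(dims, h, cores, period, k = 0.2, A = 60,
                             V0 = -26, drift = c(0, 0), duration = NULL,
                             frame_dt = 10) {
  nx <- dims[1]; ny <- dims[2]
  if (is.null(duration)) duration <- 2 * period
  if (duration < 2 * period) stop("duration must be >= 2 * period")
  xs <- (seq_len(nx) - 1) * h; ys <- (seq_len(ny) - 1) * h
  if (any(cores$x0 < 0 | cores$x0 > max(xs) | cores$y0 < 0 | cores$y0 > max(ys)))
    stop("vortex core outside domain")
  times <- seq(0, duration, by = frame_dt)
  nt <- length(times)
  frames <- matrix(0, nt, nx * ny)
  X <- matrix(xs, nx, ny); Y <- matrix(ys, nx, ny, byrow = TRUE)
  truth <- vector("list", nt)
  for (it in seq_len(nt)) {
    t <- times[it]
    phi <- matrix(0, nx, ny)
    cx <- cores$x0 + drift[1] * t / 1000
    cy <- cores$y0 + drift[2] * t / 1000
    for (i in seq_len(nrow(cores))) {
      r <- sqrt((X - cx[i])^2 + (Y - cy[i])^2)
      phi <- phi + cores$chirality[i] * atan2(Y - cy[i], X - cx[i]) + k * r
    }
    frames[it, ] <- as.vector(V0 + A * cos(phi - 2 * pi * t / period))
    truth[[it]] <- data.frame(frame = it, time_ms = t, x_mm = cx, y_mm = cy,
                              chirality = cores$chirality)
  }
  list(movie = voltage_movie(frames, times, c(nx, ny, 1L), h,
                             provenance = list(generator = "spiral",
                                               period = period, k = k)),
       ps_truth = do.call(rbind, truth))
}

#' Analytic scroll-wave movie (stacked phase-shifted spiral layers)
#'
#' Stacks `nz` spiral layers with a per-layer phase shift (`twist`); the
#' ground-truth filament is the vertical core line (straight when twist = 0).
#'
#' @inheritParams gen_spiral_movie
#' @param nz number of layers (>= 3).
#' @param twist phase shift per layer (rad).
#' @return list with `movie` (3D [voltage_movie()]) and `filament_truth`
#'   (data frame `x_mm`, `y_mm` of core columns).
#' @export
gen_scroll_movie <- function(dims, h, cores, period, nz, twist = 0, k = 0.2,
                             A = 60, V0 = -26, duration = NULL, frame_dt = 10) {
  if (nz < 3) stop("nz must be >= 3")
  base <- gen_spiral_movie(dims, h, cores, period, k = k, A = A, V0 = V0,
                           duration = duration, frame_dt = frame_dt)
  nx <- dims[1]; ny <- dims[2]
  nt <- nrow(base$movie$frames)
  frames <- matrix(0, nt, nx * ny * nz)
  xs <- (seq_len(nx) - 1) * h; ys <- (seq_len(ny) - 1) * h
  X <- matrix(xs, nx, ny); Y <- matrix(ys, nx, ny, byrow = TRUE)
  phi <- matrix(0, nx, ny)
  for (i in seq_len(nrow(cores))) {
    r <- sqrt((X - cores$x0[i])^2 + (Y - cores$y0[i])^2)
    phi <- phi + cores$chirality[i] * atan2(Y - cores$y0[i], X - cores$x0[i]) + k * r
  }
  for (z in seq_len(nz)) {
    shift <- (z - 1) * twist
    for (it in seq_len(nt)) {
      t <- base$movie$times[it]
      frames[it, ((z - 1) * nx * ny + 1):(z * nx * ny)] <-
        as.vector(V0 + A * cos(phi - 2 * pi * t / period + shift))
    }
  }
  list(movie = voltage_movie(frames, base$movie$times, c(nx, ny, nz), h,
                             provenance = list(generator = "scroll",
                                               period = period, twist = twist)),
       filament_truth = data.frame(x_mm = cores$x0, y_mm = cores$y0,
                                   chirality = cores$chirality))
}

#' Plane-wave movie with exactly known conduction velocity
#'
#' A traveling pulse whose activation time at position x is `x / cv`. The
#' upstroke is piecewise linear over 30 ms - long enough that, at the
#' standard 10 ms frame cadence, the -40 mV threshold crossing is always
#' bracketed by two frames inside the linear segment, so linearly
#' interpolated crossings recover the activation time (and hence CV) exactly.
#'
#' @param cv conduction velocity (cm/s), > 0.
#' @param dims grid `c(nx, ny)` (wave travels along x).
#' @param h spacing (mm).
#' @param duration total duration (ms); default long enough to cross the grid.
#' @param frame_dt frame cadence (ms).
#' @param apd plateau duration of the pulse (ms).
#' @return a [voltage_movie()].
#' @export
gen_plane_wave_movie <- function(cv, dims, h = 0.25, duration = NULL,
                                 frame_dt = 10, apd = 200) {
  if (cv <= 0) stop("cv must be > 0")
  nx <- dims[1]; ny <- if (length(dims) > 1) dims[2] else 1
  v_mm_ms <- cv / 100          # cm/s -> mm/ms
  xs <- (seq_len(nx) - 1) * h
  ta <- xs / v_mm_ms
  if (is.null(duration)) duration <- max(ta) + apd + 100
  times <- seq(0, duration, by = frame_dt)
  rise <- 30; fall <- 40
  pulse <- function(dtau) {
    v <- rep(-86, length(dtau))
    i <- dtau >= 0 & dtau < rise
    v[i] <- -86 + 120 * dtau[i] / rise
    i <- dtau >= rise & dtau < rise + apd
    v[i] <- 34
    i <- dtau >= rise + apd & dtau < rise + apd + fall
    v[i] <- 34 - 120 * (dtau[i] - rise - apd) / fall
    v
  }
  frames <- matrix(0, length(times), nx * ny)
  for (it in seq_along(times)) {
    col <- pulse(times[it] - ta)            # length nx
    frames[it, ] <- rep(col, times = ny)
  }
  voltage_movie(frames, times, c(nx, ny, 1L), h,
                provenance = list(generator = "plane_wave", cv = cv))
}

#' Correlated feature table with prescribed moments
#'
#' Draws a multivariate-normal table via the Cholesky factor of the target
#' correlation matrix, scaled and shifted to the target means/SDs. If
#' 3-decimal rounding of a printed matrix breaks positive semi-definiteness,
#' the matrix is repaired by clipping eigenvalues at 1e-8 and rescaling the
#' diagonal (a message reports the repair). Count columns (`ps`, `filament`)
#' are rounded to nonnegative integers.
#'
#' @param n number of cases.
#' @param summary a [summary_stats()] object giving targets; defaults to the
#'   packaged printed summary ([printed_summary()]).
#' @param seed integer seed (reproducible draws).
#' @return a data frame with the summary's variables as columns.
#' @export
gen_correlated_table <- function(n, summary = printed_summary(), seed = 1) {
  r <- summary$r
  ev <- eigen(r, symmetric = TRUE)
  if (min(ev$values) < 1e-8) {
    vals <- pmax(ev$values, 1e-8)
    r <- ev$vectors %*% diag(vals) %*% t(ev$vectors)
    d <- sqrt(diag(r))
    r <- r / outer(d, d)
    dimnames(r) <- dimnames(summary$r)
    message("correlation target repaired to PSD by eigenvalue clipping ",
            "(min eigenvalue was ", signif(min(ev$values), 3), ")")
  }
  L <- chol(r)
  p <- ncol(r)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  Z <- matrix(rnorm(n * p), n, p)
  X <- Z %*% L
  X <- sweep(X, 2, summary$sd[colnames(r)], `*`)
  X <- sweep(X, 2, summary$mean[colnames(r)], `+`)
  out <- as.data.frame(X)
  names(out) <- colnames(r)
  for (cn in intersect(c("ps", "filament"), names(out)))
    out[[cn]] <- pmax(0, round(out[[cn]]))
  out
}
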