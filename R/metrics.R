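## Electrical-instability quantifiers: reentry APD at a probe node, dominant
## frequency mapping, phase mapping with delay embedding, phase-singularity
## detection via topological charge on 2x2 plaquettes, and scroll-wave
## filament detection on voxels via the two-frame iso-potential condition.

#' Mean APD90 during reentry at a probe node
#'
#' Segments the probe's voltage trace into activations (-40 mV upstrokes),
#' computes APD90 per activation and returns their mean together with the
#' activation count.
#'
#' @param movie a [voltage_movie()], at least 10 s long for production use.
#' @param probe 1-based node index; defaults to the domain-center node.
#' @return list with `mean_apd` (ms), `apds`, `n_activations`.
#' @export
mean_reentry_apd <- function(movie, probe = center_node(movie)) {
  tt <- movie$times
  vv <- movie$frames[, probe]
  ups <- detect_upstrokes(tt, vv)
  if (length(ups) < 2)
    stop("insufficient activity: fewer than 2 activations at the probe node")
  # per-activation windows: [ups_i - lead, ups_{i+1} - lead)
  lead <- 2 * frame_step(movie)
  apds <- vapply(seq_along(ups), function(i) {
    t0 <- ups[i] - lead
    t1 <- if (i < length(ups)) ups[i + 1] - lead else max(tt) + 1
    sel <- tt >= t0 & tt < t1
    .apd90_one(tt[sel], vv[sel])
  }, numeric(1))
  apds <- apds[is.finite(apds)]
  if (length(apds) < 1)
    stop("insufficient activity: no measurable APD at the probe node")
  list(mean_apd = mean(apds), apds = apds, n_activations = length(ups))
}

#' Dominant-frequency map
#'
#' Per node, the mean-detrended signal is zero-padded so the FFT frequency
#' resolution is at most `resolution` Hz, and the dominant frequency is the
#' power argmax within `band`. The per-case scalar is the mean over nodes;
#' nodes with (near-)constant signals have no defined DF and are excluded
#' (their count is reported).
#'
#' @param movie a [voltage_movie()] of duration >= 2 s.
#' @param band search band in Hz (excludes DC/drift below 0.5 Hz).
#' @param resolution spectral resolution ceiling (Hz).
#' @return list with `df_hz` (per-node vector, NA where undefined),
#'   `mean_df`, `n_excluded`.
#' @export
dominant_frequency_map <- function(movie, band = c(0.5, 30),
                                   resolution = 0.01) {
  nt <- nrow(movie$frames)
  dt_s <- frame_step(movie) / 1000
  if ((nt - 1) * dt_s < 2) stop("movie must be at least 2 s long")
  fs <- 1 / dt_s
  nfft <- 2^ceiling(log2(fs / resolution))
  freqs <- (0:(nfft - 1)) * fs / nfft
  sel <- which(freqs >= band[1] & freqs <= band[2])
  nn <- ncol(movie$frames)
  dfv <- rep(NA_real_, nn)
  chunk <- max(1L, floor(2e6 / nfft))
  for (start in seq(1L, nn, by = chunk)) {
    cols <- start:min(nn, start + chunk - 1L)
    Xc <- movie$frames[, cols, drop = FALSE]
    mu <- colMeans(Xc)
    Xc <- sweep(Xc, 2, mu)
    amp <- apply(abs(Xc), 2, max)
    live <- amp > 1e-6
    if (!any(live)) next
    Z <- matrix(0, nfft, sum(live))
    Z[seq_len(nt), ] <- Xc[, live, drop = FALSE]
    P <- abs(mvfft(Z))^2
    dfv[cols[live]] <- freqs[sel[max.col(t(P[sel, , drop = FALSE]),
                                         ties.method = "first")]]
  }
  n_excl <- sum(is.na(dfv))
  list(df_hz = dfv, mean_df = mean(dfv, na.rm = TRUE), n_excluded = n_excl)
}

#' Phase field by delay embedding
#'
#' `theta(x, t) = atan2(V(x, t + tau) - Vmean(t), V(x, t) - Vmean(t))` where
#' `Vmean(t)` is the spatial mean of the frame at time t (the embedding
#' origin). The final tau-worth of frames is dropped. tau must be an integer
#' number of frames.
#'
#' @param movie a [voltage_movie()].
#' @param tau delay (ms), default 10 (one frame at the standard cadence).
#' @return list of class `phase_field`: `theta` (nt' x nnode, values in
#'   [-pi, pi)), `times`, `dims`, `h`.
#' @export
compute_phase <- function(movie, tau = 10) {
  step <- frame_step(movie)
  k <- tau / step
  if (abs(k - round(k)) > 1e-9)
    stop("tau must be an integer multiple of the frame step (", step, " ms)")
  k <- as.integer(round(k))
  nt <- nrow(movie$frames)
  if (nt <= k) stop("movie shorter than the delay tau")
  idx <- seq_len(nt - k)
  vmean <- rowMeans(movie$frames[idx, , drop = FALSE])
  num <- movie$frames[idx + k, , drop = FALSE] - vmean
  den <- movie$frames[idx, , drop = FALSE] - vmean
  theta <- atan2(num, den)
  theta[theta >= pi] <- -pi          # range [-pi, pi) exactly
  structure(list(theta = theta, times = movie$times[idx], dims = movie$dims,
                 h = movie$h), class = "phase_field")
}

#' Wrapped phase difference
#'
#' `theta1 - theta2` wrapped into [-pi, pi), congruent to the raw difference
#' modulo 2 pi for arbitrary (not only principal-value) inputs.
#'
#' @param theta1,theta2 phases in radians (vectorized).
#' @return wrapped differences in [-pi, pi).
#' @export
phase_difference <- function(theta1, theta2) {
  ((theta1 - theta2 + pi) %% (2 * pi)) - pi
}

#' Phase singularities in one frame by topological charge
#'
#' For every 2x2 node plaquette of a 2D frame (or one z-slice of a 3D frame)
#' the four wrapped phase differences around the loop are summed; a sum
#' within `tol` of +/- 2 pi marks a singularity of that charge at the
#' plaquette center.
#'
#' @param phase a `phase_field` from [compute_phase()].
#' @param frame 1-based frame index.
#' @param z 0-based slice index for 3D fields.
#' @param tol tolerance on the +/- 2 pi sum (rad).
#' @return data frame `x_mm`, `y_mm`, `ix`, `iy`, `charge` (+1/-1 units of
#'   2 pi); zero rows when no singularity.
#' @export
detect_ps <- function(phase, frame, z = 0, tol = 0.1) {
  d <- phase$dims
  th <- matrix(phase$theta[frame, (z * d[1] * d[2] + 1):((z + 1) * d[1] * d[2])],
               d[1], d[2])
  nx <- d[1]; ny <- d[2]
  a <- th[-nx, -ny]   # (i,   j)
  b <- th[-1, -ny]    # (i+1, j)
  cc <- th[-1, -1]    # (i+1, j+1)
  dd <- th[-nx, -1]   # (i,   j+1)
  s <- phase_difference(b, a) + phase_difference(cc, b) +
       phase_difference(dd, cc) + phase_difference(a, dd)
  pos <- which(abs(s - 2 * pi) < tol, arr.ind = TRUE)
  neg <- which(abs(s + 2 * pi) < tol, arr.ind = TRUE)
  res <- rbind(
    if (nrow(pos)) data.frame(ix = pos[, 1] - 1L, iy = pos[, 2] - 1L, charge = 1L),
    if (nrow(neg)) data.frame(ix = neg[, 1] - 1L, iy = neg[, 2] - 1L, charge = -1L))
  if (is.null(res)) res <- data.frame(ix = integer(0), iy = integer(0),
                                      charge = integer(0))
  res$x_mm <- (res$ix + 0.5) * phase$h
  res$y_mm <- (res$iy + 0.5) * phase$h
  res[c("x_mm", "y_mm", "ix", "iy", "charge")]
}

#' Time-averaged phase-singularity count of a movie
#'
#' Runs [compute_phase()] and [detect_ps()] over every usable frame (all
#' z-slices for 3D movies) and averages the per-frame counts.
#'
#' @inheritParams compute_phase
#' @param tol plaquette-sum tolerance (rad).
#' @return list with `mean_count`, per-frame `counts`, and `records` (a data
#'   frame with `frame`, `time_ms`, `z`, `x_mm`, `y_mm`, `charge`).
#' @export
ps_count <- function(movie, tau = 10, tol = 0.1) {
  ph <- compute_phase(movie, tau)
  nt <- nrow(ph$theta)
  nz <- ph$dims[3]
  recs <- list()
  counts <- numeric(nt)
  for (f in seq_len(nt)) {
    tot <- 0L
    for (z in 0:(nz - 1)) {
      p <- detect_ps(ph, f, z = z, tol = tol)
      tot <- tot + nrow(p)
      if (nrow(p))
        recs[[length(recs) + 1]] <- cbind(frame = f, time_ms = ph$times[f],
                                          z = z, p)
    }
    counts[f] <- tot
  }
  list(mean_count = mean(counts), counts = counts,
       records = if (length(recs)) do.call(rbind, recs) else NULL)
}

#' Filament elements in a 3D movie by the two-frame iso-potential rule
#'
#' For every voxel the centroid potential is interpolated from four corner
#' nodes with weights p = q = r = 0.5 (so V_c = 0.5 V(x,y,z) + 0.5 V(x+1,y,z)
#' + 0.5 V(x,y+1,z) - 0.5 V(x,y,z+1)); a voxel is a filament element iff its
#' centroid potential lies within `eps` of V_iso at both frame n and frame
#' n+1 (the stationarity condition dVm/dt = 0 absorbed into the two-frame
#' rule). Elements are grouped into 26-connectivity components.
#'
#' @param movie a 3D [voltage_movie()] (nz > 1).
#' @param frame frame index n (frames n and n+1 are used).
#' @param v_iso iso-potential (mV); `NULL` selects the per-frame estimate:
#'   mean Vm over surface-slice singularity locations, clamped to
#'   [-75, -10] mV, falling back to -40 mV when no surface singularity exists.
#' @param eps iso tolerance (mV); `NULL` selects half the maximum per-node
#'   |delta V| between the two frames, capped at 5 mV.
#' @param tau delay for the surface-phase V_iso estimate (ms).
#' @return list with `elements` (data frame `ix, iy, iz` 0-based voxel
#'   indices), `n_elements`, `n_components`, `v_iso`, `eps`.
#' @export
detect_filaments <- function(movie, frame, v_iso = NULL, eps = NULL, tau = 10) {
  d <- movie$dims
  if (d[3] < 2)
    stop("filament detection needs a 3D movie (nz > 1); use detect_ps for sheets")
  if (frame + 1 > nrow(movie$frames)) stop("frames n and n+1 must be available")
  V1 <- array(movie$frames[frame, ], dim = d)
  V2 <- array(movie$frames[frame + 1, ], dim = d)
  if (is.null(v_iso)) {
    v_iso <- tryCatch({
      ph <- compute_phase(movie, tau)
      f <- min(frame, nrow(ph$theta))
      surf <- detect_ps(ph, f, z = 0)
      if (nrow(surf) == 0) -40 else {
        vals <- V1[cbind(surf$ix + 1L, surf$iy + 1L, 1L)]
        min(max(mean(vals), -75), -10)
      }
    }, error = function(e) -40)
  }
  if (v_iso < -75 || v_iso > -10) stop("v_iso must lie in [-75, -10] mV")
  if (is.null(eps)) eps <- min(max(abs(V2 - V1)) / 2, 5)
  if (eps <= 0) stop("eps must be > 0")
  cen <- function(V) {
    0.5 * V[-d[1], -d[2], -d[3], drop = FALSE] +
    0.5 * V[-1,    -d[2], -d[3], drop = FALSE] +
    0.5 * V[-d[1], -1,    -d[3], drop = FALSE] -
    0.5 * V[-d[1], -d[2], -1,    drop = FALSE]
  }
  C1 <- cen(V1); C2 <- cen(V2)
  hit <- abs(C1 - v_iso) < eps & abs(C2 - v_iso) < eps
  idx <- which(hit, arr.ind = TRUE)
  if (nrow(idx) == 0) {
    return(list(elements = data.frame(ix = integer(0), iy = integer(0),
                                      iz = integer(0)),
                n_elements = 0L, n_components = 0L, v_iso = v_iso, eps = eps))
  }
  el <- data.frame(ix = idx[, 1] - 1L, iy = idx[, 2] - 1L, iz = idx[, 3] - 1L)
  n_comp <- .connected_components_26(el)
  list(elements = el, n_elements = nrow(el), n_components = n_comp,
       v_iso = v_iso, eps = eps)
}

# number of 26-connectivity components among voxel index triples
.connected_components_26 <- function(el) {
  n <- nrow(el)
  if (n == 0) return(0L)
  if (n == 1) return(1L)
  key <- paste(el$ix, el$iy, el$iz)
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offs <- offs[!(offs$dx == 0 & offs$dy == 0 & offs$dz == 0), ]
  from <- integer(0); to <- integer(0)
  for (j in seq_len(nrow(offs))) {
    hit <- match(paste(el$ix + offs$dx[j], el$iy + offs$dy[j],
                       el$iz + offs$dz[j]), key)
    ok <- which(!is.na(hit))
    from <- c(from, ok); to <- c(to, hit[ok])
  }
  if (!length(from)) return(n)
  g <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  igraph::components(g)$no
}

#' Time-averaged filament counts of a 3D movie
#'
#' @inheritParams detect_filaments
#' @param frames which frames to analyze (default all with an n+1 partner).
#' @return list with `mean_elements` (the per-case scalar), `mean_components`
#'   (diagnostic), and per-frame vectors.
#' @export
filament_count <- function(movie, frames = NULL, v_iso = NULL, eps = NULL) {
  nt <- nrow(movie$frames)
  if (is.null(frames)) frames <- seq_len(nt - 1)
  nel <- ncmp <- numeric(length(frames))
  for (i in seq_along(frames)) {
    r <- detect_filaments(movie, frames[i], v_iso = v_iso, eps = eps)
    nel[i] <- r$n_elements; ncmp[i] <- r$n_components
  }
  list(mean_elements = mean(nel), mean_components = mean(ncmp),
       n_elements = nel, n_components = ncmp)
}

#' Write singularity/filament records as CSV
#'
#' Columns `frame_ms`, `x`, `y` (and `z`), `charge`.
#' @param records data frame from [ps_count()]'s `records`.
#' @param path file path.
#' @export
write_ps_records <- function(records, path) {
  out <- data.frame(frame_ms = records$time_ms, x = records$x_mm,
                    y = records$y_mm, z = records$z, charge = records$charge)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Assemble the six per-case metrics
#'
#' The per-case scalars of one simulated tachyarrhythmia case: mean reentry
#' APD, mean dominant frequency, time-averaged singularity count,
#' time-averaged filament element count, stroke volume, and tension
#' amplitude. Failed constituent metrics yield NA (with the failure message
#' collected in `attr(, "failures")`), never a silent gap.
#'
#' @param movie a [voltage_movie()].
#' @param tension a tension field (see [run_crossbridge()]), or NULL.
#' @param vlv left-ventricular volume trace (list with `time`, `vlv`), or NULL.
#' @return one-row data frame `apd, df, ps, filament, sv, amptens`.
#' @export
case_metrics <- function(movie, tension = NULL, vlv = NULL) {
  fails <- character(0)
  grab <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      fails[[length(fails) + 1]] <<- paste0(name, ": ", conditionMessage(e))
      NA_real_
    })
  }
  apd <- grab("apd", mean_reentry_apd(movie)$mean_apd)
  dfq <- grab("df", dominant_frequency_map(movie)$mean_df)
  psc <- grab("ps", ps_count(movie)$mean_count)
  fil <- if (movie$dims[3] > 1) grab("filament", filament_count(movie)$mean_elements)
         else grab("filament", stop("2D sheet: no filaments"))
  sv <- if (is.null(vlv)) NA_real_ else
    grab("sv", stroke_volume(vlv$vlv, vlv$time, aortic_flow = vlv$qao)$sv)
  amp <- if (is.null(tension)) NA_real_ else grab("amptens", amp_tens(tension))
  out <- data.frame(apd = apd, df = dfq, ps = psc, filament = fil,
                    sv = sv, amptens = amp)
  attr(out, "failures") <- fails
  out
}
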