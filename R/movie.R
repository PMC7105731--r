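## VoltageMovie: the space-time membrane-potential field on a regular grid,
## the common currency of all detectors. Frames are stored as an nt x nnode
## matrix with node index x-fastest (i = x + nx (y + ny z), 0-based spatial
## indices, node-centered coordinates x_mm = i_x * h).

#' Voltage movie container
#'
#' @param frames nt x nnode matrix of membrane potential (mV).
#' @param times frame times (ms), uniformly spaced.
#' @param dims grid dimensions `c(nx, ny, nz)` (nz = 1 for sheets).
#' @param h node spacing (mm).
#' @param ca optional nt x nnode matrix of cytosolic calcium (mM).
#' @param provenance free-form list recording protocol, parameters, seed.
#' @return an object of class `voltage_movie`.
#' @export
voltage_movie <- function(frames, times, dims, h, ca = NULL,
                          provenance = list()) {
  dims <- as.integer(dims)
  if (length(dims) == 2) dims <- c(dims, 1L)
  stopifnot(length(dims) == 3, ncol(frames) == prod(dims),
            nrow(frames) == length(times), h > 0)
  if (length(times) > 1) {
    dtv <- diff(times)
    if (max(abs(dtv - dtv[1])) > 1e-6) stop("frame times must be uniform")
  }
  if (!all(is.finite(frames))) stop("frames contain non-finite values")
  structure(list(frames = frames, times = times, dims = dims, h = h,
                 ca = ca, provenance = provenance),
            class = "voltage_movie")
}

#' @export
print.voltage_movie <- function(x, ...) {
  cat("<voltage_movie> ", paste(x$dims, collapse = "x"), " grid, h = ", x$h,
      " mm, ", nrow(x$frames), " frames @ ", frame_step(x), " ms\n", sep = "")
  invisible(x)
}

#' Frame cadence of a movie (ms)
#' @param movie a `voltage_movie`.
#' @export
frame_step <- function(movie) {
  if (length(movie$times) < 2) return(NA_real_)
  movie$times[2] - movie$times[1]
}

#' Linear node index from 0-based spatial indices
#' @param movie a `voltage_movie` (or anything with `$dims`).
#' @param ix,iy,iz 0-based spatial indices.
#' @return 1-based column index into the frame matrix.
#' @export
node_index <- function(movie, ix, iy, iz = 0) {
  d <- movie$dims
  1L + ix + d[1] * (iy + d[2] * iz)
}

#' Center node of the grid
#' @param movie a `voltage_movie`.
#' @export
center_node <- function(movie) {
  d <- movie$dims
  node_index(movie, d[1] %/% 2, d[2] %/% 2, d[3] %/% 2)
}

# one frame as an nx x ny (x nz) array
.frame_array <- function(movie, i) {
  d <- movie$dims
  a <- array(movie$frames[i, ], dim = d)
  if (d[3] == 1) dim(a) <- d[1:2]
  a
}

#' @export
plot.voltage_movie <- function(x, frame = nrow(x$frames), z = 1, ...) {
  a <- array(x$frames[frame, ], dim = x$dims)[, , z]
  image(seq_len(x$dims[1]) * x$h, seq_len(x$dims[2]) * x$h, a,
        xlab = "x (mm)", ylab = "y (mm)",
        main = sprintf("Vm at t = %g ms", x$times[frame]), ...)
  invisible(x)
}

#' Save / load a voltage movie
#'
#' Runtime persistence of the movie container (frames, times, grid geometry,
#' calcium, provenance).
#' @param movie a `voltage_movie`.
#' @param path file path.
#' @export
save_movie <- function(movie, path) { saveRDS(movie, path); invisible(path) }

#' @rdname save_movie
#' @export
load_movie <- function(path) {
  m <- readRDS(path)
  stopifnot(inherits(m, "voltage_movie"))
  m
}
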