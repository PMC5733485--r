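#' Uniformly sampled 3-D marker trajectories for one actor
#'
#' A `marker_series` stores positions (in metres) for a set of reflective
#' markers sampled at a fixed rate, together with a per-marker, per-frame
#' validity mask marking frames lost to occlusion or tracking failure.
#'
#' @param positions numeric array of dimension `frames x 3 x markers`
#'   (coordinates X, Y, Z in metres). A `frames x 3` matrix is accepted for a
#'   single marker.
#' @param sampling_rate_hz sampling rate in Hz (240 for the supported
#'   optical-capture regime).
#' @param t0 time of the first frame in seconds relative to the start of the
#'   recording. Frame `i` covers the half-open interval
#'   `[t0 + (i-1)/fs, t0 + i/fs)`.
#' @param valid logical matrix `frames x markers`; `FALSE` marks missing
#'   samples. Defaults to marking any frame with a non-finite coordinate
#'   invalid.
#' @param markers character vector of marker labels; defaults to dimnames of
#'   `positions` or `m1, m2, ...`.
#'
#' @return An object of class `marker_series`: a list with elements
#'   `positions`, `valid`, `sampling_rate_hz`, `t0`, `markers`.
#' @export
marker_series <- function(positions, sampling_rate_hz, t0 = 0, valid = NULL,
                          markers = NULL) {
  if (is.matrix(positions)) {
    positions <- array(positions, dim = c(nrow(positions), 3L, 1L))
  }
  if (!is.array(positions) || length(dim(positions)) != 3L || dim(positions)[2] != 3L) {
    stop("`positions` must be a frames x 3 x markers array", call. = FALSE)
  }
  if (!is.numeric(sampling_rate_hz) || length(sampling_rate_hz) != 1L ||
      sampling_rate_hz <= 0) {
    stop("`sampling_rate_hz` must be a positive scalar", call. = FALSE)
  }
  n <- dim(positions)[1]
  m <- dim(positions)[3]
  if (is.null(markers)) {
    markers <- dimnames(positions)[[3]]
    if (is.null(markers)) markers <- paste0("m", seq_len(m))
  }
  if (length(markers) != m) {
    stop("`markers` length does not match number of marker slices", call. = FALSE)
  }
  dimnames(positions) <- list(NULL, c("X", "Y", "Z"), markers)
  fin <- is.finite(positions)
  finite_ok <- fin[, 1L, , drop = FALSE] & fin[, 2L, , drop = FALSE] &
    fin[, 3L, , drop = FALSE]
  dim(finite_ok) <- c(n, m)
  if (is.null(valid)) {
    valid <- finite_ok
  }
  if (!is.matrix(valid) || nrow(valid) != n || ncol(valid) != m) {
    stop("`valid` must be a frames x markers logical matrix", call. = FALSE)
  }
  colnames(valid) <- markers
  if (any(valid & !finite_ok)) {
    stop("non-finite position marked valid", call. = FALSE)
  }
  structure(
    list(positions = positions, valid = valid,
         sampling_rate_hz = sampling_rate_hz, t0 = t0, markers = markers),
    class = "marker_series"
  )
}

#' @export
print.marker_series <- function(x, ...) {
  n <- dim(x$positions)[1]
  cat(sprintf(
    "<marker_series> %d markers x %d frames @ %g Hz (%.2f s from t0 = %.2f s)\n",
    length(x$markers), n, x$sampling_rate_hz, n / x$sampling_rate_hz, x$t0))
  cat(" markers:", paste(x$markers, collapse = ", "), "\n")
  frac <- 1 - mean(x$valid)
  cat(sprintf(" missing: %.2f%% of samples\n", 100 * frac))
  invisible(x)
}

n_frames <- function(mts) dim(mts$positions)[1]

#' Frame sample times of a marker series
#'
#' @param mts a [marker_series()].
#' @return numeric vector of frame start times in seconds.
#' @export
frame_times <- function(mts) {
  mts$t0 + (seq_len(n_frames(mts)) - 1L) / mts$sampling_rate_hz
}
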