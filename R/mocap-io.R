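#' Read a tab-separated marker trajectory file
#'
#' Parses the marker TSV dialect written by optical-capture exports and by
#' [write_marker_tsv()]: optional leading comment lines starting with `#`,
#' then a header row `frame<TAB>time<TAB><label>_X<TAB><label>_Y<TAB><label>_Z ...`,
#' one row per frame. Cells that are empty, non-numeric, or `NaN` are marked
#' invalid; a marker's frame is invalid if any of its three coordinates is.
#'
#' @param path file path.
#' @param sampling_rate_hz sampling rate in Hz of the recording.
#' @param unit unit of the coordinates in the file, `"mm"` (capture-system
#'   default) or `"m"`. Positions are converted to metres internally.
#' @param zero_is_missing if `TRUE`, frames where all three coordinates of a
#'   marker equal exactly 0 (a common capture-system fill value for lost
#'   markers) are marked invalid.
#' @return A [marker_series()].
#' @export
read_marker_tsv <- function(path, sampling_rate_hz, unit = c("mm", "m"),
                            zero_is_missing = FALSE) {
  unit <- match.arg(unit)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2L) stop(sprintf("%s: no data rows", path), call. = FALSE)
  hdr_line <- which(!startsWith(lines, "#"))[1]
  if (is.na(hdr_line)) {
    stop(sprintf("%s: no header row found", path), call. = FALSE)
  }
  header <- strsplit(lines[hdr_line], "\t", fixed = TRUE)[[1]]
  if (length(header) < 5L || header[1] != "frame" || header[2] != "time") {
    stop(sprintf("%s:%d: malformed header (expected 'frame', 'time', then <label>_X/_Y/_Z triplets)",
                 path, hdr_line), call. = FALSE)
  }
  coord_cols <- header[-(1:2)]
  if (length(coord_cols) %% 3L != 0L) {
    stop(sprintf("%s:%d: coordinate columns not in X/Y/Z triplets", path, hdr_line),
         call. = FALSE)
  }
  labels <- unique(sub("_[XYZ]$", "", coord_cols))
  expected <- as.vector(vapply(labels, function(l) paste0(l, c("_X", "_Y", "_Z")),
                               character(3)))
  if (!identical(coord_cols, expected)) {
    stop(sprintf("%s:%d: header columns are not consecutive <label>_X/_Y/_Z triplets",
                 path, hdr_line), call. = FALSE)
  }
  nf <- count.fields(path, sep = "\t", skip = hdr_line, comment.char = "",
                     blank.lines.skip = FALSE)
  # trailing empty cells are dropped by count.fields; only over-long rows are
  # unambiguously ragged
  if (any(nf > length(header), na.rm = TRUE)) {
    bad <- which(nf > length(header))[1]
    stop(sprintf("%s:%d: ragged row (%d fields, header has %d)",
                 path, hdr_line + bad, nf[bad], length(header)), call. = FALSE)
  }
  dat <- read.delim(path, header = TRUE, sep = "\t", skip = hdr_line - 1L,
                    comment.char = "", colClasses = "character",
                    check.names = FALSE, blank.lines.skip = FALSE)
  n <- nrow(dat)
  m <- length(labels)
  pos <- array(NA_real_, dim = c(n, 3L, m), dimnames = list(NULL, c("X", "Y", "Z"), labels))
  for (j in seq_along(labels)) {
    for (k in 1:3) {
      raw <- dat[[2L + (j - 1L) * 3L + k]]
      raw[is.null(raw)] <- NA_character_
      v <- suppressWarnings(as.numeric(raw))
      pos[, k, j] <- v
    }
  }
  scale <- if (unit == "mm") 1e-3 else 1
  pos <- pos * scale
  fin <- is.finite(pos)
  valid <- fin[, 1L, , drop = FALSE] & fin[, 2L, , drop = FALSE] & fin[, 3L, , drop = FALSE]
  dim(valid) <- c(n, m)
  if (zero_is_missing) {
    zr <- fin & (pos == 0)
    zero <- zr[, 1L, , drop = FALSE] & zr[, 2L, , drop = FALSE] & zr[, 3L, , drop = FALSE]
    dim(zero) <- c(n, m)
    valid <- valid & !zero
  }
  t0 <- suppressWarnings(as.numeric(dat[[2]][1]))
  if (!is.finite(t0)) t0 <- 0
  marker_series(pos, sampling_rate_hz, t0 = t0, valid = valid, markers = labels)
}

#' Write a marker series to the tab-separated trajectory dialect
#'
#' @param mts a [marker_series()].
#' @param path output path.
#' @param unit coordinate unit to write, `"mm"` or `"m"`.
#' @param digits decimal places written (6 in mm keeps nanometre precision).
#' @return `path`, invisibly.
#' @export
write_marker_tsv <- function(mts, path, unit = c("mm", "m"), digits = 6L) {
  unit <- match.arg(unit)
  scale <- if (unit == "mm") 1e3 else 1
  n <- n_frames(mts)
  m <- length(mts$markers)
  hdr <- c("frame", "time",
           as.vector(vapply(mts$markers,
                            function(l) paste0(l, c("_X", "_Y", "_Z")),
                            character(3))))
  cells <- matrix("", nrow = n, ncol = 3L * m)
  fmt <- paste0("%.", digits, "f")
  for (j in seq_len(m)) {
    for (k in 1:3) {
      col <- 3L * (j - 1L) + k
      v <- mts$positions[, k, j] * scale
      s <- sprintf(fmt, v)
      s[!mts$valid[, j] | !is.finite(v)] <- ""
      cells[, col] <- s
    }
  }
  tt <- sprintf("%.9f", frame_times(mts))
  rows <- paste(seq_len(n) - 1L, tt,
                apply(cells, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(sprintf("# dyadmotion marker export"),
               sprintf("# sampling_rate_hz: %g", mts$sampling_rate_hz),
               sprintf("# unit: %s", unit),
               paste(hdr, collapse = "\t"),
               rows), path)
  invisible(path)
}

#' Trim a marker series to a rated window
#'
#' The global interaction rating covers a fixed window (for the supported
#' study design: 3 min starting at 2 min for 4-month recordings, 5 min
#' starting at 2 min for 13-month recordings); motion features are computed
#' over the same window.
#'
#' @param mts a [marker_series()].
#' @param start_s window start in seconds on the recording's timeline.
#' @param duration_s window length in seconds.
#' @return A [marker_series()] covering `[start_s, start_s + duration_s)`
#'   exactly, with `t0 = start_s`.
#' @export
trim_to_window <- function(mts, start_s, duration_s) {
  fs <- mts$sampling_rate_hz
  n <- n_frames(mts)
  if (duration_s <= 0) stop("`duration_s` must be positive", call. = FALSE)
  i0 <- (start_s - mts$t0) * fs
  if (abs(i0 - round(i0)) > 1e-6 || abs(duration_s * fs - round(duration_s * fs)) > 1e-6) {
    stop("window must be frame-aligned at the sampling rate", call. = FALSE)
  }
  i0 <- round(i0)
  nw <- round(duration_s * fs)
  if (i0 < 0 || i0 + nw > n) {
    stop(sprintf("window [%g, %g) exceeds recording [%g, %g)",
                 start_s, start_s + duration_s, mts$t0, mts$t0 + n / fs),
         call. = FALSE)
  }
  idx <- (i0 + 1L):(i0 + nw)
  marker_series(mts$positions[idx, , , drop = FALSE], fs, t0 = start_s,
                valid = mts$valid[idx, , drop = FALSE], markers = mts$markers)
}

#' Fill missing samples by linear interpolation, enforcing the discard rule
#'
#' Missing runs are filled per coordinate by linear interpolation between the
#' flanking valid frames (runs touching the edges are filled by holding the
#' nearest valid frame). A series is only repaired when, for every marker,
#' missing time is below `max_missing_fraction` of the window; otherwise the
#' recording is rejected, mirroring the exclusion of dyads with excessive
#' marker loss.
#'
#' @param mts a [marker_series()].
#' @param max_missing_fraction maximum tolerated missing fraction per marker
#'   (default 0.05; the series is rejected when a marker reaches it).
#' @return A fully valid [marker_series()], or an object of class
#'   `mocap_rejection` (see [is_rejection()]) naming the offending marker and
#'   its missing fraction.
#' @export
interpolate_missing <- function(mts, max_missing_fraction = 0.05) {
  n <- n_frames(mts)
  frac <- colMeans(!mts$valid)
  worst <- which.max(frac)
  if (frac[worst] > 0 && frac[worst] >= max_missing_fraction) {
    return(structure(
      list(marker = mts$markers[worst],
           missing_fraction = unname(frac[worst]),
           reason = sprintf("marker '%s' missing %.1f%% of window (limit %.1f%%)",
                            mts$markers[worst], 100 * frac[worst],
                            100 * max_missing_fraction)),
      class = "mocap_rejection"))
  }
  if (any(colSums(mts$valid) == 0L)) {
    worst <- which(colSums(mts$valid) == 0L)[1]
    return(structure(
      list(marker = mts$markers[worst], missing_fraction = 1,
           reason = sprintf("marker '%s' has no valid frames", mts$markers[worst])),
      class = "mocap_rejection"))
  }
  if (all(mts$valid)) return(mts)
  pos <- mts$positions
  for (j in seq_along(mts$markers)) {
    ok <- mts$valid[, j]
    if (all(ok)) next
    xi <- which(ok)
    for (k in 1:3) {
      pos[, k, j] <- approx(x = xi, y = pos[xi, k, j], xout = seq_len(n),
                            method = "linear", rule = 2)$y
    }
  }
  marker_series(pos, mts$sampling_rate_hz, t0 = mts$t0,
                valid = matrix(TRUE, n, length(mts$markers)),
                markers = mts$markers)
}

#' Test whether a value is a missing-data rejection
#'
#' @param x an object, typically the return value of [interpolate_missing()].
#' @return `TRUE` for objects of class `mocap_rejection`.
#' @export
is_rejection <- function(x) inherits(x, "mocap_rejection")

#' @export
print.mocap_rejection <- function(x, ...) {
  cat("<mocap_rejection>", x$reason, "\n")
  invisible(x)
}

#' Zero-phase Butterworth low-pass filter
#'
#' Applies an order-`order` Butterworth low-pass filter forward and backward
#' (zero phase) to every coordinate of every marker. Zero-phase filtering is
#' used so that movement onsets, which feed the response-window coordination
#' features, are not delayed; the effective amplitude response is the squared
#' single-pass Butterworth magnitude `1 / (1 + (f / cutoff_hz)^(2 * order))`.
#'
#' @param mts a fully valid [marker_series()].
#' @param order filter order (default 4).
#' @param cutoff_hz cutoff frequency in Hz (default 10); must be below the
#'   Nyquist frequency.
#' @return A filtered [marker_series()] of identical dimensions.
#' @export
lowpass_filter <- function(mts, order = 4, cutoff_hz = 10) {
  fs <- mts$sampling_rate_hz
  if (cutoff_hz >= fs / 2) {
    stop(sprintf("`cutoff_hz` (%g) must be below the Nyquist frequency (%g)",
                 cutoff_hz, fs / 2), call. = FALSE)
  }
  if (!all(mts$valid)) {
    stop("series contains invalid frames; run interpolate_missing() first",
         call. = FALSE)
  }
  bf <- butter(order, cutoff_hz / (fs / 2), type = "low")
  pos <- mts$positions
  for (j in seq_along(mts$markers)) {
    for (k in 1:3) {
      x <- pos[, k, j]
      # filtfilt is exact for constants only up to round-off; remove the mean
      # first so near-static markers are preserved to tight tolerance
      mu <- mean(x)
      pos[, k, j] <- filtfilt(bf, x - mu) + mu
    }
  }
  marker_series(pos, fs, t0 = mts$t0, valid = mts$valid, markers = mts$markers)
}
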