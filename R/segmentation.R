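#' Movement segment list
#'
#' Ordered, disjoint, half-open movement intervals `[onset, offset)` in
#' seconds for one actor and body part, contained in a common analysis
#' window.
#'
#' @param onset,offset numeric vectors of interval bounds in seconds.
#' @param window length-2 numeric, `[start, end)` of the analysis window.
#' @param role,body_part optional annotations.
#' @return A data frame of class `movement_segments` with columns `onset`,
#'   `offset` and attributes `window`, `role`, `body_part`.
#' @export
movement_segments <- function(onset, offset, window, role = NA_character_,
                              body_part = NA_character_) {
  if (length(onset) != length(offset)) {
    stop("`onset` and `offset` differ in length", call. = FALSE)
  }
  if (length(window) != 2L || window[2] <= window[1]) {
    stop("`window` must be c(start, end) with end > start", call. = FALSE)
  }
  tol <- 1e-9
  if (length(onset)) {
    if (any(offset - onset <= 0)) stop("empty or negative-length segment", call. = FALSE)
    if (is.unsorted(onset, strictly = TRUE)) stop("segments not sorted", call. = FALSE)
    if (length(onset) > 1L && any(onset[-1] < offset[-length(offset)] - tol)) {
      stop("segments overlap", call. = FALSE)
    }
    if (min(onset) < window[1] - tol || max(offset) > window[2] + tol) {
      stop("segments extend outside the window", call. = FALSE)
    }
  }
  structure(
    data.frame(onset = as.numeric(onset), offset = as.numeric(offset)),
    window = as.numeric(window), role = role, body_part = body_part,
    class = c("movement_segments", "data.frame")
  )
}

seg_window <- function(segs) attr(segs, "window")

#' @export
print.movement_segments <- function(x, ...) {
  w <- seg_window(x)
  cat(sprintf("<movement_segments> %s/%s: %d segments in [%g, %g) s, moving %.1f%%\n",
              attr(x, "role"), attr(x, "body_part"), nrow(x), w[1], w[2],
              100 * sum(x$offset - x$onset) / diff(w)))
  invisible(x)
}

#' Spike-robust mean of an energy series
#'
#' Mean kinetic energy after excluding the sparse high-amplitude spikes
#' caused by impulsive movements: samples above the `spike_percentile`
#' percentile of the series are dropped before averaging. At percentile 100
#' this is the plain arithmetic mean.
#'
#' @param E an `energy_series` (see [kinetic_energy()]) or numeric vector.
#' @param spike_percentile percentile (0-100] above which samples are treated
#'   as spikes; default 99.
#' @return Mean energy in joules.
#' @export
robust_mean_energy <- function(E, spike_percentile = 99) {
  e <- if (inherits(E, "energy_series")) E$energy else as.numeric(E)
  if (length(e) == 0L) stop("empty energy series", call. = FALSE)
  if (spike_percentile <= 0 || spike_percentile > 100) {
    stop("`spike_percentile` must be in (0, 100]", call. = FALSE)
  }
  if (spike_percentile == 100) return(mean(e))
  cut <- quantile(e, spike_percentile / 100, names = FALSE, type = 7)
  mean(e[e <= cut])
}

#' Threshold segmentation of an energy series
#'
#' Frames whose energy strictly exceeds `threshold_fraction` times the
#' spike-robust mean energy are classified as moving; maximal runs of moving
#' frames become raw segments with frame-boundary times. Spikes, lying above
#' the threshold by definition, stay inside movement and do not perturb the
#' segmentation. The threshold is computed per series, i.e. per actor and
#' body part.
#'
#' @param E an `energy_series`.
#' @param threshold_fraction fraction of the robust mean energy used as the
#'   movement threshold (default 0.20).
#' @param spike_percentile passed to [robust_mean_energy()].
#' @param mean_energy optional externally supplied mean energy (e.g. a grand
#'   mean over a cohort); overrides the per-series robust mean.
#' @return A raw [movement_segments()] list. A series whose robust mean is 0
#'   (no movement at all) yields an empty list flagged with attribute
#'   `all_silent`.
#' @export
threshold_segment <- function(E, threshold_fraction = 0.20,
                              spike_percentile = 99, mean_energy = NULL) {
  stopifnot(inherits(E, "energy_series"))
  fs <- E$sampling_rate_hz
  n <- length(E$energy)
  window <- c(E$t0, E$t0 + n / fs)
  m <- if (is.null(mean_energy)) robust_mean_energy(E, spike_percentile) else mean_energy
  if (m <= 0) {
    out <- movement_segments(numeric(0), numeric(0), window,
                             role = E$role, body_part = E$body_part)
    attr(out, "all_silent") <- TRUE
    return(out)
  }
  thr <- threshold_fraction * m
  moving <- E$energy > thr
  r <- rle(moving)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  movement_segments(
    onset = E$t0 + (starts[keep] - 1L) / fs,
    offset = E$t0 + ends[keep] / fs,
    window = window, role = E$role, body_part = E$body_part
  )
}

#' Merge movements separated by short pauses
#'
#' Gaps shorter than `min_gap_s` (default 350 ms, the mean reaction time to
#' visual stimuli) between consecutive movements are closed left to right by
#' uniting the flanking segments. Gaps of exactly `min_gap_s` are kept. The
#' operation is idempotent.
#'
#' @param segs a [movement_segments()] list.
#' @param min_gap_s minimum pause duration to survive, seconds.
#' @return A merged [movement_segments()] list.
#' @export
merge_short_pauses <- function(segs, min_gap_s = 0.35) {
  if (nrow(segs) <= 1L) return(segs)
  tol <- 1e-9
  gap <- segs$onset[-1] - segs$offset[-nrow(segs)]
  grp <- cumsum(c(TRUE, gap >= min_gap_s - tol))
  movement_segments(
    onset = as.numeric(tapply(segs$onset, grp, min)),
    offset = as.numeric(tapply(segs$offset, grp, max)),
    window = seg_window(segs), role = attr(segs, "role"),
    body_part = attr(segs, "body_part")
  )
}

#' Discard movements shorter than a minimum duration
#'
#' Movements strictly shorter than `min_dur_s` (default 350 ms) are removed;
#' movements of exactly `min_dur_s` are kept. Applied after
#' [merge_short_pauses()], so two short bursts separated by a sub-threshold
#' pause survive as one merged movement.
#'
#' @param segs a merged [movement_segments()] list.
#' @param min_dur_s minimum movement duration, seconds.
#' @return A cleaned [movement_segments()] list.
#' @export
discard_short_movements <- function(segs, min_dur_s = 0.35) {
  tol <- 1e-9
  keep <- (segs$offset - segs$onset) >= min_dur_s - tol
  movement_segments(segs$onset[keep], segs$offset[keep], seg_window(segs),
                    role = attr(segs, "role"), body_part = attr(segs, "body_part"))
}

#' Full movement segmentation of an energy series
#'
#' Convenience chain: [threshold_segment()], then [merge_short_pauses()],
#' then [discard_short_movements()]. The cleaned output contains no segment
#' and no gap shorter than 350 ms (at the defaults).
#'
#' @inheritParams threshold_segment
#' @param min_gap_s,min_dur_s cleaning thresholds in seconds.
#' @return A cleaned [movement_segments()] list.
#' @export
segment_movements <- function(E, threshold_fraction = 0.20, min_gap_s = 0.35,
                              min_dur_s = 0.35, spike_percentile = 99,
                              mean_energy = NULL) {
  raw <- threshold_segment(E, threshold_fraction, spike_percentile, mean_energy)
  discard_short_movements(merge_short_pauses(raw, min_gap_s), min_dur_s)
}

#' Write movement segments as BED-like tab-separated text
#'
#' Columns: role, body_part, onset and offset in seconds (millisecond
#' precision or better).
#'
#' @param segs a [movement_segments()] list.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_segments_tsv <- function(segs, path) {
  df <- data.frame(role = attr(segs, "role"), body_part = attr(segs, "body_part"),
                   onset_s = sprintf("%.6f", segs$onset),
                   offset_s = sprintf("%.6f", segs$offset))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
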