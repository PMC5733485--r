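#' Specification of a synthetic mother-infant dyad
#'
#' Describes the generative model for one synthetic recording: each actor
#' alternates pauses and movement episodes; during an episode every marker of
#' the actor translates a fixed distance at constant speed along a fixed
#' direction (alternating sign, so positions stay bounded), which keeps the
#' kinetic-energy signal unambiguously above the segmentation threshold for
#' the whole episode and at zero outside it. Infant movements are optionally
#' anchored to mother movements: per mother episode, with probability `p_co`
#' the infant starts `latency` seconds after the mother's onset while she is
#' still moving (coactive), with probability `p_alt` it starts `latency`
#' seconds after her offset while she is still (alternating), and otherwise
#' deep inside her pause, outside the response window (independent). Sensor
#' noise is additive Gaussian per coordinate; spikes are single-sample
#' position jumps planted inside movement episodes (mimicking impulsive
#' movements); missing data are contiguous runs, as produced by marker
#' occlusion.
#'
#' All planted movement durations and inter-movement gaps are at least
#' 0.5 s, so ground truth passes the 350 ms merge/discard cleaning
#' unchanged.
#'
#' @param duration_s recording length, seconds.
#' @param sampling_rate_hz sampling rate, Hz (240, the supported capture
#'   regime).
#' @param seed integer seed; all generation is deterministic given the spec.
#' @param mother_movement_range,mother_pause_range uniform ranges (seconds)
#'   for the mother's episode and pause durations. When coupling is active
#'   the pause minimum must be at least 2.5 s and the movement minimum at
#'   least 1 s so every coupling label is geometrically realisable.
#' @param infant_movement_range uniform range for infant episode durations.
#' @param infant_pause_range pause range for the uncoupled infant renewal
#'   process (used only when `p_co + p_alt == 0`).
#' @param amplitude_m displacement of each episode, metres.
#' @param p_co,p_alt per-mother-episode probabilities of a coactive /
#'   alternating infant movement; `p_co + p_alt <= 1`.
#' @param latency_range_s uniform latency range, seconds, bounded by the
#'   1.5 s response window.
#' @param noise_sd_m additive Gaussian sensor noise per coordinate, metres.
#' @param spike_rate_per_min rate of single-sample position spikes.
#' @param spike_multiplier spike amplitude as a multiple of `amplitude_m`.
#' @param missing_fraction,missing_run_length_s contiguous-run missing-data
#'   model applied to both actors (0 disables).
#' @param mother_episodes,infant_episodes optional explicit episode tables
#'   (`onset`, `offset` in seconds) overriding the renewal processes.
#' @return A validated object of class `dyad_spec`.
#' @export
dyad_spec <- function(duration_s = 60, sampling_rate_hz = 240, seed = 1L,
                      mother_movement_range = c(1.0, 2.5),
                      mother_pause_range = c(2.5, 4.0),
                      infant_movement_range = c(0.5, 1.2),
                      infant_pause_range = mother_pause_range,
                      amplitude_m = 0.15,
                      p_co = 0.25, p_alt = 0.25,
                      latency_range_s = c(0.2, 1.2),
                      noise_sd_m = 5e-4,
                      spike_rate_per_min = 2, spike_multiplier = 5,
                      missing_fraction = 0, missing_run_length_s = 0.5,
                      mother_episodes = NULL, infant_episodes = NULL) {
  if (duration_s <= 0) stop_field("duration_s", "must be positive")
  if (sampling_rate_hz <= 0) stop_field("sampling_rate_hz", "must be positive")
  chk_range <- function(r, field, min_lo) {
    if (length(r) != 2L || any(!is.finite(r)) || r[1] > r[2] || r[1] < min_lo) {
      stop_field(field, sprintf("must be c(lo, hi) with hi >= lo >= %g", min_lo))
    }
  }
  chk_range(mother_movement_range, "mother_movement_range", 0.5)
  chk_range(mother_pause_range, "mother_pause_range", 0.5)
  chk_range(infant_movement_range, "infant_movement_range", 0.5)
  chk_range(infant_pause_range, "infant_pause_range", 0.5)
  if (p_co < 0 || p_alt < 0 || p_co + p_alt > 1 + 1e-12) {
    stop_field("p_co/p_alt", "must be nonnegative with p_co + p_alt <= 1")
  }
  coupled <- (p_co + p_alt) > 0 && is.null(infant_episodes)
  if (coupled && is.null(mother_episodes)) {
    if (mother_pause_range[1] < 2.5) {
      stop_field("mother_pause_range",
                 "minimum pause must be >= 2.5 s when coupling is active")
    }
    if (mother_movement_range[1] < 1.0) {
      stop_field("mother_movement_range",
                 "minimum movement must be >= 1 s when coupling is active")
    }
  }
  chk_range(latency_range_s, "latency_range_s", 0.05)
  if (latency_range_s[2] > 1.5) {
    stop_field("latency_range_s", "must be bounded by the 1.5 s response window")
  }
  if (amplitude_m <= 0) stop_field("amplitude_m", "must be positive")
  if (noise_sd_m < 0) stop_field("noise_sd_m", "must be >= 0")
  if (spike_rate_per_min < 0) stop_field("spike_rate_per_min", "must be >= 0")
  if (spike_multiplier < 0) stop_field("spike_multiplier", "must be >= 0")
  if (missing_fraction < 0 || missing_fraction >= 1) {
    stop_field("missing_fraction", "must be in [0, 1)")
  }
  if (missing_run_length_s <= 0) stop_field("missing_run_length_s", "must be positive")
  chk_eps <- function(ep, field) {
    if (is.null(ep)) return(invisible())
    if (!all(c("onset", "offset") %in% names(ep))) {
      stop_field(field, "must have onset and offset columns")
    }
    if (nrow(ep)) {
      if (any(ep$offset - ep$onset < 0.5 - 1e-9)) {
        stop_field(field, "planted episodes must last >= 0.5 s")
      }
      if (is.unsorted(ep$onset, strictly = TRUE) ||
          (nrow(ep) > 1L && any(ep$onset[-1] - ep$offset[-nrow(ep)] < 0.5 - 1e-9))) {
        stop_field(field, "episodes must be sorted with gaps >= 0.5 s")
      }
      if (min(ep$onset) < 0 || max(ep$offset) > duration_s) {
        stop_field(field, "episodes must lie inside [0, duration_s)")
      }
    }
  }
  chk_eps(mother_episodes, "mother_episodes")
  chk_eps(infant_episodes, "infant_episodes")
  structure(
    list(duration_s = duration_s, sampling_rate_hz = sampling_rate_hz,
         seed = as.integer(seed),
         mother_movement_range = mother_movement_range,
         mother_pause_range = mother_pause_range,
         infant_movement_range = infant_movement_range,
         infant_pause_range = infant_pause_range,
         amplitude_m = amplitude_m, p_co = p_co, p_alt = p_alt,
         latency_range_s = latency_range_s, noise_sd_m = noise_sd_m,
         spike_rate_per_min = spike_rate_per_min,
         spike_multiplier = spike_multiplier,
         missing_fraction = missing_fraction,
         missing_run_length_s = missing_run_length_s,
         mother_episodes = mother_episodes, infant_episodes = infant_episodes),
    class = "dyad_spec")
}

# Alternating pause/movement renewal process; keeps a trailing margin so the
# last episode never touches the window end.
renewal_episodes <- function(duration_s, pause_range, movement_range,
                             margin = 0.5) {
  t <- runif(1, pause_range[1], pause_range[2])
  onset <- numeric(0)
  offset <- numeric(0)
  repeat {
    d <- runif(1, movement_range[1], movement_range[2])
    if (t + d > duration_s - margin) break
    onset <- c(onset, t)
    offset <- c(offset, t + d)
    t <- t + d + runif(1, pause_range[1], pause_range[2])
  }
  data.frame(onset = onset, offset = offset)
}

runif1 <- function(lo, hi) {
  if (hi <= lo) return(lo)
  runif(1, lo, hi)
}

# One infant movement candidate per mother episode, anchored per its drawn
# coupling label; geometric margins guarantee every candidate survives the
# 0.5 s duration/gap floors except at the window end.
infant_coupled_episodes <- function(mother, duration_s, spec) {
  lr <- spec$latency_range_s
  onset <- numeric(0)
  lat <- numeric(0)
  label <- character(0)
  n_m <- nrow(mother)
  for (k in seq_len(n_m)) {
    m_on <- mother$onset[k]
    m_off <- mother$offset[k]
    next_on <- if (k < n_m) mother$onset[k + 1L] else duration_s
    u <- runif(1)
    if (u < spec$p_co) {
      hi <- min(lr[2], m_off - m_on - 0.2)
      l <- runif1(min(lr[1], hi), hi)
      onset <- c(onset, m_on + l); lat <- c(lat, l); label <- c(label, "coactive")
    } else if (u < spec$p_co + spec$p_alt) {
      hi <- min(lr[2], 1.4)
      l <- runif1(min(max(lr[1], 0.1), hi), hi)
      onset <- c(onset, m_off + l); lat <- c(lat, l); label <- c(label, "alternating")
    } else {
      lo <- m_off + 1.6
      hi <- next_on - 0.8
      if (hi <= lo + 1e-9) next
      onset <- c(onset, runif(1, lo, hi)); lat <- c(lat, NA_real_)
      label <- c(label, "independent")
    }
  }
  dur <- runif(length(onset), spec$infant_movement_range[1],
               spec$infant_movement_range[2])
  offset <- onset + dur
  n <- length(onset)
  if (n > 1L) {
    offset[-n] <- pmin(offset[-n], onset[-1] - 0.5)
  }
  offset <- pmin(offset, duration_s - 0.2)
  keep <- (offset - onset) >= 0.5 - 1e-9
  data.frame(onset = onset[keep], offset = offset[keep],
             label = label[keep], latency = lat[keep],
             stringsAsFactors = FALSE)
}

#' Coupling labels implied by two episode lists
#'
#' Classifies each infant onset against the mother's episodes by the
#' response-window definitions: coactive when the onset falls inside a mother
#' episode at most `response_window_s` after its onset, alternating when it
#' falls in a pause at most `response_window_s` after the preceding offset,
#' independent otherwise.
#'
#' @param infant_onsets numeric vector of onsets, seconds.
#' @param mother episode data frame (`onset`, `offset`).
#' @param response_window_s latency bound, seconds.
#' @return Character vector of labels.
#' @export
coupling_labels <- function(infant_onsets, mother, response_window_s = 1.5) {
  tol <- 1e-9
  vapply(infant_onsets, function(t_on) {
    idx <- findInterval(t_on, mother$onset)
    if (idx < 1L) return("independent")
    if (t_on < mother$offset[idx] - tol) {
      if (t_on - mother$onset[idx] <= response_window_s + tol) "coactive"
      else "independent"
    } else if (t_on - mother$offset[idx] <= response_window_s + tol) {
      "alternating"
    } else {
      "independent"
    }
  }, character(1))
}

# Anatomical-ish marker layout (metres); arbitrary rigid offsets, since the
# generator translates the whole marker set rigidly.
actor_layout <- function(role) {
  base <- rbind(
    head = c(0, 0, 0.60),
    wrist_l = c(-0.25, 0.30, 0.20), wrist_r = c(0.25, 0.30, 0.20),
    elbow_l = c(-0.30, 0.15, 0.35), elbow_r = c(0.30, 0.15, 0.35),
    shoulder_l = c(-0.20, 0, 0.50), shoulder_r = c(0.20, 0, 0.50))
  if (role == "infant") base <- 0.5 * base + matrix(c(0, 0.8, 0), 7, 3, byrow = TRUE)
  base
}

build_actor_series <- function(episodes, spec, role) {
  fs <- spec$sampling_rate_hz
  n <- round(spec$duration_s * fs)
  tt <- (seq_len(n) - 1L) / fs
  # scalar displacement profile: constant-speed ramp of amplitude_m per
  # episode, direction sign alternating so positions stay bounded
  s <- numeric(n)
  base_disp <- 0
  sgn <- 1
  for (k in seq_len(nrow(episodes))) {
    on <- episodes$onset[k]
    off <- episodes$offset[k]
    idx <- which(tt >= on & tt < off)
    s[idx] <- base_disp + sgn * spec$amplitude_m * (tt[idx] - on) / (off - on)
    base_disp <- base_disp + sgn * spec$amplitude_m
    after <- tt >= off
    s[after] <- base_disp
    sgn <- -sgn
  }
  u <- rnorm(3)
  u <- u / sqrt(sum(u^2))
  layout <- actor_layout(role)
  pos <- array(0, dim = c(n, 3L, nrow(layout)),
               dimnames = list(NULL, c("X", "Y", "Z"), rownames(layout)))
  for (m in seq_len(nrow(layout))) {
    for (c3 in 1:3) {
      pos[, c3, m] <- layout[m, c3] + u[c3] * s
    }
  }
  if (spec$noise_sd_m > 0) {
    pos <- pos + array(rnorm(length(pos), sd = spec$noise_sd_m), dim = dim(pos))
  }
  if (spec$spike_rate_per_min > 0 && spec$spike_multiplier > 0 &&
      nrow(episodes) > 0L) {
    n_spikes <- rpois(1, spec$spike_rate_per_min * spec$duration_s / 60)
    moving <- rep(FALSE, n)
    for (k in seq_len(nrow(episodes))) {
      moving[tt >= episodes$onset[k] & tt < episodes$offset[k]] <- TRUE
    }
    mov_idx <- which(moving)
    if (n_spikes > 0L && length(mov_idx) > 0L) {
      frames <- sample(mov_idx, min(n_spikes, length(mov_idx)))
      for (f in frames) {
        m <- sample.int(nrow(layout), 1L)
        d <- rnorm(3)
        d <- d / sqrt(sum(d^2))
        pos[f, , m] <- pos[f, , m] + spec$spike_multiplier * spec$amplitude_m * d
      }
    }
  }
  marker_series(pos, fs, t0 = 0, markers = rownames(layout))
}

#' Generate one synthetic dyad with ground truth
#'
#' Draws mother and infant movement episodes (see [dyad_spec()]), builds the
#' corresponding marker trajectories, and returns them together with the
#' planted ground truth: the true movement intervals per actor and, for every
#' infant movement, its coupling label and the latency used. Output is
#' deterministic given the spec (including its seed).
#'
#' @param spec a [dyad_spec()].
#' @param trajectories if `FALSE`, skip building marker series and return
#'   ground truth only (fast path for coupling statistics at scale).
#' @return A list of class `dyad`: `mother` and `infant` ([marker_series()]
#'   or `NULL`), `truth` (list with `mother` and `infant` episode tables, the
#'   infant's carrying `label` and `latency` columns), and `spec`.
#' @export
generate_dyad <- function(spec, trajectories = TRUE) {
  stopifnot(inherits(spec, "dyad_spec"))
  fs <- spec$sampling_rate_hz
  # episode bounds are snapped to the frame grid so ground-truth intervals
  # are unambiguous at the sampling resolution
  snap <- function(ep) {
    ep$onset <- round(ep$onset * fs) / fs
    ep$offset <- round(ep$offset * fs) / fs
    ep
  }
  with_seed(spec$seed, {
    mother_eps <- if (!is.null(spec$mother_episodes)) {
      as.data.frame(spec$mother_episodes)
    } else {
      renewal_episodes(spec$duration_s, spec$mother_pause_range,
                       spec$mother_movement_range)
    }
    mother_eps <- snap(mother_eps)
    if (!is.null(spec$infant_episodes)) {
      inf <- as.data.frame(spec$infant_episodes)
      inf$label <- coupling_labels(inf$onset, mother_eps)
      inf$latency <- rep(NA_real_, nrow(inf))
      infant_eps <- inf
    } else if (spec$p_co + spec$p_alt > 0) {
      infant_eps <- infant_coupled_episodes(mother_eps, spec$duration_s, spec)
    } else {
      inf <- renewal_episodes(spec$duration_s, spec$infant_pause_range,
                              spec$infant_movement_range)
      inf$label <- coupling_labels(inf$onset, mother_eps)
      inf$latency <- rep(NA_real_, nrow(inf))
      infant_eps <- inf
    }
    infant_eps <- snap(infant_eps)
    mother_ms <- infant_ms <- NULL
    if (trajectories) {
      mother_ms <- build_actor_series(mother_eps, spec, "mother")
      infant_ms <- build_actor_series(infant_eps, spec, "infant")
      if (spec$missing_fraction > 0) {
        seeds <- sample.int(2^30, 2L)
        mother_ms <- inject_missing(mother_ms, spec$missing_fraction,
                                    spec$missing_run_length_s, seeds[1])
        infant_ms <- inject_missing(infant_ms, spec$missing_fraction,
                                    spec$missing_run_length_s, seeds[2])
      }
    }
    structure(
      list(mother = mother_ms, infant = infant_ms,
           truth = list(mother = mother_eps,
                        infant = infant_eps),
           spec = spec),
      class = "dyad")
  })
}

#' @export
print.dyad <- function(x, ...) {
  cat(sprintf("<dyad> %g s @ %g Hz; mother %d movements, infant %d movements\n",
              x$spec$duration_s, x$spec$sampling_rate_hz,
              nrow(x$truth$mother), nrow(x$truth$infant)))
  if (nrow(x$truth$infant)) {
    cat(" infant labels:",
        paste(sprintf("%s=%d", names(table(x$truth$infant$label)),
                      as.integer(table(x$truth$infant$label))), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Invalidate contiguous runs of samples to emulate marker occlusion
#'
#' Per marker, approximately `missing_fraction` of the series is invalidated
#' in contiguous runs of `run_length_s` seconds (total invalid time is within
#' one run length of the request). Runs are placed in disjoint random
#' positions; invalidated positions are set to `NA`.
#'
#' @param mts a [marker_series()].
#' @param missing_fraction fraction of the duration to invalidate, in
#'   `[0, 1)`.
#' @param run_length_s length of each missing run, seconds.
#' @param seed integer seed for run placement.
#' @return A [marker_series()] with an updated validity mask.
#' @export
inject_missing <- function(mts, missing_fraction, run_length_s, seed = 1L) {
  if (missing_fraction < 0 || missing_fraction >= 1) {
    stop_field("missing_fraction", "must be in [0, 1)")
  }
  if (missing_fraction == 0) return(mts)
  n <- n_frames(mts)
  fs <- mts$sampling_rate_hz
  rf <- max(1L, round(run_length_s * fs))
  n_runs <- round(missing_fraction * n / rf)
  if (n_runs == 0L) return(mts)
  n_blocks <- n %/% (2L * rf)
  if (n_runs > n_blocks) {
    stop("missing_fraction too high for this run length", call. = FALSE)
  }
  pos <- mts$positions
  valid <- mts$valid
  with_seed(seed, {
    for (j in seq_along(mts$markers)) {
      blocks <- sample.int(n_blocks, n_runs)
      for (b in blocks) {
        start <- (b - 1L) * 2L * rf + sample.int(rf, 1L)
        idx <- start:(start + rf - 1L)
        valid[idx, j] <- FALSE
        pos[idx, , j] <- NA_real_
      }
    }
  })
  marker_series(pos, fs, t0 = mts$t0, valid = valid, markers = mts$markers)
}

#' Write a dyad's trajectories and ground truth to disk
#'
#' Marker trajectories are written in the TSV dialect read by
#' [read_marker_tsv()]; ground truth as a sidecar JSON with intervals in
#' seconds and coupling labels.
#'
#' @param dyad a [generate_dyad()] result.
#' @param dir output directory (created if needed).
#' @param stem file-name stem.
#' @return Named character vector of the paths written, invisibly.
#' @export
write_dyad <- function(dyad, dir, stem = "dyad") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    mother = file.path(dir, paste0(stem, "_mother.tsv")),
    infant = file.path(dir, paste0(stem, "_infant.tsv")),
    truth = file.path(dir, paste0(stem, "_truth.json")))
  write_marker_tsv(dyad$mother, paths[["mother"]])
  write_marker_tsv(dyad$infant, paths[["infant"]])
  jsonlite::write_json(dyad$truth, paths[["truth"]], digits = NA, dataframe = "columns")
  invisible(paths)
}
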