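# Randomized segment-list builders and independent oracles used across tests.

# Sorted, disjoint list with durations and gaps >= 0.4 s (survives cleaning).
random_clean_segments <- function(window = c(0, 60)) {
  t <- window[1] + runif(1, 0, 2)
  on <- numeric(0)
  off <- numeric(0)
  repeat {
    d <- runif(1, 0.4, 2.5)
    if (t + d > window[2]) break
    on <- c(on, t)
    off <- c(off, t + d)
    t <- t + d + 0.4 + runif(1, 0, 3)
    if (t >= window[2]) break
  }
  movement_segments(on, off, window)
}

# Raw-style list: still sorted/disjoint but with arbitrarily short segments
# and gaps, as threshold output can produce.
random_raw_segments <- function(window = c(0, 30)) {
  t <- window[1] + runif(1, 0, 0.3)
  on <- numeric(0)
  off <- numeric(0)
  repeat {
    d <- runif(1, 0.02, 1.2)
    if (t + d > window[2]) break
    on <- c(on, t)
    off <- c(off, t + d)
    t <- t + d + runif(1, 0.02, 1.0)
    if (t >= window[2]) break
  }
  movement_segments(on, off, window)
}

# Grid-sampling oracle for the time-share features: membership indicators on
# a fine time grid, independent of the package's interval arithmetic.
grid_time_shares <- function(infant, mother, dt = 1e-3) {
  w <- attr(infant, "window")
  tt <- seq(w[1] + dt / 2, w[2], by = dt)
  inm <- rep(FALSE, length(tt))
  mom <- rep(FALSE, length(tt))
  for (i in seq_len(nrow(infant))) {
    inm[tt >= infant$onset[i] & tt < infant$offset[i]] <- TRUE
  }
  for (i in seq_len(nrow(mother))) {
    mom[tt >= mother$onset[i] & tt < mother$offset[i]] <- TRUE
  }
  list(infant_activity = mean(inm), maternal_activity = mean(mom),
       overlap = mean(inm & mom), silence = mean(!inm & !mom))
}

truth_segments <- function(dyad, actor) {
  tr <- dyad$truth[[actor]]
  movement_segments(tr$onset, tr$offset, c(0, dyad$spec$duration_s),
                    role = actor)
}

# Unfiltered stage chain: trajectories -> CoM speeds -> energy -> cleaned
# segments (the zero-noise path, where there is nothing for the low-pass
# filter to remove).
segments_from_trajectories <- function(dyad, actor, model,
                                       body_part = "upper_body") {
  sp <- segment_com_speed(dyad[[actor]], model)
  E <- kinetic_energy(sp, model, body_part)
  segment_movements(E)
}
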