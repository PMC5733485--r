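energy_of <- function(e, fs = 240, t0 = 0) {
  structure(list(energy = e, sampling_rate_hz = fs, t0 = t0,
                 body_part = "upper_body", role = "mother"),
            class = "energy_series")
}

test_that("robust mean excludes sparse spikes and degrades to the plain mean", {
  expect_equal(robust_mean_energy(energy_of(rep(2.5, 500))), 2.5)
  e <- c(rep(1, 1000), rep(1000, 5))
  expect_equal(robust_mean_energy(energy_of(e), 99), 1, tolerance = 1e-12)
  expect_equal(robust_mean_energy(energy_of(e), 100), mean(e))
  expect_error(robust_mean_energy(energy_of(numeric(0))), "empty")
})

test_that("threshold segmentation recovers square-wave runs exactly", {
  fs <- 10
  e <- rep(c(0, 1, 0, 1, 0), times = c(10, 20, 15, 5, 10))
  segs <- threshold_segment(energy_of(e, fs))
  expect_equal(segs$onset, c(1.0, 4.5))
  expect_equal(segs$offset, c(3.0, 5.0))
  # all-zero energy: flagged all-silent, no segments
  s0 <- threshold_segment(energy_of(rep(0, 50), fs))
  expect_equal(nrow(s0), 0)
  expect_true(isTRUE(attr(s0, "all_silent")))
  # frames exactly at the threshold count as silence (strict inequality)
  et <- energy_of(c(rep(1, 50), rep(0.2, 10), rep(1, 40)), fs)
  m <- robust_mean_energy(et)
  s1 <- threshold_segment(et, threshold_fraction = 0.2 / m)
  expect_equal(nrow(s1), 2)
})

test_that("merge closes only sub-350 ms pauses, left to right", {
  w <- c(0, 10)
  m1 <- merge_short_pauses(movement_segments(c(0, 1.2), c(1.0, 2.0), w))
  expect_equal(unname(as.matrix(m1[, 1:2])), cbind(0, 2.0))
  m2 <- merge_short_pauses(movement_segments(c(0, 1.4), c(1.0, 2.0), w))
  expect_equal(nrow(m2), 2)  # gap 0.4 s >= 0.35 survives
  m3 <- merge_short_pauses(movement_segments(c(0, 1.35), c(1.0, 2.0), w))
  expect_equal(nrow(m3), 2)  # exactly 350 ms is kept
  chain <- merge_short_pauses(
    movement_segments(c(0, 0.6, 1.2), c(0.5, 1.1, 1.7), w))
  expect_equal(unname(as.matrix(chain[, 1:2])), cbind(0, 1.7))
})

test_that("discard removes strictly sub-350 ms movements", {
  w <- c(0, 10)
  expect_equal(nrow(discard_short_movements(movement_segments(5.0, 5.3, w))), 0)
  expect_equal(nrow(discard_short_movements(movement_segments(5.0, 5.35, w))), 1)
  only_short <- movement_segments(c(1, 2, 3), c(1.2, 2.1, 3.3), w)
  expect_equal(nrow(discard_short_movements(only_short)), 0)
})

test_that("cleaning postconditions hold and cleaning is idempotent on random input", {
  set.seed(301)
  for (i in 1:200) {
    raw <- random_raw_segments()
    cleaned <- discard_short_movements(merge_short_pauses(raw))
    if (nrow(cleaned)) {
      expect_true(all(cleaned$offset - cleaned$onset >= 0.35 - 1e-9))
      if (nrow(cleaned) > 1) {
        gaps <- cleaned$onset[-1] - cleaned$offset[-nrow(cleaned)]
        expect_true(all(gaps >= 0.35 - 1e-9))
      }
    }
    again <- discard_short_movements(merge_short_pauses(cleaned))
    expect_identical(again$onset, cleaned$onset)
    expect_identical(again$offset, cleaned$offset)
  }
})

test_that("segments are invariant to a uniform energy rescaling", {
  d <- generate_dyad(dyad_spec(duration_s = 20, seed = 21, noise_sd_m = 0,
                               spike_rate_per_min = 0))
  model <- default_segment_models("13m")$mother
  E <- kinetic_energy(segment_com_speed(d$mother, model), model, "upper_body")
  s1 <- segment_movements(E)
  for (c_scale in c(1e-3, 7, 1e4)) {
    E2 <- E
    E2$energy <- c_scale * E$energy
    s2 <- segment_movements(E2)
    expect_equal(s2$onset, s1$onset)
    expect_equal(s2$offset, s1$offset)
  }
})

test_that("zero-noise synthetic dyads are recovered within one sample per boundary", {
  models <- default_segment_models("13m")
  for (s in 1:10) {
    d <- generate_dyad(dyad_spec(duration_s = 60, seed = s, p_co = 0.3,
                                 p_alt = 0.3, noise_sd_m = 0,
                                 spike_rate_per_min = 0))
    for (actor in c("mother", "infant")) {
      got <- segments_from_trajectories(d, actor, models[[actor]])
      tr <- d$truth[[actor]]
      expect_equal(nrow(got), nrow(tr))
      err <- max(abs(c(got$onset - tr$onset, got$offset - tr$offset)))
      expect_lte(err, 1 / 240 + 1e-9)
    }
  }
})

test_that("spikes inside movement shift neither the robust mean nor boundaries", {
  d <- generate_dyad(dyad_spec(duration_s = 60, seed = 31, noise_sd_m = 0,
                               spike_rate_per_min = 0))
  model <- default_segment_models("13m")$mother
  E <- kinetic_energy(segment_com_speed(d$mother, model), model, "upper_body")
  m0 <- robust_mean_energy(E)
  s0 <- segment_movements(E)
  tt <- d$truth$mother
  set.seed(1)
  moving <- which(sapply(frame_times(d$mother), function(t)
    any(t >= tt$onset & t < tt$offset)))
  E2 <- E
  E2$energy[sample(moving, 5)] <- 1000 * m0
  expect_lt(abs(robust_mean_energy(E2) - m0) / m0, 0.01)
  s2 <- segment_movements(E2)
  expect_equal(nrow(s2), nrow(s0))
  expect_lte(max(abs(c(s2$onset - s0$onset, s2$offset - s0$offset))), 1 / 240)
})

test_that("segment lists serialize to readable tab-separated text", {
  segs <- movement_segments(c(0.5, 2), c(1.5, 3), c(0, 10),
                            role = "mother", body_part = "arms")
  p <- tempfile(fileext = ".tsv")
  write_segments_tsv(segs, p)
  back <- read.delim(p)
  expect_equal(back$onset_s, c(0.5, 2))
  expect_equal(back$role, c("mother", "mother"))
})
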