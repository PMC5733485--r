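seg <- function(on, off, w = c(0, 300)) movement_segments(on, off, w)

test_that("activity, overlap and silence ratios match interval arithmetic", {
  w <- c(0, 300)
  expect_equal(activity_ratio(seg(0, 300)), 1.0)
  expect_equal(activity_ratio(seg(numeric(0), numeric(0))), 0.0)
  expect_equal(activity_ratio(seg(c(0, 60), c(30, 90))), 0.2)
  expect_error(activity_ratio(seg(1, 2), window = c(5, 5)), "window")

  a <- seg(c(0, 60), c(30, 90))
  expect_equal(overlap_ratio(a, a), activity_ratio(a))
  expect_equal(overlap_ratio(seg(0, 100), seg(150, 250)), 0)
  expect_equal(overlap_ratio(seg(0, 100), seg(50, 150)), 50 / 300)

  expect_equal(silence_ratio(seg(numeric(0), numeric(0)),
                             seg(numeric(0), numeric(0))), 1.0)
  expect_equal(silence_ratio(seg(0, 200), seg(150, 300)), 0.0)
  expect_error(overlap_ratio(seg(0, 1), movement_segments(0, 1, c(0, 200))),
               "window")
})

test_that("inclusion-exclusion identity holds on random segment pairs", {
  set.seed(401)
  for (i in 1:100) {
    w <- c(0, 60)
    inf <- random_clean_segments(w)
    mot <- random_clean_segments(w)
    lhs <- activity_ratio(inf) + activity_ratio(mot) -
      overlap_ratio(inf, mot) + silence_ratio(inf, mot)
    expect_equal(lhs, 1, tolerance = 1e-9)
    # grid-sampling oracle for the individual shares
    g <- grid_time_shares(inf, mot)
    expect_equal(overlap_ratio(inf, mot), g$overlap, tolerance = 2e-3)
    expect_equal(silence_ratio(inf, mot), g$silence, tolerance = 2e-3)
  }
})

test_that("coactive onsets require a moving partner within the response window", {
  w <- c(0, 60)
  partner <- seg(0, 5, w)
  expect_equal(coactive_onset_ratio(seg(1.0, 2.0, w), partner), 1.0)
  expect_equal(coactive_onset_ratio(seg(3.0, 4.0, w), partner), 0.0) # 3 s > 1.5 s
  expect_equal(coactive_onset_ratio(seg(1.5, 2.5, w), partner), 1.0) # bound inclusive
  expect_equal(coactive_onset_ratio(seg(6.0, 7.0, w), partner), 0.0) # partner still
  # simultaneous onsets count by default, excluded on request
  expect_equal(coactive_onset_ratio(seg(0, 1, w), partner), 1.0)
  expect_equal(coactive_onset_ratio(seg(0, 1, w), partner,
                                    include_simultaneous_onset = FALSE), 0.0)
  # reference is the containing segment's own onset, not an earlier one
  partner2 <- seg(c(0, 3), c(1, 8), w)
  expect_equal(coactive_onset_ratio(seg(4.0, 5, w), partner2), 1.0)
})

test_that("alternating onsets require a still partner shortly after its offset", {
  w <- c(0, 60)
  partner <- seg(0, 5, w)
  expect_equal(alternating_onset_ratio(seg(6.0, 7.0, w), partner), 1.0)
  expect_equal(alternating_onset_ratio(seg(7.0, 8.0, w), partner), 0.0) # 2 s > 1.5 s
  expect_equal(alternating_onset_ratio(seg(6.5, 7.5, w), partner), 1.0) # bound inclusive
  expect_equal(alternating_onset_ratio(seg(1.0, 2.0, w), partner), 0.0) # partner moving
  # an onset before any partner movement has no preceding offset
  expect_equal(alternating_onset_ratio(seg(1, 2, w), seg(10, 15, w)), 0.0)
})

test_that("empty target lists yield a reasoned missing value, not zero", {
  w <- c(0, 60)
  r <- coactive_onset_ratio(seg(numeric(0), numeric(0), w), seg(0, 5, w))
  expect_true(is.na(r))
  expect_match(attr(r, "reason"), "no movements")
  r2 <- alternating_onset_ratio(seg(numeric(0), numeric(0), w), seg(0, 5, w))
  expect_true(is.na(r2))
})

test_that("no onset is both coactive and alternating (partner state partitions)", {
  set.seed(402)
  for (i in 1:50) {
    w <- c(0, 60)
    target <- random_clean_segments(w)
    partner <- random_clean_segments(w)
    if (nrow(target) == 0) next
    co <- vapply(target$onset, function(t)
      coactive_onset_ratio(movement_segments(t, t + 0.5, w), partner), numeric(1))
    al <- vapply(target$onset, function(t)
      alternating_onset_ratio(movement_segments(t, t + 0.5, w), partner), numeric(1))
    expect_true(all(co + al <= 1))
  }
})

test_that("features are invariant to a common time shift", {
  set.seed(403)
  w <- c(0, 60)
  inf <- random_clean_segments(w)
  mot <- random_clean_segments(w)
  delta <- 13.7
  shift <- function(s) movement_segments(s$onset + delta, s$offset + delta,
                                         w + delta)
  f1 <- motion_features(inf, mot)
  f2 <- motion_features(shift(inf), shift(mot))
  expect_equal(unlist(f2), unlist(f1), tolerance = 1e-9)
})

test_that("planted coupling probabilities are recovered within binomial error", {
  n_co <- 0
  n_tot <- 0
  for (s in 1:60) {
    d <- generate_dyad(dyad_spec(duration_s = 60, seed = s, p_co = 0.6,
                                 p_alt = 0.2), trajectories = FALSE)
    w <- c(0, 60)
    inf <- truth_segments(d, "infant")
    mot <- truth_segments(d, "mother")
    r <- coactive_onset_ratio(inf, mot)
    n_co <- n_co + r * nrow(inf)
    n_tot <- n_tot + nrow(inf)
  }
  phat <- n_co / n_tot
  expect_lt(abs(phat - 0.6), 3 * sqrt(0.6 * 0.4 / n_tot))
})

test_that("the feature table matches per-dyad calls and propagates missingness", {
  set.seed(404)
  w <- c(0, 60)
  mk_set <- function(id) {
    list(dyad_id = id,
         infant = list(upper_body = random_clean_segments(w),
                       arms = random_clean_segments(w),
                       head = random_clean_segments(w)),
         mother = list(upper_body = random_clean_segments(w),
                       arms = random_clean_segments(w),
                       head = random_clean_segments(w)))
  }
  sets <- list(mk_set("a"), mk_set("b"))
  tab <- extract_feature_table(sets)
  expect_equal(dim(tab), c(6, 10))
  expect_equal(tab$body_part, rep(c("upper_body", "arms", "head"), 2))
  i <- which(tab$dyad_id == "b" & tab$body_part == "arms")
  single <- motion_features(sets[[2]]$infant$arms, sets[[2]]$mother$arms)
  expect_equal(as.numeric(tab[i, motion_feature_names()]),
               as.numeric(unlist(single)))
  # empty infant list: activity 0, onset ratios missing, logged
  sets[[1]]$infant$arms <- movement_segments(numeric(0), numeric(0), w)
  tab2 <- extract_feature_table(sets)
  j <- which(tab2$dyad_id == "a" & tab2$body_part == "arms")
  expect_equal(tab2$infant_activity_ratio[j], 0)
  expect_true(is.na(tab2$infant_coactive_onset_ratio[j]))
  expect_true(is.na(tab2$infant_alternating_onset_ratio[j]))
  expect_false(is.na(tab2$maternal_activity_ratio[j]))
  expect_match(paste(attr(tab2, "log"), collapse = ";"), "no movements")
  # dyad lacking a body part: row kept with missing cells
  sets[[1]]$infant$head <- NULL
  tab3 <- extract_feature_table(sets)
  k <- which(tab3$dyad_id == "a" & tab3$body_part == "head")
  expect_true(all(is.na(tab3[k, motion_feature_names()])))
})
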