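#' Generate a cohort of dyads with a planted feature-composite correlation
#'
#' Creates `n_dyads` synthetic dyads whose generative parameters vary
#' monotonically across the cohort (pause durations for the activity, overlap
#' and silence features; coupling probabilities for the onset features), runs
#' the full extraction pipeline on each, and synthesises a composite score
#' whose population Spearman correlation with the extracted target feature
#' equals `planted_rho`.
#'
#' The composite is built through a Gaussian copula on the extracted-feature
#' ranks: with `z1` the normal score of the feature rank and
#' `z2 = r z1 + sqrt(1 - r^2) eps`, choosing `r = 2 sin(pi rho / 6)` makes
#' the population Spearman correlation of the pair exactly `rho`; the
#' composite is `1 + 4 pnorm(z2)`, a continuous score on the 1-5 rating
#' scale. At `|rho| = 1` the noise term vanishes and the composite is an
#' exact monotone transform of the extracted feature, so the recovered
#' correlation is exactly plus or minus 1.
#'
#' @param n_dyads number of dyads (>= 3).
#' @param feature_target one of [motion_feature_names()].
#' @param planted_rho target Spearman correlation, in `[-1, 1]`.
#' @param seed integer seed driving dyad generation and the composite noise.
#' @param duration_s per-dyad recording length, seconds.
#' @param body_part body part whose feature carries the planted correlation.
#' @param age_group passed to [default_segment_models()].
#' @param noise_sd_m sensor noise handed to each [dyad_spec()].
#' @return List with `dyads` (each a [generate_dyad()] result plus
#'   `dyad_id`), `ratings` (data frame `dyad_id`, `synthetic_composite`),
#'   `features` (full extracted feature table), `feature_target`,
#'   `body_part`, `planted_rho`, `config`, `models`.
#' @export
generate_cohort <- function(n_dyads, feature_target, planted_rho, seed = 1L,
                            duration_s = 60, body_part = "arms",
                            age_group = "13m", noise_sd_m = 5e-4) {
  if (!feature_target %in% motion_feature_names()) {
    stop(sprintf("unknown feature_target '%s'; valid names: %s", feature_target,
                 paste(motion_feature_names(), collapse = ", ")), call. = FALSE)
  }
  if (abs(planted_rho) > 1) stop_field("planted_rho", "must lie in [-1, 1]")
  if (n_dyads < 3L) stop_field("n_dyads", "must be >= 3")
  grid <- seq(0, 1, length.out = n_dyads)
  spec_for <- function(i) {
    g <- grid[i]
    if (feature_target %in% c("infant_coactive_onset_ratio",
                              "maternal_coactive_onset_ratio")) {
      dyad_spec(duration_s = duration_s, p_co = 0.05 + 0.85 * g, p_alt = 0.05,
                noise_sd_m = noise_sd_m, seed = 0L)
    } else if (feature_target %in% c("infant_alternating_onset_ratio",
                                     "maternal_alternating_onset_ratio")) {
      dyad_spec(duration_s = duration_s, p_co = 0.05, p_alt = 0.05 + 0.85 * g,
                noise_sd_m = noise_sd_m, seed = 0L)
    } else {
      pause_lo <- 2.5 + 3.0 * g
      dyad_spec(duration_s = duration_s,
                mother_pause_range = c(pause_lo, pause_lo + 1.0),
                infant_pause_range = c(pause_lo, pause_lo + 1.0),
                noise_sd_m = noise_sd_m, seed = 0L)
    }
  }
  config <- run_config(age_group)
  models <- default_segment_models(age_group)
  with_seed(seed, {
    dyad_seeds <- sample.int(2^30, n_dyads)
    dyads <- vector("list", n_dyads)
    for (i in seq_len(n_dyads)) {
      sp <- spec_for(i)
      sp$seed <- dyad_seeds[i]
      dy <- generate_dyad(sp)
      dy$dyad_id <- sprintf("dyad%03d", i)
      dyads[[i]] <- dy
    }
    extraction <- run_extract(dyads, config, models)
    feats <- extraction$features
    f <- feats[feats$body_part == body_part, feature_target]
    f <- f[match(sprintf("dyad%03d", seq_len(n_dyads)),
                 feats$dyad_id[feats$body_part == body_part])]
    r_f <- avg_rank(f)
    n_ok <- sum(is.finite(f))
    z1 <- qnorm((r_f - 0.5) / n_ok)
    if (abs(planted_rho) == 1) {
      z2 <- sign(planted_rho) * z1
    } else {
      r2 <- 2 * sin(pi * planted_rho / 6)
      z2 <- r2 * z1 + sqrt(1 - r2^2) * rnorm(n_dyads)
    }
    ratings <- data.frame(dyad_id = sprintf("dyad%03d", seq_len(n_dyads)),
                          synthetic_composite = 1 + 4 * pnorm(z2),
                          stringsAsFactors = FALSE)
    list(dyads = dyads, ratings = ratings, features = feats,
         feature_target = feature_target, body_part = body_part,
         planted_rho = planted_rho, config = config, models = models)
  })
}
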