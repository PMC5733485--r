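#' Names of the dyadic motion features
#'
#' Four coarse-grained features (two individual activity ratios plus the
#' dyadic overlap and silence ratios) and four fine-grained onset-coordination
#' features.
#'
#' @return Character vector of the eight feature names.
#' @export
motion_feature_names <- function() {
  c("infant_activity_ratio", "maternal_activity_ratio",
    "overlap_ratio", "silence_ratio",
    "infant_coactive_onset_ratio", "maternal_coactive_onset_ratio",
    "infant_alternating_onset_ratio", "maternal_alternating_onset_ratio")
}

check_same_window <- function(a, b) {
  wa <- seg_window(a)
  wb <- seg_window(b)
  if (max(abs(wa - wb)) > 1e-9) {
    stop("segment lists cover different windows", call. = FALSE)
  }
  wa
}

#' Fraction of the window spent moving
#'
#' @param segs a [movement_segments()] list.
#' @param window optional `c(start, end)` override; defaults to the list's
#'   own window.
#' @return Total movement time divided by window duration.
#' @export
activity_ratio <- function(segs, window = seg_window(segs)) {
  dur <- window[2] - window[1]
  if (dur <= 0) stop("zero-length window", call. = FALSE)
  sum(segs$offset - segs$onset) / dur
}

#' Fraction of the window in which both actors move simultaneously
#'
#' @param infant,mother [movement_segments()] lists over the same window.
#' @return Total pairwise intersection time divided by window duration.
#' @export
overlap_ratio <- function(infant, mother) {
  window <- check_same_window(infant, mother)
  intersect_length(infant, mother) / (window[2] - window[1])
}

#' Fraction of the window in which neither actor moves
#'
#' @inheritParams overlap_ratio
#' @return `(window - |union of all segments|) / window`.
#' @export
silence_ratio <- function(infant, mother) {
  window <- check_same_window(infant, mother)
  u <- merge_intervals(c(infant$onset, mother$onset), c(infant$offset, mother$offset))
  1 - sum(u$offset - u$onset) / (window[2] - window[1])
}

# For each target onset, index of the partner segment whose onset is the
# latest at or before it (0 when none).
preceding_index <- function(t_on, partner) {
  findInterval(t_on, partner$onset)
}

#' Coactive onset ratio
#'
#' The fraction of the target actor's movements that start (a) while the
#' partner is already moving and (b) at most `response_window_s` after the
#' onset of the partner movement containing the target onset. A target onset
#' coinciding exactly with a partner onset, or falling exactly at the
#' response-window bound, counts (both conditions read as inclusive).
#'
#' @param target,partner cleaned [movement_segments()] lists over the same
#'   window.
#' @param response_window_s maximum latency after the partner onset, seconds
#'   (default 1.5, a conservative infant response window).
#' @param include_simultaneous_onset whether a target onset exactly equal to
#'   the partner onset counts as coactive (default `TRUE`).
#' @return The ratio in `[0, 1]`, or `NA` (with a `reason` attribute) when
#'   the target list is empty, since 0/0 is undefined and reporting 0 would
#'   bias towards "no coordination".
#' @export
coactive_onset_ratio <- function(target, partner, response_window_s = 1.5,
                                 include_simultaneous_onset = TRUE) {
  check_same_window(target, partner)
  n <- nrow(target)
  if (n == 0L) {
    return(structure(NA_real_, reason = "target actor has no movements in window"))
  }
  tol <- 1e-9
  idx <- preceding_index(target$onset, partner)
  hit <- logical(n)
  ok <- idx >= 1L
  if (any(ok)) {
    p_on <- partner$onset[idx[ok]]
    p_off <- partner$offset[idx[ok]]
    t_on <- target$onset[ok]
    contained <- t_on < p_off - tol
    lat <- t_on - p_on
    inside <- contained & lat <= response_window_s + tol
    if (!include_simultaneous_onset) inside <- inside & lat > tol
    hit[ok] <- inside
  }
  sum(hit) / n
}

#' Alternating onset ratio
#'
#' The fraction of the target actor's movements that start (a) while the
#' partner is not moving and (b) at most `response_window_s` after the most
#' recent partner movement offset. Target onsets preceding any partner
#' movement are never counted.
#'
#' @inheritParams coactive_onset_ratio
#' @return The ratio in `[0, 1]`, or `NA` with a `reason` attribute when the
#'   target list is empty.
#' @export
alternating_onset_ratio <- function(target, partner, response_window_s = 1.5) {
  check_same_window(target, partner)
  n <- nrow(target)
  if (n == 0L) {
    return(structure(NA_real_, reason = "target actor has no movements in window"))
  }
  tol <- 1e-9
  idx <- preceding_index(target$onset, partner)
  hit <- logical(n)
  ok <- idx >= 1L
  if (any(ok)) {
    p_off <- partner$offset[idx[ok]]
    t_on <- target$onset[ok]
    not_moving <- t_on >= p_off - tol        # outside the containing segment
    lag <- t_on - p_off
    hit[ok] <- not_moving & lag <= response_window_s + tol
  }
  sum(hit) / n
}

#' All eight motion features for one dyad and body part
#'
#' @param infant,mother cleaned [movement_segments()] lists over the same
#'   window.
#' @param response_window_s latency bound for the onset features, seconds.
#' @return Named list of the eight features (see [motion_feature_names()]);
#'   onset ratios are `NA` when the corresponding actor has no movements.
#' @export
motion_features <- function(infant, mother, response_window_s = 1.5) {
  check_same_window(infant, mother)
  list(
    infant_activity_ratio = activity_ratio(infant),
    maternal_activity_ratio = activity_ratio(mother),
    overlap_ratio = overlap_ratio(infant, mother),
    silence_ratio = silence_ratio(infant, mother),
    infant_coactive_onset_ratio =
      as.numeric(coactive_onset_ratio(infant, mother, response_window_s)),
    maternal_coactive_onset_ratio =
      as.numeric(coactive_onset_ratio(mother, infant, response_window_s)),
    infant_alternating_onset_ratio =
      as.numeric(alternating_onset_ratio(infant, mother, response_window_s)),
    maternal_alternating_onset_ratio =
      as.numeric(alternating_onset_ratio(mother, infant, response_window_s))
  )
}

#' Feature table over a cohort of dyads
#'
#' Builds one row per dyad and body part from pre-computed cleaned segment
#' lists. Missing features (an actor without movements, or a dyad lacking a
#' body part) propagate as `NA` and are reported in the attached log, never
#' silently zero-filled.
#'
#' @param segment_sets a list, one element per dyad, each a list with
#'   `dyad_id` and elements `infant` and `mother`, themselves named lists of
#'   cleaned [movement_segments()] keyed by body part.
#' @param body_parts body parts to tabulate.
#' @param response_window_s latency bound for the onset features, seconds.
#' @return A data frame with columns `dyad_id`, `body_part` and the eight
#'   feature columns, with attribute `log` (character vector of per-row
#'   notes).
#' @export
extract_feature_table <- function(segment_sets,
                                  body_parts = c("upper_body", "arms", "head"),
                                  response_window_s = 1.5) {
  rows <- list()
  log <- character(0)
  for (d in segment_sets) {
    for (bp in body_parts) {
      inf <- d$infant[[bp]]
      mot <- d$mother[[bp]]
      if (is.null(inf) || is.null(mot)) {
        feats <- setNames(as.list(rep(NA_real_, 8L)), motion_feature_names())
        log <- c(log, sprintf("dyad %s: body part '%s' missing", d$dyad_id, bp))
      } else {
        feats <- motion_features(inf, mot, response_window_s)
        if (nrow(inf) == 0L) {
          log <- c(log, sprintf("dyad %s/%s: infant has no movements; onset ratios NA",
                                d$dyad_id, bp))
        }
        if (nrow(mot) == 0L) {
          log <- c(log, sprintf("dyad %s/%s: mother has no movements; onset ratios NA",
                                d$dyad_id, bp))
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        dyad_id = d$dyad_id, body_part = bp, as.data.frame(feats),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "log") <- log
  out
}
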