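#' Run configuration for end-to-end feature extraction
#'
#' Bundles the processing parameters of the pipeline: the rated window (2 min
#' in, then 3 min for 4-month recordings or 5 min for 13-month recordings),
#' the per-marker missing-data budget, the low-pass filter, the segmentation
#' threshold and cleaning durations, and the response window of the onset
#' features. All values are overridable.
#'
#' @param age_group `"13m"` or `"4m"` (sets the default rated window and the
#'   infant segment model).
#' @param window_start_s,window_duration_s rated window; set
#'   `window_start_s = NULL` to analyse each recording in full (the default
#'   for synthetic dyads, which are generated without a warm-up period).
#' @param sampling_rate_hz,unit capture-file properties used when reading.
#' @param max_missing_fraction per-marker missing-data budget (default 0.05).
#' @param filter_order,cutoff_hz Butterworth low-pass parameters.
#' @param threshold_fraction movement threshold as a fraction of the robust
#'   mean energy (default 0.20).
#' @param min_gap_s,min_dur_s segment cleaning floors, seconds (default
#'   0.35).
#' @param response_window_s onset-feature latency bound, seconds (default
#'   1.5).
#' @param spike_percentile robust-mean spike percentile (default 99).
#' @param body_parts body parts to extract.
#' @return A list of class `run_config`.
#' @export
run_config <- function(age_group = c("13m", "4m"),
                       window_start_s = NULL,
                       window_duration_s = if (age_group == "4m") 180 else 300,
                       sampling_rate_hz = 240, unit = "mm",
                       max_missing_fraction = 0.05,
                       filter_order = 4, cutoff_hz = 10,
                       threshold_fraction = 0.20,
                       min_gap_s = 0.35, min_dur_s = 0.35,
                       response_window_s = 1.5, spike_percentile = 99,
                       body_parts = c("upper_body", "arms", "head")) {
  age_group <- match.arg(age_group)
  stopifnot(max_missing_fraction > 0, filter_order >= 1, cutoff_hz > 0,
            threshold_fraction > 0, min_gap_s >= 0, min_dur_s >= 0,
            response_window_s > 0)
  structure(
    list(age_group = age_group, window_start_s = window_start_s,
         window_duration_s = window_duration_s,
         sampling_rate_hz = sampling_rate_hz, unit = unit,
         max_missing_fraction = max_missing_fraction,
         filter_order = filter_order, cutoff_hz = cutoff_hz,
         threshold_fraction = threshold_fraction,
         min_gap_s = min_gap_s, min_dur_s = min_dur_s,
         response_window_s = response_window_s,
         spike_percentile = spike_percentile, body_parts = body_parts),
    class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Any field of [run_config()] may appear in the file; unspecified fields
#' keep their defaults.
#'
#' @param path YAML file.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop(sprintf("unknown config field(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  do.call(run_config, vals)
}

process_actor <- function(ms, model, config) {
  if (!is.null(config$window_start_s)) {
    ms <- trim_to_window(ms, config$window_start_s, config$window_duration_s)
  }
  ms <- interpolate_missing(ms, config$max_missing_fraction)
  if (is_rejection(ms)) return(ms)
  ms <- lowpass_filter(ms, config$filter_order, config$cutoff_hz)
  sp <- segment_com_speed(ms, model)
  segs <- list()
  for (bp in config$body_parts) {
    E <- kinetic_energy(sp, model, bp)
    segs[[bp]] <- segment_movements(E, config$threshold_fraction,
                                    config$min_gap_s, config$min_dur_s,
                                    config$spike_percentile)
  }
  segs
}

#' End-to-end feature extraction over a cohort of dyads
#'
#' Runs read -> trim -> interpolate/reject -> filter -> kinetic energy ->
#' segmentation -> features for every dyad, recording per-dyad quality
#' control. A dyad failing the missing-data policy (or erroring) is listed in
#' the QC report with its reason and contributes no feature rows; the run
#' continues. Deterministic given its inputs.
#'
#' @param dyads list of dyads; each element needs `mother` and `infant`
#'   [marker_series()] and optionally `dyad_id` (defaults to its position).
#'   [generate_dyad()] output is accepted directly.
#' @param config a [run_config()].
#' @param models segment models per role, as [default_segment_models()].
#' @return List with `features` (the [extract_feature_table()] data frame),
#'   `qc` (data frame: `dyad_id`, `status`, `reason`), and `segments` (the
#'   cleaned per-dyad segment lists).
#' @export
run_extract <- function(dyads, config = run_config(),
                        models = default_segment_models(config$age_group)) {
  qc <- list()
  segment_sets <- list()
  for (i in seq_along(dyads)) {
    d <- dyads[[i]]
    id <- if (!is.null(d$dyad_id)) d$dyad_id else sprintf("dyad%03d", i)
    res <- tryCatch({
      mother <- process_actor(d$mother, models$mother, config)
      infant <- process_actor(d$infant, models$infant, config)
      if (is_rejection(mother)) {
        list(status = "rejected", reason = paste0("mother: ", mother$reason))
      } else if (is_rejection(infant)) {
        list(status = "rejected", reason = paste0("infant: ", infant$reason))
      } else {
        list(status = "ok", reason = "", mother = mother, infant = infant)
      }
    }, error = function(e) list(status = "failed", reason = conditionMessage(e)))
    qc[[i]] <- data.frame(dyad_id = id, status = res$status, reason = res$reason,
                          stringsAsFactors = FALSE)
    if (res$status == "ok") {
      segment_sets[[length(segment_sets) + 1L]] <-
        list(dyad_id = id, mother = res$mother, infant = res$infant)
    }
  }
  features <- if (length(segment_sets)) {
    extract_feature_table(segment_sets, config$body_parts,
                          config$response_window_s)
  } else {
    empty <- data.frame(dyad_id = character(0), body_part = character(0))
    for (f in motion_feature_names()) empty[[f]] <- numeric(0)
    empty
  }
  list(features = features, qc = do.call(rbind, qc), segments = segment_sets)
}

#' Correlate extracted features with interaction-quality ratings
#'
#' Joins the feature table with per-dyad composite scores (building them from
#' sub-scale ratings first when a composite map is supplied) and computes the
#' pairwise-complete Spearman correlation table.
#'
#' @param features feature table from [run_extract()]/[extract_feature_table()].
#' @param ratings data frame keyed by `dyad_id`: either composite scores, or
#'   raw sub-scale ratings when `composite_map` is given.
#' @param composite_map optional [cib_composite_map()]-style list.
#' @param bh_correction passed to [correlation_table()].
#' @return The correlation table data frame.
#' @export
run_correlate <- function(features, ratings, composite_map = NULL,
                          bh_correction = FALSE) {
  if (is.null(ratings) || nrow(ratings) == 0L) {
    stop("empty ratings table", call. = FALSE)
  }
  composites <- if (!is.null(composite_map)) {
    composite_scores(ratings, composite_map)
  } else {
    ratings
  }
  correlation_table(features, composites, bh_correction = bh_correction)
}
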