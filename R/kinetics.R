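#' Anthropometric segment-mass fractions
#'
#' Default fractions of total body mass carried by each modelled segment,
#' taken from the standard adult anthropometric tables used in biomechanics
#' (head-and-neck 0.081, forearm-plus-hand 0.022 per side, upper arm 0.028
#' per side). The shoulder is not a standard table segment; the shipped value
#' (0.05 per side) is a documented approximation of the clavicle/scapula
#' region and, like all fractions, is configuration rather than a constant.
#'
#' @return Named numeric vector with elements `head`, `forearm`, `upper_arm`,
#'   `shoulder` (per-side values for the bilateral segments).
#' @export
default_mass_fractions <- function() {
  c(head = 0.081, forearm = 0.022, upper_arm = 0.028, shoulder = 0.050)
}

#' Default marker-to-segment mapping
#'
#' Marker labels used by the synthetic generator and expected by the shipped
#' segment models: `head`, `wrist_l`, `wrist_r`, `elbow_l`, `elbow_r`,
#' `shoulder_l`, `shoulder_r`.
#'
#' @return A named list mapping each segment to its defining marker labels.
#' @export
default_marker_map <- function() {
  list(
    head = c("head"),
    forearm_l = c(wrist = "wrist_l", elbow = "elbow_l"),
    forearm_r = c(wrist = "wrist_r", elbow = "elbow_r"),
    upper_arm_l = c(elbow = "elbow_l", shoulder = "shoulder_l"),
    upper_arm_r = c(elbow = "elbow_r", shoulder = "shoulder_r"),
    shoulder_l = c(shoulder = "shoulder_l"),
    shoulder_r = c(shoulder = "shoulder_r")
  )
}

#' Body-segment model for kinetic-energy computation
#'
#' Describes one actor's segments: total body mass, the fraction of it carried
#' by each segment, which segments are present, how segment centres of mass
#' are estimated from markers, and the marker labels involved. Infants in a
#' seat with limited shoulder mobility are modelled without the shoulder and
#' upper-arm terms (`segments_present = c("head", "forearm")`).
#'
#' @param role `"mother"` or `"infant"`.
#' @param total_mass_kg total body mass in kilograms.
#' @param mass_fractions named vector as [default_mass_fractions()]; values
#'   are per side for the bilateral segments and must lie in (0, 1) with the
#'   used fractions summing below 1.
#' @param segments_present subset of `c("head", "forearm", "upper_arm",
#'   "shoulder")`.
#' @param marker_map list as [default_marker_map()].
#' @param com_fraction fraction along the defining marker pair at which the
#'   centre of mass of the forearm (wrist towards elbow) and upper arm (elbow
#'   towards shoulder) is placed; default 0.5 (midpoint).
#' @return An object of class `segment_model`.
#' @export
segment_model <- function(role = c("mother", "infant"), total_mass_kg,
                          mass_fractions = default_mass_fractions(),
                          segments_present = c("head", "forearm", "upper_arm", "shoulder"),
                          marker_map = default_marker_map(),
                          com_fraction = 0.5) {
  role <- match.arg(role)
  if (!is.numeric(total_mass_kg) || total_mass_kg <= 0) {
    stop_field("total_mass_kg", "must be a positive mass in kg")
  }
  need <- c("head", "forearm", "upper_arm", "shoulder")
  if (!all(need %in% names(mass_fractions))) {
    stop_field("mass_fractions", paste("must name", paste(need, collapse = ", ")))
  }
  mf <- mass_fractions[need]
  if (any(mf <= 0 | mf >= 1)) stop_field("mass_fractions", "must lie in (0, 1)")
  segments_present <- match.arg(segments_present, need, several.ok = TRUE)
  if (!"head" %in% segments_present || !"forearm" %in% segments_present) {
    stop_field("segments_present", "must include at least head and forearm")
  }
  sides <- c(head = 1, forearm = 2, upper_arm = 2, shoulder = 2)
  used <- sum(mf[segments_present] * sides[segments_present])
  if (used >= 1) stop_field("mass_fractions", "used fractions sum to >= 1")
  if (com_fraction < 0 || com_fraction > 1) {
    stop_field("com_fraction", "must lie in [0, 1]")
  }
  structure(
    list(role = role, total_mass_kg = total_mass_kg, mass_fractions = mf,
         segments_present = segments_present, marker_map = marker_map,
         com_fraction = com_fraction),
    class = "segment_model"
  )
}

#' Default segment models for the two actors
#'
#' Mothers use the full segment set; infants at 4 months lack the shoulder
#' and upper-arm terms. Infant mass fractions default to the adult table (a
#' configuration hook, since no standard infant rescaling ships with the
#' adult tables).
#'
#' @param age_group `"4m"` or `"13m"` (controls the infant segment set).
#' @param mother_mass_kg,infant_mass_kg total body masses in kg.
#' @return Named list with elements `mother` and `infant`.
#' @export
default_segment_models <- function(age_group = c("13m", "4m"),
                                   mother_mass_kg = 65,
                                   infant_mass_kg = if (age_group == "4m") 6.5 else 9.5) {
  age_group <- match.arg(age_group)
  infant_segments <- if (age_group == "4m") c("head", "forearm")
                     else c("head", "forearm", "upper_arm", "shoulder")
  list(
    mother = segment_model("mother", mother_mass_kg),
    infant = segment_model("infant", infant_mass_kg,
                           segments_present = infant_segments)
  )
}

segment_names <- function(model) {
  segs <- "head"
  for (s in c("forearm", "upper_arm", "shoulder")) {
    if (s %in% model$segments_present) segs <- c(segs, paste0(s, c("_l", "_r")))
  }
  segs
}

marker_slice <- function(mts, label) {
  j <- match(label, mts$markers)
  if (is.na(j)) {
    stop(sprintf("marker '%s' required by the segment model is absent", label),
         call. = FALSE)
  }
  mts$positions[, , j]
}

#' Centre-of-mass speed of each body segment
#'
#' Estimates each segment's centre of mass per frame (head: centroid of the
#' head markers; forearm-plus-hand: a point `com_fraction` along
#' wrist-to-elbow; upper arm: `com_fraction` along elbow-to-shoulder;
#' shoulder: the shoulder marker itself), differentiates by central finite
#' differences at the sampling rate (one-sided at the series ends), and
#' returns the Euclidean speed. Left and right segments are kept separate.
#'
#' @param mts a filtered, fully valid [marker_series()].
#' @param model a [segment_model()].
#' @return An object of class `speed_series`: list with `speeds` (frames x
#'   segments matrix, m/s), `sampling_rate_hz`, `t0`, `role`.
#' @export
segment_com_speed <- function(mts, model) {
  if (!all(mts$valid)) {
    stop("series contains invalid frames; run interpolate_missing() first",
         call. = FALSE)
  }
  n <- n_frames(mts)
  fs <- mts$sampling_rate_hz
  segs <- segment_names(model)
  f <- model$com_fraction
  com <- function(seg) {
    map <- model$marker_map[[seg]]
    if (is.null(map)) {
      stop(sprintf("segment '%s' missing from marker_map", seg), call. = FALSE)
    }
    if (seg == "head") {
      ps <- lapply(map, function(l) marker_slice(mts, l))
      Reduce(`+`, ps) / length(ps)
    } else if (startsWith(seg, "forearm")) {
      (1 - f) * marker_slice(mts, map[["wrist"]]) + f * marker_slice(mts, map[["elbow"]])
    } else if (startsWith(seg, "upper_arm")) {
      (1 - f) * marker_slice(mts, map[["elbow"]]) + f * marker_slice(mts, map[["shoulder"]])
    } else {
      marker_slice(mts, map[["shoulder"]])
    }
  }
  speeds <- matrix(0, nrow = n, ncol = length(segs), dimnames = list(NULL, segs))
  for (seg in segs) {
    p <- com(seg)
    v <- matrix(0, n, 3L)
    if (n >= 3L) {
      v[2:(n - 1L), ] <- (p[3:n, , drop = FALSE] - p[1:(n - 2L), , drop = FALSE]) * (fs / 2)
    }
    if (n >= 2L) {
      v[1L, ] <- (p[2L, ] - p[1L, ]) * fs
      v[n, ] <- (p[n, ] - p[n - 1L, ]) * fs
    }
    speeds[, seg] <- sqrt(rowSums(v^2))
  }
  structure(list(speeds = speeds, sampling_rate_hz = fs, t0 = mts$t0,
                 role = model$role),
            class = "speed_series")
}

#' Per-frame translational kinetic energy of a body part
#'
#' Combines segment centre-of-mass speeds into the translational kinetic
#' energy of one body part:
#' head `K_h = 1/2 m_h v_h^2`; arms `K_a = sum_sides 1/2 m_fa v_fa^2`, plus
#' the upper-arm terms when that segment is present; upper body
#' `K_ub = K_h + ` the forearm terms, plus upper-arm and shoulder terms when
#' present. Segment masses are `fraction x total_mass_kg`, output is joules.
#'
#' @param speeds a [segment_com_speed()] result.
#' @param model the matching [segment_model()].
#' @param body_part `"head"`, `"arms"` or `"upper_body"`.
#' @return An object of class `energy_series`: list with `energy` (joules per
#'   frame), `sampling_rate_hz`, `t0`, `body_part`, `role`.
#' @export
kinetic_energy <- function(speeds, model, body_part = c("upper_body", "arms", "head")) {
  body_part <- match.arg(body_part)
  if (!identical(speeds$role, model$role)) {
    stop("`speeds` and `model` refer to different actors", call. = FALSE)
  }
  v <- speeds$speeds
  M <- model$total_mass_kg
  mf <- model$mass_fractions
  term <- function(seg_base) {
    cols <- grep(paste0("^", seg_base, "(_l|_r)?$"), colnames(v), value = TRUE)
    if (length(cols) == 0L) return(0)
    m <- mf[[seg_base]] * M
    rowSums(0.5 * m * v[, cols, drop = FALSE]^2)
  }
  have <- model$segments_present
  E <- switch(
    body_part,
    head = term("head"),
    arms = term("forearm") + if ("upper_arm" %in% have) term("upper_arm") else 0,
    upper_body = term("head") + term("forearm") +
      (if ("upper_arm" %in% have) term("upper_arm") else 0) +
      (if ("shoulder" %in% have) term("shoulder") else 0)
  )
  structure(list(energy = as.numeric(E), sampling_rate_hz = speeds$sampling_rate_hz,
                 t0 = speeds$t0, body_part = body_part, role = model$role),
            class = "energy_series")
}

#' @export
print.energy_series <- function(x, ...) {
  cat(sprintf("<energy_series> %s/%s: %d frames @ %g Hz, mean %.3g J\n",
              x$role, x$body_part, length(x$energy), x$sampling_rate_hz,
              mean(x$energy)))
  invisible(x)
}
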