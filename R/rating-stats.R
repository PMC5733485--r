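#' Built-in CIB composite definitions
#'
#' The Coding Interactive Behavior (CIB) sub-scales are averaged into
#' theoretically motivated composites whose membership depends on infant age;
#' some composites are single pass-through scales, and reversed scales are
#' re-oriented (`r -> 6 - r` on the 1-5 Likert scale) before averaging. The
#' map returned here is the single source of truth for scale membership and
#' can be replaced wholesale (e.g. loaded from YAML) for other coding
#' schemes.
#'
#' @param age_group `"4m"` or `"13m"`.
#' @return Named list: each composite is a list with `scales` (character) and
#'   `reversed` (character subset of `scales`).
#' @export
cib_composite_map <- function(age_group = c("4m", "13m")) {
  age_group <- match.arg(age_group)
  comp <- function(scales, reversed = character(0)) {
    list(scales = scales, reversed = reversed)
  }
  base <- list(
    maternal_sensitivity = comp(c("acknowledgement", "elaborating",
                                  "positive_affect_parent", "vocal_appropriateness",
                                  "appropriate_range_of_affect", "resourcefulness",
                                  "supportive_presence")),
    maternal_intrusiveness = comp("overriding"),
    infant_involvement = comp(c("gaze_joint_attention", "alert",
                                "vocalizations", "initiation")),
    infant_negativity = comp("negative_emotionality"),
    dyadic_reciprocity = comp(c("dyadic_reciprocity_scale", "fluency",
                                "adaptation_regulation")),
    dyadic_negative_states = comp("constriction"),
    parent_led = comp("parent_led_scale"),
    child_led = comp("child_led_scale")
  )
  if (age_group == "4m") {
    base$maternal_sensitivity$scales <-
      c(base$maternal_sensitivity$scales, "imitation")
    base$infant_involvement$scales <-
      c(base$infant_involvement$scales, "positive_affect_infant")
  } else {
    base$maternal_limit_setting <- comp(c("consistency_of_style",
                                          "on_task_persistence",
                                          "appropriate_structure"))
    base$infant_involvement$scales <-
      c(base$infant_involvement$scales, "fatigue", "competent_use_of_environment",
        "creative_symbolic_play")
    base$infant_involvement$reversed <- "fatigue"
    base$infant_negativity$scales <-
      c(base$infant_negativity$scales, "labile_affect")
    base$infant_compliance <- comp(c("compliance_to_parent", "on_task_persistence"))
  }
  base
}

#' CIB composite scores from sub-scale ratings
#'
#' Each composite is the arithmetic mean of its constituent scales after
#' re-orienting reversed scales (`r -> 6 - r`). Single-scale composites pass
#' through unchanged.
#'
#' @param ratings data frame with a `dyad_id` column and one numeric column
#'   per sub-scale, ratings on the 1-5 Likert scale.
#' @param composite_map named list as returned by [cib_composite_map()].
#' @return Data frame with `dyad_id` and one column per composite, values in
#'   `[1, 5]`.
#' @export
composite_scores <- function(ratings, composite_map) {
  if (!"dyad_id" %in% names(ratings)) {
    stop("`ratings` must have a dyad_id column", call. = FALSE)
  }
  num <- ratings[setdiff(names(ratings), "dyad_id")]
  rng <- suppressWarnings(range(unlist(num), na.rm = TRUE))
  if (is.finite(rng[1]) && (rng[1] < 1 || rng[2] > 5)) {
    stop("ratings outside the 1-5 Likert scale", call. = FALSE)
  }
  out <- data.frame(dyad_id = ratings$dyad_id)
  for (comp in names(composite_map)) {
    def <- composite_map[[comp]]
    missing_scales <- setdiff(def$scales, names(ratings))
    if (length(missing_scales)) {
      stop(sprintf("composite '%s': missing scale(s) %s", comp,
                   paste(missing_scales, collapse = ", ")), call. = FALSE)
    }
    vals <- as.matrix(ratings[def$scales])
    for (s in def$reversed) {
      vals[, s] <- 6 - vals[, s]
    }
    out[[comp]] <- rowMeans(vals)
  }
  out
}

#' Cronbach's alpha internal-consistency coefficient
#'
#' `alpha = k/(k-1) * (1 - sum(item variances) / variance(item sums))` with
#' sample (n-1) variances.
#'
#' @param items numeric matrix or data frame, rows = dyads, columns = scale
#'   items.
#' @return The alpha coefficient.
#' @export
cronbach_alpha <- function(items) {
  x <- as.matrix(items)
  k <- ncol(x)
  if (k < 2L || nrow(x) < 2L) {
    stop("need at least 2 items and 2 observations", call. = FALSE)
  }
  total_var <- var(rowSums(x))
  if (total_var <= 0) stop("zero total variance; alpha undefined", call. = FALSE)
  k / (k - 1) * (1 - sum(apply(x, 2L, var)) / total_var)
}

#' ICC(2,1): two-way random effects, absolute agreement, single measures
#'
#' Computed from the two-way ANOVA mean squares (rows = rated targets,
#' columns = coders): `(MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`,
#' with the standard F-based confidence interval for this model. Degenerate
#' tables with no between-target variance yield a coefficient at or below
#' zero, reported as computed rather than clamped.
#'
#' @param ratings numeric matrix or data frame, rows = targets, columns =
#'   coders; must be complete.
#' @param conf_level confidence level for the interval (default 0.95).
#' @return List with `icc`, `lower`, `upper`, `n` (targets), `k` (coders).
#' @export
icc_2_1 <- function(ratings, conf_level = 0.95) {
  x <- as.matrix(ratings)
  if (anyNA(x)) stop("ratings table must be complete", call. = FALSE)
  n <- nrow(x)
  k <- ncol(x)
  if (n < 2L || k < 2L) stop("need >= 2 targets and >= 2 coders", call. = FALSE)
  grand <- mean(x)
  row_m <- rowMeans(x)
  col_m <- colMeans(x)
  SSR <- k * sum((row_m - grand)^2)
  SSC <- n * sum((col_m - grand)^2)
  SST <- sum((x - grand)^2)
  SSE <- SST - SSR - SSC
  MSR <- SSR / (n - 1)
  MSC <- SSC / (k - 1)
  MSE <- SSE / ((n - 1) * (k - 1))
  icc <- (MSR - MSE) / (MSR + (k - 1) * MSE + k * (MSC - MSE) / n)
  alpha <- 1 - conf_level
  if (MSE == 0 && MSC == 0) {
    # forced agreement: interval collapses
    return(list(icc = icc, lower = icc, upper = icc, n = n, k = k))
  }
  a <- (k * icc) / (n * (1 - icc))
  b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
  v <- (a * MSC + b * MSE)^2 /
    ((a * MSC)^2 / (k - 1) + (b * MSE)^2 / ((n - 1) * (k - 1)))
  FL <- qf(1 - alpha / 2, n - 1, v)
  FU <- qf(1 - alpha / 2, v, n - 1)
  lower <- n * (MSR - FL * MSE) /
    (FL * (k * MSC + (k * n - k - n) * MSE) + n * MSR)
  upper <- n * (FU * MSR - MSE) /
    (k * MSC + (k * n - k - n) * MSE + n * FU * MSR)
  list(icc = icc, lower = lower, upper = upper, n = n, k = k)
}

avg_rank <- function(x) rank(x, ties.method = "average", na.last = "keep")

all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  p <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, p + (p >= k))
  }))
}

#' Spearman rank correlation with a two-tailed p-value
#'
#' The coefficient is the Pearson correlation of average-tied ranks. The
#' two-tailed p-value uses the t approximation with n - 2 degrees of freedom
#' (the default, appropriate for the cohort sizes this pipeline targets) or
#' an exact permutation null for very small samples.
#'
#' @param x,y paired numeric vectors; pairs with a missing value are dropped
#'   (pairwise-complete).
#' @param p_method `"t"` (default) or `"exact"` (full permutation null,
#'   n <= 9 only).
#' @return List with `rho`, `p`, `n`. `rho` is `NA` when fewer than 3
#'   complete pairs remain or either vector is constant.
#' @export
spearman_cor <- function(x, y, p_method = c("t", "exact")) {
  p_method <- match.arg(p_method)
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]
  y <- y[keep]
  n <- length(x)
  if (n < 3L) return(list(rho = NA_real_, p = NA_real_, n = n))
  rx <- avg_rank(x)
  ry <- avg_rank(y)
  if (sd(rx) == 0 || sd(ry) == 0) {
    return(list(rho = NA_real_, p = NA_real_, n = n))
  }
  cx <- rx - mean(rx)
  cy <- ry - mean(ry)
  rho <- sum(cx * cy) / sqrt(sum(cx^2) * sum(cy^2))
  rho <- max(-1, min(1, rho))
  if (p_method == "exact") {
    if (n > 9L) stop("exact permutation p-value limited to n <= 9", call. = FALSE)
    perms <- all_permutations(n)
    denom <- sqrt(sum(cx^2) * sum(cy^2))
    rhos <- as.numeric(matrix(cy[perms], nrow = nrow(perms)) %*% cx) / denom
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
  } else {
    if (abs(rho) >= 1) {
      p <- 0
    } else {
      tstat <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * pt(-abs(tstat), df = n - 2)
    }
  }
  list(rho = rho, p = p, n = n)
}

#' Correlation table between motion features and composites
#'
#' Pairwise-complete Spearman correlations for every combination of (feature
#' x body part) and composite, reproducing the layout of a feature-by-
#' composite correlation table: one row per feature and body part, one
#' column group per composite with rho, two-tailed p, and the n used. No
#' multiplicity adjustment is applied by default, matching per-cell
#' reporting; Benjamini-Hochberg adjustment across the table is available
#' behind `bh_correction` for reuse.
#'
#' @param features feature table from [extract_feature_table()] (columns
#'   `dyad_id`, `body_part`, features).
#' @param composites data frame from [composite_scores()] (or any data frame
#'   with `dyad_id` plus numeric composite columns).
#' @param feature_names feature columns to correlate; defaults to the eight
#'   motion features present in `features`.
#' @param bh_correction apply Benjamini-Hochberg adjustment to the p-values
#'   across all cells.
#' @return Long data frame with columns `feature`, `body_part`, `composite`,
#'   `rho`, `p`, `n`. Cells with fewer than 3 complete pairs are `NA`.
#' @export
correlation_table <- function(features, composites,
                              feature_names = intersect(motion_feature_names(),
                                                        names(features)),
                              bh_correction = FALSE) {
  if (nrow(composites) == 0L) stop("empty composites table", call. = FALSE)
  common <- intersect(features$dyad_id, composites$dyad_id)
  if (length(common) == 0L) {
    stop(sprintf("no overlapping dyad ids (features: %s...; composites: %s...)",
                 paste(utils::head(unique(features$dyad_id), 3), collapse = ","),
                 paste(utils::head(unique(composites$dyad_id), 3), collapse = ",")),
         call. = FALSE)
  }
  comp_names <- setdiff(names(composites), "dyad_id")
  body_parts <- unique(features$body_part)
  rows <- list()
  for (feat in feature_names) {
    for (bp in body_parts) {
      sub <- features[features$body_part == bp, c("dyad_id", feat)]
      m <- merge(sub, composites, by = "dyad_id")
      for (comp in comp_names) {
        r <- spearman_cor(m[[feat]], m[[comp]])
        rows[[length(rows) + 1L]] <- data.frame(
          feature = feat, body_part = bp, composite = comp,
          rho = r$rho, p = r$p, n = r$n, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (bh_correction) out$p_adj <- p.adjust(out$p, method = "BH")
  out
}
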