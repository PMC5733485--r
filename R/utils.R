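# internal helpers shared across modules

# Evaluate `expr` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so library calls never perturb user-level reproducibility.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv())
    on.exit({
      if (had) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
      stop("`seed` must be a single finite number", call. = FALSE)
    }
    set.seed(as.integer(seed))
  }
  expr
}

stop_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

# Merge overlapping/adjacent intervals of a two-column matrix-like input
# (onset, offset); returns a data.frame sorted by onset with disjoint rows.
merge_intervals <- function(onset, offset) {
  if (length(onset) == 0L) {
    return(data.frame(onset = numeric(0), offset = numeric(0)))
  }
  o <- order(onset, offset)
  onset <- onset[o]
  offset <- offset[o]
  out_on <- onset[1L]
  out_off <- offset[1L]
  if (length(onset) > 1L) {
    for (i in 2L:length(onset)) {
      k <- length(out_on)
      if (onset[i] <= out_off[k]) {
        out_off[k] <- max(out_off[k], offset[i])
      } else {
        out_on <- c(out_on, onset[i])
        out_off <- c(out_off, offset[i])
      }
    }
  }
  data.frame(onset = out_on, offset = out_off)
}

# Total length of the pairwise intersection of two disjoint interval lists.
intersect_length <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L) return(0)
  tot <- 0
  j <- 1L
  for (i in seq_len(nrow(a))) {
    while (j <= nrow(b) && b$offset[j] <= a$onset[i]) j <- j + 1L
    k <- j
    while (k <= nrow(b) && b$onset[k] < a$offset[i]) {
      tot <- tot + max(0, min(a$offset[i], b$offset[k]) - max(a$onset[i], b$onset[k]))
      k <- k + 1L
    }
  }
  tot
}
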