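test_that("composite scores average orientation-adjusted scales", {
  map <- list(
    intrusiveness = list(scales = "overriding", reversed = character(0)),
    engagement = list(scales = c("alert", "initiation"), reversed = character(0)),
    involvement = list(scales = c("alert", "fatigue"), reversed = "fatigue"))
  ratings <- data.frame(dyad_id = c("d1", "d2"),
                        overriding = c(3, 5), alert = c(2, 4),
                        initiation = c(4, 2), fatigue = c(5, 1))
  cs <- composite_scores(ratings, map)
  expect_equal(cs$intrusiveness, c(3, 5))          # single-scale pass-through
  expect_equal(cs$engagement, c(3, 3))             # plain mean
  expect_equal(cs$involvement, c((2 + 1) / 2, (4 + 5) / 2))  # 5 reverses to 1
  expect_error(composite_scores(ratings[-2], map), "overriding")
  bad <- ratings
  bad$alert[1] <- 6
  expect_error(composite_scores(bad, map), "Likert")
})

test_that("built-in composite maps differ by age and bound their constituents", {
  m4 <- cib_composite_map("4m")
  m13 <- cib_composite_map("13m")
  expect_true("imitation" %in% m4$maternal_sensitivity$scales)
  expect_false("imitation" %in% m13$maternal_sensitivity$scales)
  expect_true("labile_affect" %in% m13$infant_negativity$scales)
  expect_true("maternal_limit_setting" %in% names(m13))
  expect_false("maternal_limit_setting" %in% names(m4))
  expect_identical(m13$infant_involvement$reversed, "fatigue")
  set.seed(501)
  scales <- unique(unlist(lapply(m13, `[[`, "scales")))
  ratings <- as.data.frame(setNames(
    lapply(scales, function(s) sample(1:5, 12, replace = TRUE)), scales))
  ratings$dyad_id <- sprintf("d%02d", 1:12)
  cs <- composite_scores(ratings, m13)
  for (comp in names(m13)) {
    vals <- as.matrix(ratings[m13[[comp]]$scales])
    for (s in m13[[comp]]$reversed) vals[, s] <- 6 - vals[, s]
    expect_true(all(cs[[comp]] >= apply(vals, 1, min) - 1e-12))
    expect_true(all(cs[[comp]] <= apply(vals, 1, max) + 1e-12))
  }
})

test_that("Cronbach's alpha matches the direct formula and its limits", {
  v <- c(2, 4, 3, 5, 1, 4)
  expect_equal(cronbach_alpha(cbind(v, v, v, v)), 1.0)
  m <- matrix(c(3, 4, 2, 5, 2, 4, 3, 5, 3, 5, 2, 4), 4, 3)
  k <- 3
  direct <- k / (k - 1) * (1 - sum(apply(m, 2, var)) / var(rowSums(m)))
  expect_equal(cronbach_alpha(m), direct, tolerance = 1e-12)
  expect_error(cronbach_alpha(matrix(1, 4, 3)), "variance")
  # population alpha of independent items is 0
  set.seed(502)
  alphas <- replicate(400, cronbach_alpha(matrix(rnorm(80), 40, 2)))
  expect_lt(abs(mean(alphas)), 0.05)
})

test_that("ICC(2,1) matches the two-way ANOVA oracle and penalizes coder bias", {
  set.seed(503)
  x <- matrix(rnorm(20, mean = 3), 10, 2)
  x[, 2] <- x[, 1] + rnorm(10, sd = 0.4)
  long <- data.frame(y = c(x), target = factor(rep(1:10, 2)),
                     coder = factor(rep(1:2, each = 10)))
  a <- stats::anova(stats::aov(y ~ target + coder, data = long))
  MSR <- a["target", "Mean Sq"]
  MSC <- a["coder", "Mean Sq"]
  MSE <- a["Residuals", "Mean Sq"]
  oracle <- (MSR - MSE) / (MSR + MSE + 2 * (MSC - MSE) / 10)
  r <- icc_2_1(x)
  expect_equal(r$icc, oracle, tolerance = 1e-12)
  expect_lt(r$lower, r$icc)
  expect_gt(r$upper, r$icc)

  base <- cbind(1:6, 1:6)
  expect_equal(icc_2_1(base)$icc, 1.0)
  iccs <- sapply(c(0, 0.5, 1, 2), function(b) icc_2_1(cbind(1:6, 1:6 + b))$icc)
  expect_true(all(diff(iccs) < 0))  # absolute agreement penalizes bias
  # destroying the pairing drives agreement to zero on average
  set.seed(504)
  perms <- replicate(300, {
    y <- rnorm(12)
    icc_2_1(cbind(y, sample(y)))$icc
  })
  expect_lt(abs(mean(perms)), 0.1)
})

test_that("Spearman matches a brute-force rank-then-Pearson oracle, ties included", {
  set.seed(505)
  worst <- 0
  for (i in 1:300) {
    n <- sample(4:40, 1)
    x <- sample(1:8, n, replace = TRUE)
    y <- sample(1:8, n, replace = TRUE)
    got <- spearman_cor(x, y)
    oracle <- suppressWarnings(cor(rank(x), rank(y)))
    if (!is.finite(oracle)) {
      expect_true(is.na(got$rho))
    } else {
      worst <- max(worst, abs(got$rho - oracle))
    }
  }
  expect_lt(worst, 1e-12)
  expect_equal(spearman_cor(1:7, (1:7)^3)$rho, 1.0)
  expect_equal(spearman_cor(1:7, rev(1:7))$rho, -1.0)
  expect_true(is.na(spearman_cor(rep(1, 8), rnorm(8))$rho))
})

test_that("Spearman is symmetric and invariant under monotone transforms", {
  set.seed(506)
  x <- rnorm(25)
  y <- rnorm(25)
  expect_equal(spearman_cor(x, y)$rho, spearman_cor(y, x)$rho)
  expect_equal(spearman_cor(exp(x), y)$rho, spearman_cor(x, y)$rho)
  expect_equal(spearman_cor(x, -1 / (1 + exp(-y)))$rho, -spearman_cor(x, y)$rho)
})

test_that("two-tailed p-values: t approximation and exact permutation null", {
  set.seed(507)
  x <- rnorm(20)
  y <- 0.5 * x + rnorm(20)
  r <- spearman_cor(x, y)
  tstat <- r$rho * sqrt((20 - 2) / (1 - r$rho^2))
  expect_equal(r$p, 2 * pt(-abs(tstat), 18), tolerance = 1e-12)
  # exact null: a perfect monotone pair of 5 has p = 2 / 5!
  expect_equal(spearman_cor(1:5, 2 * (1:5), p_method = "exact")$p, 2 / 120)
  expect_error(spearman_cor(1:10, 1:10, p_method = "exact"), "n <= 9")
  # degenerate n
  expect_true(is.na(spearman_cor(1:2, 2:1)$rho))
})

test_that("correlation tables are pairwise-complete with per-cell n", {
  set.seed(508)
  n <- 12
  feats <- data.frame(dyad_id = sprintf("d%02d", 1:n), body_part = "arms",
                      silence_ratio = seq(0.1, 0.9, length.out = n),
                      overlap_ratio = c(NA, rnorm(n - 1)))
  comps <- data.frame(dyad_id = sprintf("d%02d", 1:n),
                      quality = seq(1, 5, length.out = n))
  tab <- correlation_table(feats, comps,
                          feature_names = c("silence_ratio", "overlap_ratio"))
  cell <- tab[tab$feature == "silence_ratio", ]
  expect_equal(cell$rho, 1.0)
  expect_equal(cell$n, n)
  expect_equal(tab[tab$feature == "overlap_ratio", "n"], n - 1)
  # all-missing feature column gives missing cells
  feats$overlap_ratio <- NA_real_
  tab2 <- correlation_table(feats, comps,
                           feature_names = c("silence_ratio", "overlap_ratio"))
  expect_true(is.na(tab2[tab2$feature == "overlap_ratio", "rho"]))
  # BH adjustment is opt-in
  expect_false("p_adj" %in% names(tab))
  tab3 <- correlation_table(feats, comps, feature_names = "silence_ratio",
                           bh_correction = TRUE)
  expect_true("p_adj" %in% names(tab3))
  expect_error(correlation_table(feats, comps[0, ]), "empty")
  comps$dyad_id <- sprintf("x%02d", 1:n)
  expect_error(correlation_table(feats, comps), "overlapping")
})
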