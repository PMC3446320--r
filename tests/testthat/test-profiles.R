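# Temporal profiles: folds, phase metrics, smoothing, SNR, clustering,
# factorial ANOVA and post hoc.

test_that("signed folds follow the symmetric convention", {
  pr <- temporal_profile(c(2, 2, 4, 4, 1, 1), c(0, 0, 6, 6, 12, 12))
  f <- fold_changes(pr)
  expect_equal(as.vector(f), c(1, 2, -2))
  flat <- fold_changes(temporal_profile(rep(3, 8), rep(c(0, 6, 12, 18), 2)))
  expect_equal(as.vector(flat), rep(1, 4))
  expect_error(fold_changes(temporal_profile(c(-1, 2), c(0, 6))),
               "positive")
  # sign flips, magnitude preserved when reference and target swap
  a <- fold_changes(temporal_profile(c(2, 5), c(0, 6)))[["6"]]
  b <- fold_changes(temporal_profile(c(5, 2), c(0, 6)))[["6"]]
  expect_equal(a, 2.5)
  expect_equal(b, -2.5)
})

test_that("acrophase and amplitude pick the documented extrema", {
  f1 <- c(`0` = 1, `6` = 1.2, `12` = 2.5, `18` = -1.43)
  m1 <- acrophase_amplitude(f1)
  expect_equal(m1$acrophase, 12)
  expect_equal(m1$amplitude, 2.5)

  f2 <- c(`0` = 1, `6` = -3, `12` = 1.1, `18` = 1)
  m2 <- acrophase_amplitude(f2)
  expect_equal(m2$acrophase, 12)
  expect_equal(m2$amplitude, -3)

  flat <- acrophase_amplitude(c(`0` = 1, `6` = 1, `12` = 1))
  expect_equal(flat$acrophase, 0)        # tie -> earliest sampled time
  expect_equal(flat$amplitude, 1)
})

test_that("planted on-grid acrophases are recovered under light noise", {
  set.seed(23)
  grid <- c(0, 6, 12, 18)
  hits <- 0; total <- 0
  for (i in 1:100) {
    phase <- sample(grid, 1)
    amp <- 0.5
    vals <- 2^(amp * cos(2 * pi * (rep(grid, each = 3) - phase) / 24) +
                 rnorm(12, 0, 0.1 * amp))
    pm <- acrophase_amplitude(fold_changes(
      temporal_profile(vals, rep(grid, each = 3))))
    total <- total + 1
    if (pm$acrophase == phase) hits <- hits + 1
  }
  expect_gte(hits / total, 0.9)
})

test_that("profile correlation matches cor.test", {
  a <- temporal_profile(c(1, 2, 3), c(0, 6, 12))
  b <- temporal_profile(c(2, 4, 6), c(0, 6, 12))
  pc <- profile_correlation(a, b)
  expect_equal(pc$r, 1)
  expect_equal(pc$p, 0)
  neg <- profile_correlation(a, temporal_profile(c(-1, -2, -3) + 10,
                                                 c(0, 6, 12)))
  expect_equal(neg$r, -1)
  set.seed(6)
  for (i in 1:10) {
    x <- rnorm(8); y <- rnorm(8)
    pa <- temporal_profile(x, 1:8); pb <- temporal_profile(y, 1:8)
    mine <- profile_correlation(pa, pb)
    orc <- cor.test(x, y)
    expect_equal(mine$r, unname(orc$estimate), tolerance = 1e-10)
    expect_equal(mine$p, orc$p.value, tolerance = 1e-10)
  }
  expect_error(profile_correlation(a, temporal_profile(rep(1, 3),
                                                       c(0, 6, 12))),
               "zero variance")
})

test_that("smooth_zscore matches the brute-force window oracle", {
  expect_error(smooth_zscore(rep(2, 10)), "zero variance")
  ramp <- smooth_zscore(1:10, window = 1L)
  expect_equal(mean(ramp), 0, tolerance = 1e-12)
  expect_equal(sd(ramp), 1, tolerance = 1e-12)
  x <- cos(2 * pi * (0:11) / 12)
  sm <- moving_average(x, 5L)
  expect_equal(sm, oracle_moving_average(x, 5), tolerance = 1e-12)
  z <- smooth_zscore(x, 5L)
  expect_equal(z, (sm - mean(sm)) / sd(sm), tolerance = 1e-12)
})

test_that("snr ranking prefers reproducible rhythmic profiles", {
  t12 <- 2 * pi * (0:11) / 12
  day1 <- rbind(rhythmic = cos(t12), flat = rep(1, 12),
                noisy = cos(t12) + c(1, -1))
  day2 <- rbind(rhythmic = cos(t12), flat = rep(1, 12),
                noisy = cos(t12) - c(1, -1))
  res <- snr_rank(day1, day2)
  expect_equal(res$ranking$profile_id[1], "rhythmic")
  expect_equal(res$ranking$reproducibility[1], 1)
  expect_equal(res$ranking$profile_id[3], "flat")  # zero range -> lowest
  expect_equal(unname(res$averaged["noisy", ]), cos(t12))
  expect_equal(snr_rank(matrix(c(1, 3), 1), matrix(c(3, 5), 1),
                        window = 1)$averaged[1, ], c(2, 4))
  expect_error(snr_rank(day1, day2[, 1:6]), "identical shape")
})

test_that("sota co-clusters duplicates and separates antiphase groups", {
  t24 <- 2 * pi * (0:11) / 12
  base <- cos(t24)
  X <- rbind(a1 = base, a2 = base, b1 = -base, b2 = -base + 0.01 * sin(t24))
  res <- sota_cluster(X, 2)
  expect_equal(res$assignment[["a1"]], res$assignment[["a2"]])
  expect_equal(res$assignment[["b1"]], res$assignment[["b2"]])
  expect_false(res$assignment[["a1"]] == res$assignment[["b1"]])
  expect_identical(res, sota_cluster(X, 2))      # deterministic
  expect_error(sota_cluster(X, 5), "fewer profiles")
})

test_that("sota recovers four planted phase groups (ARI >= 0.9)", {
  set.seed(77)
  grid <- seq(0, 21, by = 3)
  phases <- c(0, 6, 12, 18)
  X <- do.call(rbind, lapply(phases, function(ph) {
    t(sapply(1:10, function(i) {
      z <- cos(2 * pi * (grid - ph) / 24) + rnorm(length(grid), 0, 0.15)
      (z - mean(z)) / sd(z)
    }))
  }))
  truth <- rep(seq_along(phases), each = 10)
  res <- sota_cluster(X, 4)
  expect_gte(adjusted_rand(res$assignment, truth), 0.9)
})

test_that("hierarchical ordering reproduces the all-pairs oracle", {
  t24 <- 2 * pi * (0:7) / 8
  X <- rbind(a = cos(t24), b = cos(t24), c = -cos(t24))
  ho <- hierarchical_order(X)
  expect_equal(sort(hclust_merge_groups(ho$hclust)[[1]]), c(1, 2))
  expect_equal(nrow(ho$hclust$merge), 2L)        # n - 1 merges
  set.seed(12)
  Y <- matrix(rnorm(5 * 10), nrow = 5)
  hy <- hierarchical_order(Y)
  expect_identical(hclust_merge_groups(hy$hclust),
                   oracle_average_linkage(Y))
  expect_error(hierarchical_order(rbind(rep(1, 4), rnorm(4))), "constant")
})

test_that("two-way ANOVA matches the lm oracle and partitions SS", {
  set.seed(44)
  for (i in 1:5) {
    A <- rep(rep(c("t0", "t12"), each = 3), 4)
    B <- rep(c("liver", "lung", "kidney", "heart"), each = 6)
    v <- rnorm(24)
    fit <- twoway_anova(v, A, B)
    orc <- anova(lm(v ~ factor(A) * factor(B)))
    expect_equal(fit$p_main_A, orc$`Pr(>F)`[1], tolerance = 1e-10)
    expect_equal(fit$p_main_B, orc$`Pr(>F)`[2], tolerance = 1e-10)
    expect_equal(fit$p_interaction, orc$`Pr(>F)`[3], tolerance = 1e-10)
    expect_equal(unname(fit$ss["A"] + fit$ss["B"] + fit$ss["AB"] +
                          fit$ss["error"]),
                 unname(fit$ss["total"]), tolerance = 1e-8)
  }
  # pure additive effects, no noise: zero interaction SS
  A <- rep(c("a1", "a2"), each = 6)
  B <- rep(rep(c("b1", "b2"), each = 3), 2)
  v <- (A == "a2") * 2 + (B == "b2") * 5 + rep(c(-0.1, 0, 0.1), 4)
  fit <- twoway_anova(v, A, B)
  expect_equal(unname(fit$ss["AB"]), 0, tolerance = 1e-12)
  expect_equal(fit$p_interaction, 1)
  expect_error(twoway_anova(v[-1], A[-1], B[-1]), "unbalanced")
})

test_that("two-way ANOVA p values are uniform under the null", {
  set.seed(501)
  nA <- 200
  pA <- pB <- pI <- numeric(nA)
  A <- rep(rep(c("t0", "t12"), each = 3), 4)
  B <- rep(paste0("b", 1:4), each = 6)
  for (i in seq_len(nA)) {
    f <- twoway_anova(rnorm(24), A, B)
    pA[i] <- f$p_main_A; pB[i] <- f$p_main_B; pI[i] <- f$p_interaction
  }
  expect_gt(ks.test(pA, "punif")$p.value, 0.01)
  expect_gt(ks.test(pB, "punif")$p.value, 0.01)
  expect_gt(ks.test(pI, "punif")$p.value, 0.01)
})

test_that("bonferroni post hoc multiplies and caps", {
  A <- rep(rep(c("t0", "t12"), each = 3), 2)
  B <- rep(c("fed", "fasted"), each = 6)
  set.seed(3)
  v <- rnorm(12, sd = 0.5)
  fit <- twoway_anova(v, A, B)
  one <- bonferroni_posthoc(fit, list(list(c("t0", "fed"),
                                           c("t12", "fed"))))
  expect_equal(one$p_bonferroni, one$p_raw)
  two <- bonferroni_posthoc(fit, list(
    list(c("t0", "fed"), c("t12", "fed")),
    list(c("t0", "fasted"), c("t12", "fasted"))))
  expect_equal(two$p_bonferroni, pmin(1, two$p_raw * 2))
  # identical cell means -> p 1, code Ns
  v0 <- rep(rep(c(1, 2, 3), 4))
  fit0 <- twoway_anova(v0, A, B)
  ns <- bonferroni_posthoc(fit0, list(list(c("t0", "fed"),
                                           c("t12", "fed"))))
  expect_equal(ns$p_raw, 1)
  expect_equal(ns$code, "Ns")
  expect_error(bonferroni_posthoc(fit, list()), ">= 1 comparison")
})
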