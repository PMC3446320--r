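# Probe model: quantile normalization, median polish, cluster fits, FIRMA.

test_that("quantile normalization matches the worked examples", {
  m <- cbind(a = c(1, 3, 5), b = c(2, 4, 6))
  qn <- quantile_normalize(m)
  expect_equal(unname(qn[, 1]), c(1.5, 3.5, 5.5))
  expect_equal(unname(qn[, 2]), c(1.5, 3.5, 5.5))

  ident <- cbind(c(2, 7, 4), c(2, 7, 4))
  expect_equal(quantile_normalize(ident), ident)

  # tie rule: tied entries get the mean of the reference ranks they span
  mt <- cbind(c(1, 1, 4), c(2, 3, 5))
  ref <- c(1.5, 2, 4.5)                 # mean of sorted columns
  qt <- quantile_normalize(mt)
  expect_equal(unname(qt[, 1]), c(mean(ref[1:2]), mean(ref[1:2]), ref[3]))
  expect_equal(unname(qt[, 2]), ref)
})

test_that("quantile normalization rejects bad input and is idempotent", {
  expect_error(quantile_normalize(cbind(c(1, 2), c(0, 3))), "positive")
  expect_error(quantile_normalize(cbind(c(1, NA), c(2, 3))), "missing")
  expect_error(quantile_normalize(matrix(1:3, ncol = 1)), ">= 2 samples")
  set.seed(42)
  m <- matrix(rexp(60) + 0.1, ncol = 5)
  once <- quantile_normalize(m)
  expect_equal(quantile_normalize(once), once, tolerance = 1e-12)
  sorted <- apply(once, 2, sort)
  expect_lt(max(abs(sorted - sorted[, 1])), 1e-12)
})

test_that("median polish matches hand-worked examples", {
  fit <- median_polish(rbind(c(1, 2), c(3, 4)))
  expect_equal(fit$overall, 2.5)
  expect_equal(unname(fit$probe_effects), c(-1, 1))
  expect_equal(unname(fit$chip_effects), c(-0.5, 0.5))
  expect_equal(max(abs(fit$residuals)), 0)

  one_row <- median_polish(matrix(c(5, 7), nrow = 1))
  expect_equal(one_row$overall, 6)
  expect_equal(unname(one_row$chip_effects), c(-1, 1))
  expect_equal(max(abs(one_row$residuals)), 0)

  expect_error(median_polish(matrix(c(1, NA), 1)), "finite")
})

test_that("median polish agrees with stats::medpolish and reconstructs", {
  # the sweep sequence is deterministic; stats::medpolish stops on an L1
  # plateau rather than on the adjustment size, so equality is checked at a
  # fixed sweep count (eps = 0 forces the oracle through all iterations)
  for (seed in 1:20) {
    set.seed(seed)
    m <- matrix(rnorm(48), nrow = 6)
    fit <- median_polish(m, max_iter = 8L, tol = 0)
    recon <- fit$overall + outer(fit$probe_effects, fit$chip_effects, "+") +
      fit$residuals
    expect_lt(max(abs(recon - m)), 1e-12)
    orc <- suppressWarnings(stats::medpolish(m, eps = 0, maxiter = 8L,
                                             trace.iter = FALSE))
    expect_equal(fit$overall, orc$overall, tolerance = 1e-12)
    expect_equal(unname(fit$probe_effects), unname(orc$row),
                 tolerance = 1e-12)
    expect_equal(unname(fit$chip_effects), unname(orc$col),
                 tolerance = 1e-12)
  }
  # convergence by the adjustment criterion centers both effect medians
  set.seed(99)
  m <- matrix(rnorm(48), nrow = 6)
  fit <- median_polish(m, max_iter = 500L, tol = 1e-10)
  expect_true(fit$converged)
  expect_lt(abs(median(fit$probe_effects)), 1e-8)
  expect_lt(abs(median(fit$chip_effects)), 1e-8)
})

test_that("noiseless additive data give zero residuals and rhythm recovery", {
  cfg <- simulation_config(n_clusters = 6, probesets_per_cluster = 4,
                           noise_sd = 0, probe_affinity_sd = 0.5,
                           frac_rhythmic_transcripts = 1,
                           frac_circadian_splice = 0,
                           frac_ultradian_splice = 0,
                           phase_mode = "grid", seed = 8)
  ds <- generate_dataset(cfg)
  res <- fit_clusters(ds$intensities, ds$layout, normalize = FALSE)
  for (fit in res$fits) expect_lt(max(abs(fit$residuals)), 1e-9)
  # theta recovers baseline + rhythm up to an additive constant per cluster
  ct <- ds$design$circadian_time
  for (g in seq_len(nrow(res$expression))) {
    cl <- rownames(res$expression)[g]
    ph <- ds$cluster_truth$transcript_phase[ds$cluster_truth$cluster_id == cl]
    expected <- cfg$transcript_amp_log2 * cos(2 * pi * (ct - ph) / 24)
    got <- res$expression[g, ]
    expect_lt(max(abs((got - mean(got)) - (expected - mean(expected)))),
              1e-9)
  }
})

test_that("residual mass concentrates on the planted splice probeset", {
  cfg <- simulation_config(n_clusters = 4, probesets_per_cluster = 8,
                           noise_sd = 0.05,
                           frac_rhythmic_transcripts = 0,
                           frac_circadian_splice = 0.1,
                           frac_ultradian_splice = 0, seed = 13)
  ds <- generate_dataset(cfg)
  res <- fit_clusters(ds$intensities, ds$layout)
  sc <- log2(firma_scores(res))
  rng <- apply(sc, 1L, function(x) diff(range(x)))
  planted <- ds$truth$is_circadian_splice
  expect_gt(min(rng[planted]), max(rng[!planted]))
})

test_that("normalize and background switches reduce to plain log2 + polish", {
  ds <- small_dataset(seed = 2)
  res <- fit_clusters(ds$intensities, ds$layout, normalize = FALSE,
                      background = "none")
  cl <- ds$layout$cluster_id[1L]
  probes <- ds$layout$probe_id[ds$layout$cluster_id == cl]
  direct <- median_polish(log2(ds$intensities[probes, ]))
  expect_equal(res$fits[[cl]]$residuals, direct$residuals)
  expect_equal(res$fits[[cl]]$overall, direct$overall)
})

test_that("firma scores follow the median-residual formula", {
  layout <- data.frame(probe_id = c("p1", "p2", "p3", "q1", "q2", "q3", "q4"),
                       probeset_id = c("ps1", "ps1", "ps1",
                                       "ps2", "ps2", "ps2", "ps2"),
                       cluster_id = "tc1", stringsAsFactors = FALSE)
  resid <- rbind(c(0.5, 0), c(0.5, 0), c(0.7, 0),
                 c(-1, 0), c(-1, 0), c(0, 0), c(0, 0))
  dimnames(resid) <- list(layout$probe_id, c("s1", "s2"))
  fits <- list(tc1 = list(overall = 0,
                          chip_effects = c(s1 = 0, s2 = 0),
                          probe_effects = setNames(rep(0, 7),
                                                   layout$probe_id),
                          residuals = resid))
  f <- firma_scores(fits, layout)
  expect_equal(f["ps1", "s1"], 2^0.5)            # odd-count median
  expect_equal(f["ps2", "s1"], 2^-0.5)           # mean-of-middle-two
  expect_equal(unname(f[, "s2"]), c(1, 1))       # zero residuals -> 1
  expect_error(firma_scores(fits["tc1"],
                            transform(layout, cluster_id = "tc2")),
               "no fit")
})

test_that("layout validation catches duplicates and split probesets", {
  bad_dup <- data.frame(probe_id = c("p1", "p1"),
                        probeset_id = c("a", "a"), cluster_id = "t")
  expect_error(fit_clusters(matrix(1, 1, 2), bad_dup), "duplicate probe")
  bad_split <- data.frame(probe_id = c("p1", "p2"),
                          probeset_id = c("a", "a"),
                          cluster_id = c("t1", "t2"))
  expect_error(validate_layout(bad_split), "more than one cluster")
})
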