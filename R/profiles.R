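# Temporal-profile descriptive machinery: signed fold changes, discrete
# acrophase/amplitude, correlations, smoothing and z-scoring, SNR ranking,
# SOTA and hierarchical clustering, factorial ANOVA with Bonferroni post hoc.

#' Build a replicate-averaged temporal profile
#'
#' @param values numeric measurements.
#' @param times circadian time (hours) of each measurement.
#' @return Data frame with columns `time`, `mean`, `sem`, `n`, ordered by
#'   time; class `temporal_profile`.
#' @export
temporal_profile <- function(values, times) {
  if (length(values) != length(times)) stop("length mismatch", call. = FALSE)
  sp <- split(values, times)
  tt <- as.numeric(names(sp))
  o <- order(tt)
  out <- data.frame(
    time = tt[o],
    mean = vapply(sp, mean, numeric(1))[o],
    sem = vapply(sp, function(x) {
      if (length(x) > 1L) stats::sd(x) / sqrt(length(x)) else 0
    }, numeric(1))[o],
    n = vapply(sp, length, integer(1))[o]
  )
  rownames(out) <- NULL
  class(out) <- c("temporal_profile", "data.frame")
  out
}

#' Signed fold changes versus a reference circadian time
#'
#' The symmetric fold convention: with ratio `rho = mean_t / mean_ref`, the
#' signed fold is `rho` when `rho >= 1` and `-1/rho` otherwise, so a halving
#' is reported as -2 and the reference time maps to +1. This makes "the
#' biggest absolute fold change" well defined for down-going changes.
#'
#' @param profile a [temporal_profile()] (or data frame with `time`, `mean`).
#' @param reference_time anchor time (default: the earliest time present).
#' @return Named numeric vector of signed folds, names = times.
#' @export
fold_changes <- function(profile, reference_time = NULL) {
  if (is.null(reference_time)) reference_time <- min(profile$time)
  ref_idx <- match(reference_time, profile$time)
  if (is.na(ref_idx)) stop("reference time not present", call. = FALSE)
  if (any(profile$mean <= 0)) {
    stop("signed folds require positive means", call. = FALSE)
  }
  rho <- profile$mean / profile$mean[ref_idx]
  fold <- ifelse(rho >= 1, rho, -1 / rho)
  names(fold) <- profile$time
  attr(fold, "reference_time") <- reference_time
  fold
}

#' Discrete acrophase and signed-fold amplitude
#'
#' Acrophase = the sampled circadian time of the largest positive signed fold
#' versus the reference time (peak time); amplitude = the signed fold of
#' largest absolute value. Ties break to the earliest sampled time. These are
#' the discrete estimators appropriate to a 4-point design; no sinusoid is
#' fitted.
#'
#' @param folds named signed-fold vector from [fold_changes()].
#' @return List with `acrophase` (hours), `amplitude` (signed fold) and
#'   `reference_time`.
#' @export
acrophase_amplitude <- function(folds) {
  if (length(folds) < 2L) stop("need folds at >= 2 times", call. = FALSE)
  times <- as.numeric(names(folds))
  acro <- times[which.max(folds)]          # which.max ties -> first = earliest
  amp <- folds[[which.max(abs(folds))]]
  list(acrophase = acro, amplitude = amp,
       reference_time = attr(folds, "reference_time") %||% min(times))
}

#' Pearson correlation between two temporal profiles
#'
#' Aligns the profiles on their shared times and computes Pearson's r on the
#' replicate means, with a two-sided p value from the t transform with n - 2
#' degrees of freedom.
#'
#' @param a,b [temporal_profile()] objects (>= 3 shared times).
#' @return List with `r`, `r_sq` and `p`.
#' @export
profile_correlation <- function(a, b) {
  shared <- intersect(a$time, b$time)
  if (length(shared) < 3L) stop("need >= 3 shared time points", call. = FALSE)
  x <- a$mean[match(shared, a$time)]
  y <- b$mean[match(shared, b$time)]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in a profile", call. = FALSE)
  }
  r <- stats::cor(x, y)
  n <- length(shared)
  if (abs(r) >= 1) {
    p <- 0
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(abs(tstat), n - 2, lower.tail = FALSE)
  }
  list(r = r, r_sq = r^2, p = p)
}

#' Moving-average smoothing followed by z-scoring
#'
#' Centered moving average of width `window` (edge windows truncated to the
#' available points), then rescaling of the smoothed series to mean 0, SD 1
#' over the time course.
#'
#' @param series ordered numeric series (length >= window).
#' @param window odd window width (default 5).
#' @return Numeric series of the same length.
#' @export
smooth_zscore <- function(series, window = 5L) {
  n <- length(series)
  if (n < window) stop("series shorter than window", call. = FALSE)
  sm <- moving_average(series, window)
  s <- stats::sd(sm)
  if (s == 0) stop("zero variance after smoothing", call. = FALSE)
  (sm - mean(sm)) / s
}

# centered moving average, edges truncated to available points
moving_average <- function(series, window) {
  n <- length(series)
  half <- (window - 1L) %/% 2L
  vapply(seq_len(n), function(i) {
    mean(series[max(1L, i - half):min(n, i + half)])
  }, numeric(1))
}

#' Rank profiles by signal-to-noise ratio and two-day reproducibility
#'
#' For each profile measured over two consecutive days: SNR = (max - min) of
#' the two-day concatenation divided by the SD of its residual about a
#' five-point moving average; reproducibility = Pearson r between the two
#' days. Profiles are ranked by descending SNR, then descending r. The
#' day-averaged profile (pointwise mean of equivalent circadian times) is
#' returned for downstream plotting. The SNR formula is a documented
#' stand-in: rank-based shortlisting, not an inferential statistic.
#'
#' @param day1,day2 numeric matrices (profiles x time) of equal shape.
#' @param window smoothing window for the residual SD (default 5).
#' @return List with `ranking` (data frame: `profile_id`, `snr`,
#'   `reproducibility`, `rank`) and `averaged` (profiles x time matrix).
#' @export
snr_rank <- function(day1, day2, window = 5L) {
  day1 <- as.matrix(day1); day2 <- as.matrix(day2)
  if (!all(dim(day1) == dim(day2))) {
    stop("day matrices must have identical shape", call. = FALSE)
  }
  np <- nrow(day1)
  ids <- rownames(day1) %||% sprintf("profile%03d", seq_len(np))
  snr <- repro <- numeric(np)
  for (i in seq_len(np)) {
    both <- c(day1[i, ], day2[i, ])
    resid <- both - moving_average(both, window)
    s <- stats::sd(resid)
    rng <- diff(range(both))
    snr[i] <- if (s == 0) {
      if (rng == 0) 0 else Inf
    } else {
      rng / s
    }
    repro[i] <- if (stats::sd(day1[i, ]) == 0 || stats::sd(day2[i, ]) == 0) {
      0
    } else {
      stats::cor(day1[i, ], day2[i, ])
    }
  }
  o <- order(-snr, -repro)
  ranking <- data.frame(profile_id = ids, snr = snr,
                        reproducibility = repro,
                        rank = order(o), stringsAsFactors = FALSE)
  averaged <- (day1 + day2) / 2
  rownames(averaged) <- ids
  list(ranking = ranking[o, ], averaged = averaged)
}

#' Self-organizing tree (SOTA) clustering of temporal profiles
#'
#' Divisive binary-tree clustering with correlation distance
#' (1 - Pearson r). The tree starts as a single cell holding all profiles;
#' at each growth step the cell with the highest resource (mean
#' member-to-centroid distance) splits into two children, seeded
#' deterministically on its two mutually most-distant members, members are
#' re-assigned to the nearer child, and one training epoch adapts the winner,
#' its parent and its sibling toward each presented profile with learning
#' rates 0.01 / 0.005 / 0.001. Growth stops at `max_clusters` cells. The
#' procedure is fully deterministic given the input order.
#'
#' @param profiles numeric matrix (profiles x time), typically z-scored.
#' @param max_clusters number of terminal cells to grow (<= nrow).
#' @param lr learning rates `c(winner, parent, sibling)`.
#' @return List with `assignment` (named integer vector of cluster labels),
#'   `centroids` (cluster x time matrix) and `resource` (per-cluster mean
#'   distance).
#' @export
sota_cluster <- function(profiles, max_clusters,
                         lr = c(winner = 0.01, parent = 0.005,
                                sibling = 0.001)) {
  X <- as.matrix(profiles)
  np <- nrow(X)
  if (np < max_clusters) {
    stop("fewer profiles than requested clusters", call. = FALSE)
  }
  ids <- rownames(X) %||% sprintf("profile%03d", seq_len(np))
  centroids <- matrix(colMeans(X), nrow = 1L)
  parent_of <- c(NA_integer_)
  sibling_of <- c(NA_integer_)
  is_leaf <- c(TRUE)
  assign_cell <- rep(1L, np)

  leaf_resource <- function(cell) {
    members <- which(assign_cell == cell)
    if (length(members) == 0L) return(-Inf)
    mean(vapply(members, function(i) cor_dist(X[i, ], centroids[cell, ]),
                numeric(1)))
  }

  while (sum(is_leaf) < max_clusters) {
    leaves <- which(is_leaf)
    res <- vapply(leaves, leaf_resource, numeric(1))
    sizes <- vapply(leaves, function(cl) sum(assign_cell == cl), numeric(1))
    splittable <- sizes >= 2L
    if (!any(splittable)) break
    # highest resource among splittable cells; ties -> larger cell, then first
    cand <- leaves[splittable]
    cres <- res[splittable]
    csize <- sizes[splittable]
    target <- cand[order(-cres, -csize)][1L]

    members <- which(assign_cell == target)
    d_to_centroid <- vapply(members, function(i) {
      cor_dist(X[i, ], centroids[target, ])
    }, numeric(1))
    a <- members[which.max(d_to_centroid)]
    d_to_a <- vapply(members, function(i) cor_dist(X[i, ], X[a, ]),
                     numeric(1))
    b <- members[which.max(d_to_a)]

    c1 <- nrow(centroids) + 1L
    c2 <- nrow(centroids) + 2L
    centroids <- rbind(centroids, X[a, ], X[b, ])
    parent_of <- c(parent_of, target, target)
    sibling_of <- c(sibling_of, c2, c1)
    is_leaf[target] <- FALSE
    is_leaf <- c(is_leaf, TRUE, TRUE)

    # re-assign members of the split cell to the nearer child (ties -> first)
    for (i in members) {
      d1 <- cor_dist(X[i, ], centroids[c1, ])
      d2 <- cor_dist(X[i, ], centroids[c2, ])
      assign_cell[i] <- if (d2 < d1) c2 else c1
    }
    # one training epoch over the split cell's members, presentation order
    for (i in members) {
      d1 <- cor_dist(X[i, ], centroids[c1, ])
      d2 <- cor_dist(X[i, ], centroids[c2, ])
      win <- if (d2 < d1) c2 else c1
      sib <- sibling_of[win]
      par <- parent_of[win]
      centroids[win, ] <- centroids[win, ] + lr[[1L]] * (X[i, ] - centroids[win, ])
      if (!is.na(par)) {
        centroids[par, ] <- centroids[par, ] + lr[[2L]] * (X[i, ] - centroids[par, ])
      }
      centroids[sib, ] <- centroids[sib, ] + lr[[3L]] * (X[i, ] - centroids[sib, ])
      assign_cell[i] <- win
    }
  }

  leaves <- which(is_leaf)
  # final assignment of every profile to the nearest terminal cell
  for (i in seq_len(np)) {
    d <- vapply(leaves, function(cl) cor_dist(X[i, ], centroids[cl, ]),
                numeric(1))
    assign_cell[i] <- leaves[which.min(d)]
  }
  labels <- match(assign_cell, leaves)
  names(labels) <- ids
  cent <- centroids[leaves, , drop = FALSE]
  rownames(cent) <- seq_along(leaves)
  colnames(cent) <- colnames(X)
  resource <- vapply(seq_along(leaves), function(k) {
    members <- which(labels == k)
    if (length(members) == 0L) return(NA_real_)
    mean(vapply(members, function(i) cor_dist(X[i, ], cent[k, ]), numeric(1)))
  }, numeric(1))
  list(assignment = labels, centroids = cent, resource = resource)
}

#' Average-linkage hierarchical clustering of profiles
#'
#' Agglomerative clustering with distance 1 - Pearson r and average linkage;
#' returns the merge tree and a leaf order for heat-map rendering. Constant
#' profiles (undefined correlation) are rejected.
#'
#' @param profiles numeric matrix (profiles x time), >= 2 rows.
#' @return List with `hclust` (a [stats::hclust] object), `order` (leaf
#'   indices) and `labels`.
#' @export
hierarchical_order <- function(profiles) {
  X <- as.matrix(profiles)
  if (nrow(X) < 2L) stop("need >= 2 profiles", call. = FALSE)
  sds <- apply(X, 1L, stats::sd)
  if (any(sds == 0)) {
    stop(sprintf("constant profile(s) have undefined correlation: %s",
                 paste(utils::head(which(sds == 0), 5L), collapse = ", ")),
         call. = FALSE)
  }
  d <- stats::as.dist(1 - stats::cor(t(X)))
  hc <- stats::hclust(d, method = "average")
  list(hclust = hc, order = hc$order,
       labels = rownames(X) %||% as.character(seq_len(nrow(X))))
}

#' Balanced two-way fixed-effects ANOVA with interaction
#'
#' Textbook partitioned sums of squares for a balanced complete two-factor
#' design (e.g. circadian time x tissue) with >= 2 replicates per cell.
#'
#' @param values numeric response.
#' @param factor_A,factor_B factor labels (e.g. time and tissue).
#' @return A `twoway_fit` list with `p_main_A`, `p_main_B`, `p_interaction`,
#'   F statistics, the SS table, cell means/sizes, `mse` and `df_error`.
#' @export
twoway_anova <- function(values, factor_A, factor_B) {
  A <- factor(factor_A); B <- factor(factor_B)
  n <- length(values)
  if (length(A) != n || length(B) != n) stop("length mismatch", call. = FALSE)
  tab <- table(A, B)
  if (any(tab == 0L)) stop("incomplete design: empty cell", call. = FALSE)
  if (length(unique(as.vector(tab))) != 1L) {
    stop("unbalanced design: unequal cell sizes", call. = FALSE)
  }
  r <- as.vector(tab)[1L]
  if (r < 2L) stop("need >= 2 replicates per cell", call. = FALSE)
  a <- nlevels(A); b <- nlevels(B)
  grand <- mean(values)
  mA <- tapply(values, A, mean)
  mB <- tapply(values, B, mean)
  mAB <- tapply(values, list(A, B), mean)
  ss_A <- r * b * sum((mA - grand)^2)
  ss_B <- r * a * sum((mB - grand)^2)
  cell_of <- mAB[cbind(A, B)]
  ss_err <- sum((values - cell_of)^2)
  ss_tot <- sum((values - grand)^2)
  ss_AB <- ss_tot - ss_A - ss_B - ss_err
  df_A <- a - 1L; df_B <- b - 1L; df_AB <- df_A * df_B
  df_err <- n - a * b
  mse <- ss_err / df_err
  f_of <- function(ss, df) {
    if (mse == 0) {
      if (ss <= 1e-12) c(F = 0, p = 1) else c(F = Inf, p = 0)
    } else {
      Fv <- (ss / df) / mse
      c(F = Fv, p = stats::pf(Fv, df, df_err, lower.tail = FALSE))
    }
  }
  rA <- f_of(ss_A, df_A); rB <- f_of(ss_B, df_B); rAB <- f_of(ss_AB, df_AB)
  structure(list(
    p_main_A = unname(rA["p"]), p_main_B = unname(rB["p"]),
    p_interaction = unname(rAB["p"]),
    F_main_A = unname(rA["F"]), F_main_B = unname(rB["F"]),
    F_interaction = unname(rAB["F"]),
    ss = c(A = ss_A, B = ss_B, AB = ss_AB, error = ss_err, total = ss_tot),
    df = c(A = df_A, B = df_B, AB = df_AB, error = df_err),
    cell_means = mAB, cell_n = r, mse = mse, df_error = df_err,
    levels_A = levels(A), levels_B = levels(B)
  ), class = "twoway_fit")
}

#' Bonferroni-corrected planned post-hoc comparisons after a two-way ANOVA
#'
#' For each planned cell-pair comparison (e.g. the two circadian times within
#' each feeding condition), a t statistic using the factorial fit's pooled
#' mean squared error and its degrees of freedom; the raw two-sided p is
#' multiplied by the number of planned comparisons and capped at 1.
#' Significance codes: `****` < 0.0001, `***` < 0.001, `**` < 0.01,
#' `*` < 0.05, otherwise `Ns`.
#'
#' @param fit a `twoway_fit` from [twoway_anova()].
#' @param planned list of comparisons, each a list/vector of two cells, a
#'   cell being `c(level_A, level_B)`.
#' @return Data frame: `comparison`, `estimate`, `t`, `p_raw`, `p_bonferroni`,
#'   `code`.
#' @export
bonferroni_posthoc <- function(fit, planned) {
  stopifnot(inherits(fit, "twoway_fit"))
  if (length(planned) == 0L) {
    stop("`planned` must list >= 1 comparison", call. = FALSE)
  }
  m <- length(planned)
  rows <- lapply(planned, function(cmp) {
    c1 <- cmp[[1L]]; c2 <- cmp[[2L]]
    get_mean <- function(cell) {
      i <- match(cell[[1L]], fit$levels_A)
      j <- match(cell[[2L]], fit$levels_B)
      if (is.na(i) || is.na(j)) {
        stop(sprintf("unknown cell (%s, %s)", cell[[1L]], cell[[2L]]),
             call. = FALSE)
      }
      fit$cell_means[i, j]
    }
    est <- get_mean(c1) - get_mean(c2)
    se <- sqrt(fit$mse * 2 / fit$cell_n)
    if (se == 0) {
      tstat <- if (est == 0) 0 else sign(est) * Inf
      p <- if (est == 0) 1 else 0
    } else {
      tstat <- est / se
      p <- 2 * stats::pt(abs(tstat), fit$df_error, lower.tail = FALSE)
    }
    data.frame(
      comparison = sprintf("(%s,%s) vs (%s,%s)", c1[[1L]], c1[[2L]],
                           c2[[1L]], c2[[2L]]),
      estimate = est, t = tstat, p_raw = p,
      p_bonferroni = min(1, p * m),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out$code <- vapply(out$p_bonferroni, function(p) {
    if (p < 1e-4) "****" else if (p < 1e-3) "***" else if (p < 0.01) "**"
    else if (p < 0.05) "*" else "Ns"
  }, character(1))
  out
}
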