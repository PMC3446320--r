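# The circadian screen on log2 FIRMA scores: per-probeset one-way time ANOVA
# with BH FDR control, optional empirical-Bayes variance moderation, and the
# antiphase ([CT0, CT12] vs [CT6, CT18]) ultradian-exclusion contrast.

#' Classical one-way fixed-effects ANOVA
#'
#' @param values numeric measurements.
#' @param groups group labels (coerced to factor), >= 2 groups and total
#'   n > number of groups.
#' @return List with `F`, `p`, `df_between`, `df_within`, `s_sq` (residual
#'   variance, the moderation input) and `degenerate` (TRUE when the
#'   within-group variance is exactly zero, in which case `p` is 0 when the
#'   group means differ and 1 when they do not).
#' @examples
#' oneway_anova(c(1, 2, 3, 3, 4, 5), rep(c("a", "b"), each = 3))
#' @export
oneway_anova <- function(values, groups) {
  groups <- factor(groups)
  k <- nlevels(groups)
  n <- length(values)
  if (k < 2L) stop("need >= 2 groups", call. = FALSE)
  if (n <= k) stop("need total n > number of groups", call. = FALSE)
  if (length(groups) != n) stop("length mismatch", call. = FALSE)
  gm <- tapply(values, groups, mean)
  gn <- tabulate(groups)
  grand <- mean(values)
  ss_between <- sum(gn * (gm[levels(groups)] - grand)^2)
  ss_within <- sum((values - gm[groups])^2)
  df_b <- k - 1L
  df_w <- n - k
  s_sq <- ss_within / df_w
  if (s_sq == 0) {
    degenerate <- TRUE
    if (ss_between == 0) {
      Fstat <- 0; p <- 1
    } else {
      Fstat <- Inf; p <- 0
    }
  } else {
    degenerate <- FALSE
    Fstat <- (ss_between / df_b) / s_sq
    p <- stats::pf(Fstat, df_b, df_w, lower.tail = FALSE)
  }
  list(F = unname(Fstat), p = unname(p), df_between = df_b, df_within = df_w,
       s_sq = unname(s_sq), degenerate = degenerate)
}

# Inverse of trigamma by Newton iteration on 1/x (monotone, globally
# convergent for y > 0); the standard approach for the log-variance
# method-of-moments fit.
trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, 2L)
    x <- x + dif
    if (abs(dif / x) < 1e-10) break
  }
  x
}

#' Empirical-Bayes moderation of per-probeset variances
#'
#' Fits a scaled inverse-chi-square prior `s0_sq * d0 / chisq_d0` to the
#' observed residual variances by method of moments on the log variances
#' (trigamma matching), then shrinks each variance toward the prior:
#' `s_tilde_sq = (d0 * s0_sq + df * s_sq) / (d0 + df)`. When the observed
#' spread of log variances does not exceed the sampling spread, `d0` is
#' infinite and all variances are pooled.
#'
#' @param s_sq_list per-probeset residual variances (>= 10 positive values).
#' @param df residual degrees of freedom of each variance (scalar).
#' @param d0 optional: force the prior degrees of freedom (`0` disables
#'   moderation, `Inf` pools completely).
#' @return List with `d0`, `s0_sq` and `s_tilde_sq` (moderated variances).
#' @export
moderate <- function(s_sq_list, df, d0 = NULL) {
  s_sq <- as.numeric(s_sq_list)
  if (any(s_sq < 0, na.rm = TRUE)) {
    stop("negative variances are not allowed", call. = FALSE)
  }
  ok <- is.finite(s_sq) & s_sq > 0
  if (is.null(d0) && sum(ok) < 10L) {
    stop("need >= 10 probesets with positive variance to fit the prior",
         call. = FALSE)
  }
  if (is.null(d0)) {
    z <- log(s_sq[ok])
    # E[log s^2] = log s0^2 + digamma(df/2) - log(df/2)
    #            - digamma(d0/2) + log(d0/2); Var matches by trigamma.
    e <- z - digamma(df / 2) + log(df / 2)
    n <- length(e)
    evar <- mean((e - mean(e))^2) * n / (n - 1) - trigamma(df / 2)
    if (is.finite(evar) && evar > 0) {
      d0 <- 2 * trigamma_inverse(evar)
      s0_sq <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
    } else {
      # observed spread within sampling spread: complete pooling, with the
      # geometric mean as the pooled value so that identical variances
      # shrink to themselves exactly
      d0 <- Inf
      s0_sq <- exp(mean(log(s_sq[ok])))
    }
  } else {
    s0_sq <- if (is.infinite(d0)) {
      exp(mean(log(s_sq[ok])))
    } else if (d0 == 0) {
      mean(s_sq[ok])  # unused when d0 = 0
    } else {
      stop("forced d0 must be 0 or Inf", call. = FALSE)
    }
  }
  s_tilde <- if (is.infinite(d0)) {
    rep(s0_sq, length(s_sq))
  } else if (d0 == 0) {
    s_sq
  } else {
    (d0 * s0_sq + df * s_sq) / (d0 + df)
  }
  list(d0 = d0, s0_sq = s0_sq, s_tilde_sq = s_tilde)
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' @param p_list p values in `[0, 1]`.
#' @return Adjusted q values, order-aligned with the input, monotone in p and
#'   capped at 1.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))
#' @export
bh_adjust <- function(p_list) {
  p <- as.numeric(p_list)
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p values must lie in [0, 1]", call. = FALSE)
  }
  m <- length(p)
  if (m == 0L) return(numeric(0))
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  q <- pmin(1, cummin(m / (m:1) * p[o]))[ro]
  q
}

#' Antiphase two-pool contrast (ultradian exclusion)
#'
#' Pools circadian times 12 h apart (`{t, t+12}`) into two antiphase groups —
#' for the canonical 4-point design, `{CT0, CT12}` versus `{CT6, CT18}` — and
#' tests their difference with a pooled-variance two-sample t statistic. A
#' 24-h sinusoid cancels between the pools (expected difference 0) while a
#' 12-h sinusoid adds coherently, so significance here flags an ultradian,
#' not circadian, profile.
#'
#' @param values numeric measurements (log2 FIRMA scores).
#' @param ct_labels circadian times (hours) of each value; the distinct times
#'   must pair up modulo 12 into exactly two pools.
#' @param s_tilde_sq optional moderated variance replacing the two-sample
#'   pooled variance (used by the moderated screen); `extra_df` is then added
#'   to the residual degrees of freedom.
#' @param extra_df prior degrees of freedom added when `s_tilde_sq` is given.
#' @return List with `stat` (t), `p` (two-sided), `df` and `degenerate`.
#' @export
antiphase_test <- function(values, ct_labels, s_tilde_sq = NULL,
                           extra_df = 0) {
  ct <- as.numeric(ct_labels)
  if (length(ct) != length(values)) stop("length mismatch", call. = FALSE)
  phase_class <- ct %% 12
  classes <- sort(unique(phase_class))
  if (length(classes) != 2L) {
    stop("circadian times must split into exactly two antiphase pools",
         call. = FALSE)
  }
  # every time must have its 12 h partner or be alone in its pool; pools are
  # defined purely by t mod 12
  g1 <- values[phase_class == classes[1L]]
  g2 <- values[phase_class == classes[2L]]
  if (length(g1) == 0L || length(g2) == 0L) {
    stop("empty antiphase pool", call. = FALSE)
  }
  n1 <- length(g1); n2 <- length(g2)
  diff <- mean(g1) - mean(g2)
  if (is.null(s_tilde_sq)) {
    df <- n1 + n2 - 2L
    s2 <- (sum((g1 - mean(g1))^2) + sum((g2 - mean(g2))^2)) / df
  } else {
    s2 <- s_tilde_sq
    df <- n1 + n2 - 2L + extra_df
  }
  se <- sqrt(s2 * (1 / n1 + 1 / n2))
  if (se == 0) {
    if (diff == 0) {
      return(list(stat = 0, p = 1, df = df, degenerate = TRUE))
    }
    return(list(stat = sign(diff) * Inf, p = 0, df = df, degenerate = TRUE))
  }
  stat <- diff / se
  p <- 2 * stats::pt(abs(stat), df, lower.tail = FALSE)
  list(stat = stat, p = p, df = df, degenerate = FALSE)
}

#' Screen probesets for circadian variation in FIRMA score
#'
#' The discovery screen: per probeset, a one-way ANOVA of log2 FIRMA score
#' across circadian-time groups (moderated by default), BH FDR adjustment
#' over all tested probesets, then the [antiphase_test()] (also BH-adjusted)
#' removes probesets whose profile is consistent with a 12-h rather than a
#' 24-h rhythm. Candidates are probesets with `q_time < alpha` and not
#' `q_anti < alpha`.
#'
#' @param scores probeset x sample FIRMA score matrix (linear scale).
#' @param design sample-design data frame with `sample_id` and
#'   `circadian_time`; must cover all score columns, with >= 2 replicates per
#'   circadian time.
#' @param alpha FDR level (default 0.05).
#' @param moderated use empirical-Bayes moderated statistics (default TRUE).
#' @param anti_universe `"all"` (default) computes the antiphase FDR over all
#'   tested probesets; `"kept"` restricts it to the time-significant set.
#' @return Data frame with one row per probeset: `probeset_id`, `F_time`,
#'   `p_time`, `q_time`, `stat_anti`, `p_anti`, `q_anti`, `degenerate`,
#'   `is_candidate`; moderation parameters in attribute `"moderation"`.
#' @export
screen_circadian <- function(scores, design, alpha = 0.05,
                             moderated = TRUE,
                             anti_universe = c("all", "kept")) {
  anti_universe <- match.arg(anti_universe)
  if (is.null(colnames(scores))) {
    stop("`scores` must have sample ids as colnames", call. = FALSE)
  }
  idx <- match(colnames(scores), design$sample_id)
  if (anyNA(idx)) {
    stop(sprintf("samples missing from design: %s",
                 paste(colnames(scores)[is.na(idx)][1:min(5, sum(is.na(idx)))],
                       collapse = ", ")), call. = FALSE)
  }
  ct <- design$circadian_time[idx]
  if (any(table(ct) < 2L)) {
    stop("need >= 2 replicates per circadian time", call. = FALSE)
  }
  logf <- log2(scores)
  np <- nrow(logf)
  F_raw <- p_time <- s_sq <- stat_anti <- p_anti <- numeric(np)
  degenerate <- logical(np)
  groups <- factor(ct)
  for (i in seq_len(np)) {
    a <- oneway_anova(logf[i, ], groups)
    F_raw[i] <- a$F; p_time[i] <- a$p; s_sq[i] <- a$s_sq
    degenerate[i] <- a$degenerate
  }
  df_w <- length(ct) - nlevels(groups)
  df_b <- nlevels(groups) - 1L

  mod <- NULL
  if (moderated) {
    fit_ok <- !degenerate
    if (sum(fit_ok) >= 10L) {
      mod <- moderate(s_sq[fit_ok], df_w)
      s_tilde <- s_sq
      s_tilde[fit_ok] <- mod$s_tilde_sq
      ratio <- ifelse(s_tilde > 0, s_sq / s_tilde, 1)
      F_time <- F_raw * ratio
      df2 <- df_w + mod$d0
      p_time <- ifelse(degenerate, p_time,
                       stats::pf(F_time, df_b, df2, lower.tail = FALSE))
    } else {
      moderated <- FALSE
      F_time <- F_raw
    }
  } else {
    F_time <- F_raw
  }
  if (!moderated) s_tilde <- NULL

  for (i in seq_len(np)) {
    at <- if (moderated && !degenerate[i]) {
      antiphase_test(logf[i, ], ct, s_tilde_sq = s_tilde[i],
                     extra_df = df_w + mod$d0 - (length(ct) - 2L))
    } else {
      antiphase_test(logf[i, ], ct)
    }
    stat_anti[i] <- at$stat; p_anti[i] <- at$p
  }

  q_time <- bh_adjust(p_time)
  kept <- q_time < alpha
  if (anti_universe == "all") {
    q_anti <- bh_adjust(p_anti)
  } else {
    q_anti <- rep(NA_real_, np)
    if (any(kept)) q_anti[kept] <- bh_adjust(p_anti[kept])
  }
  is_candidate <- kept & !(!is.na(q_anti) & q_anti < alpha)

  out <- data.frame(
    probeset_id = rownames(logf) %||% sprintf("ps%05d", seq_len(np)),
    F_time = F_time, p_time = p_time, q_time = q_time,
    stat_anti = stat_anti, p_anti = p_anti, q_anti = q_anti,
    degenerate = degenerate,
    is_candidate = is_candidate,
    stringsAsFactors = FALSE
  )
  attr(out, "moderation") <- mod
  attr(out, "alpha") <- alpha
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
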