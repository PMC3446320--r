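# Independent oracle implementations used to cross-check the package; these
# deliberately take a different computational route than the code under test.

# one-way ANOVA through R's linear-model machinery
oracle_anova <- function(values, groups) {
  fit <- stats::anova(stats::lm(values ~ factor(groups)))
  list(F = fit$`F value`[1L], p = fit$`Pr(>F)`[1L],
       s_sq = fit$`Mean Sq`[2L])
}

# brute-force one-tailed Fisher p: enumerate every table with the observed
# margins and sum the hypergeometric probabilities of tables at least as
# enriched (a' >= a)
oracle_fisher_onetail <- function(a, b, c, d) {
  m <- a + c          # total with motif
  n <- b + d          # total without
  k <- a + b          # rhythmic set size
  lo <- max(0L, k - n)
  hi <- min(k, m)
  probs <- vapply(lo:hi, function(x) {
    choose(m, x) * choose(n, k - x) / choose(m + n, k)
  }, numeric(1))
  sum(probs[(lo:hi) >= a])
}

# brute-force both-strand PSSM scan: per window, explicit products of motif
# and background probabilities on the literal (rev-complemented) reads
oracle_scan <- function(seq, pssm, background = rep(0.25, 4), threshold = 8) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  bases <- c("A", "C", "G", "T")
  bg <- stats::setNames(background, bases)
  s <- strsplit(toupper(seq), "")[[1]]
  w <- pssm$width
  out <- list()
  for (i in seq_len(max(0L, length(s) - w + 1L))) {
    win <- s[i:(i + w - 1L)]
    if (any(!win %in% bases)) next
    fwd <- sum(log2(pssm$prob[cbind(match(win, bases), seq_len(w))] /
                      bg[win]))
    rc <- rev(unname(comp[win]))
    rev_ <- sum(log2(pssm$prob[cbind(match(rc, bases), seq_len(w))] /
                       bg[rc]))
    if (fwd >= threshold) out[[length(out) + 1L]] <- c(i, 1, fwd)
    if (rev_ >= threshold) out[[length(out) + 1L]] <- c(i, -1, rev_)
  }
  if (length(out) == 0L) {
    return(data.frame(position = integer(0), strand = character(0),
                      score = numeric(0)))
  }
  m <- do.call(rbind, out)
  data.frame(position = as.integer(m[, 1L]),
             strand = ifelse(m[, 2L] > 0, "+", "-"),
             score = m[, 3L], stringsAsFactors = FALSE)
}

# brute-force average-linkage agglomeration; returns the merge sequence as a
# list of sorted member-index pairs of the two merged groups
oracle_average_linkage <- function(X) {
  n <- nrow(X)
  D <- 1 - stats::cor(t(X))
  groups <- as.list(seq_len(n))
  merges <- list()
  while (length(groups) > 1L) {
    best <- c(NA, NA); bestd <- Inf
    for (i in seq_along(groups)) {
      for (j in seq_along(groups)) {
        if (j <= i) next
        d <- mean(D[groups[[i]], groups[[j]]])
        if (d < bestd) { bestd <- d; best <- c(i, j) }
      }
    }
    merges[[length(merges) + 1L]] <-
      sort(c(groups[[best[1L]]], groups[[best[2L]]]))
    groups[[best[1L]]] <- c(groups[[best[1L]]], groups[[best[2L]]])
    groups[[best[2L]]] <- NULL
  }
  merges
}

# hclust merge matrix -> the same member-pair representation
hclust_merge_groups <- function(hc) {
  n <- length(hc$order)
  members <- vector("list", nrow(hc$merge))
  out <- list()
  for (k in seq_len(nrow(hc$merge))) {
    get <- function(v) if (v < 0) -v else members[[v]]
    members[[k]] <- sort(c(get(hc$merge[k, 1L]), get(hc$merge[k, 2L])))
    out[[k]] <- members[[k]]
  }
  out
}

# adjusted Rand index between two labelings
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  nij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  n2 <- choose(sum(tab), 2)
  expected <- ai * bj / n2
  (nij - expected) / ((ai + bj) / 2 - expected)
}

# moving-average oracle: explicit truncated windows
oracle_moving_average <- function(x, w) {
  half <- (w - 1) %/% 2
  sapply(seq_along(x), function(i) {
    mean(x[max(1, i - half):min(length(x), i + half)])
  })
}

# small default dataset shared by several tests (kept modest for speed)
small_dataset <- function(seed = 7, ...) {
  generate_dataset(simulation_config(n_clusters = 25,
                                     probesets_per_cluster = 8,
                                     seed = seed, ...))
}
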