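# Synthetic probe-level exon-array data with planted circadian structure.
#
# The generator emulates the additive RMA world: log2 probe intensity =
# cluster baseline + 24-h transcript rhythm + probe affinity + exon-restricted
# splice departure + Gaussian noise, then returns linear-scale intensities.

#' Simulation configuration for the synthetic exon-array generator
#'
#' Bundles and validates all parameters of [generate_dataset()]. Defaults
#' describe a liver-like circadian time course: 4 circadian times (CT 0, 6,
#' 12, 18) with 3 replicates each, 1000 exon-probesets (125 transcript
#' clusters of 8 probesets, 4 probes per probeset, mirroring the core-gene
#' structure of a mouse exon array), a 24-h transcript rhythm
#' in 30% of clusters, and a 24-h splice departure (log2 amplitude 0.5)
#' planted in 5% of probesets, with another 5% given a 12-h (ultradian)
#' departure.
#'
#' @param n_clusters number of transcript clusters (genes).
#' @param probesets_per_cluster exon-probesets per cluster.
#' @param probes_per_probeset probes per exon-probeset.
#' @param ct_grid circadian times in hours, strictly increasing in `[0, 24)`.
#' @param n_reps replicates per circadian time (must be >= 2).
#' @param baseline_log2 mean log2 expression level.
#' @param transcript_amp_log2 log2 amplitude of the 24-h transcript rhythm.
#' @param frac_rhythmic_transcripts fraction of clusters given a transcript
#'   rhythm.
#' @param frac_circadian_splice fraction of probesets given a 24-h splice
#'   departure.
#' @param splice_amp_log2 log2 amplitude of the splice departure.
#' @param frac_ultradian_splice fraction of probesets given a 12-h departure
#'   (disjoint from the circadian set).
#' @param probe_affinity_sd SD of per-probe affinity effects (log2).
#' @param noise_sd residual SD (log2).
#' @param phase_mode `"grid"` draws planted phases from `ct_grid` so they are
#'   exactly recoverable by the discrete acrophase estimator; `"continuous"`
#'   draws them uniformly from `[0, 24)`.
#' @param seed integer seed; mandatory so runs are reproducible.
#' @return A `simulation_config` list.
#' @examples
#' cfg <- simulation_config(n_clusters = 10, probesets_per_cluster = 4, seed = 1)
#' @export
simulation_config <- function(n_clusters = 125L,
                              probesets_per_cluster = 8L,
                              probes_per_probeset = 4L,
                              ct_grid = c(0, 6, 12, 18),
                              n_reps = 3L,
                              baseline_log2 = 8,
                              transcript_amp_log2 = 1,
                              frac_rhythmic_transcripts = 0.3,
                              frac_circadian_splice = 0.05,
                              splice_amp_log2 = 0.5,
                              frac_ultradian_splice = 0.05,
                              probe_affinity_sd = 1,
                              noise_sd = 0.2,
                              phase_mode = c("grid", "continuous"),
                              seed) {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  phase_mode <- match.arg(phase_mode)
  n_clusters <- check_count(n_clusters, "n_clusters")
  probesets_per_cluster <- check_count(probesets_per_cluster,
                                       "probesets_per_cluster")
  probes_per_probeset <- check_count(probes_per_probeset,
                                     "probes_per_probeset")
  n_reps <- check_count(n_reps, "n_reps", min = 2L)
  if (length(ct_grid) < 1L) stop("`ct_grid` must be non-empty", call. = FALSE)
  if (any(ct_grid < 0 | ct_grid >= 24) || is.unsorted(ct_grid, strictly = TRUE)) {
    stop("`ct_grid` must be strictly increasing within [0, 24)", call. = FALSE)
  }
  check_frac(frac_rhythmic_transcripts, "frac_rhythmic_transcripts")
  check_frac(frac_circadian_splice, "frac_circadian_splice")
  check_frac(frac_ultradian_splice, "frac_ultradian_splice")
  if (frac_circadian_splice + frac_ultradian_splice > 1) {
    stop("circadian and ultradian splice fractions must sum to <= 1",
         call. = FALSE)
  }
  if (probe_affinity_sd < 0 || noise_sd < 0) {
    stop("standard deviations must be >= 0", call. = FALSE)
  }
  structure(list(
    n_clusters = n_clusters,
    probesets_per_cluster = probesets_per_cluster,
    probes_per_probeset = probes_per_probeset,
    ct_grid = as.numeric(ct_grid),
    n_reps = n_reps,
    baseline_log2 = baseline_log2,
    transcript_amp_log2 = transcript_amp_log2,
    frac_rhythmic_transcripts = frac_rhythmic_transcripts,
    frac_circadian_splice = frac_circadian_splice,
    splice_amp_log2 = splice_amp_log2,
    frac_ultradian_splice = frac_ultradian_splice,
    probe_affinity_sd = probe_affinity_sd,
    noise_sd = noise_sd,
    phase_mode = phase_mode,
    seed = as.integer(seed)
  ), class = "simulation_config")
}

#' Generate a synthetic probe-level exon-array dataset
#'
#' Simulates linear-scale probe intensities with known planted structure.
#' For probe k of probeset j in cluster g, measured at circadian time t:
#' \deqn{\log_2 I = b_g + A_g \cos(2\pi (t - \phi_g)/24) + p_k + \delta_j(t) + \epsilon}
#' where the splice departure \eqn{\delta_j(t) = a_j \cos(2\pi (t - \phi_j)/P_j)}
#' is nonzero only for probesets flagged in the truth table (period
#' \eqn{P_j} = 24 h for circadian, 12 h for ultradian departures),
#' \eqn{p_k \sim N(0, \sigma_p^2)} and \eqn{\epsilon \sim N(0, \sigma^2)}.
#' Identical configurations (including seed) give bit-identical datasets.
#'
#' @param config a [simulation_config()].
#' @return A `synthetic_dataset` list with elements `layout` (probe ->
#'   probeset -> cluster data frame), `intensities` (probe x sample matrix,
#'   linear scale), `design` (sample data frame with `circadian_time`),
#'   `truth` (per-probeset planted ground truth), `cluster_truth`
#'   (per-cluster rhythm parameters) and `config`.
#' @examples
#' ds <- generate_dataset(simulation_config(n_clusters = 5, seed = 42))
#' dim(ds$intensities)
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed, {
    G <- config$n_clusters
    J <- config$probesets_per_cluster
    K <- config$probes_per_probeset
    P <- G * J

    cluster_ids <- sprintf("TC%04d", seq_len(G))
    probeset_ids <- sprintf("%s_PS%02d", rep(cluster_ids, each = J),
                            rep(seq_len(J), times = G))
    probe_ids <- sprintf("%s_p%02d", rep(probeset_ids, each = K),
                         rep(seq_len(K), times = P))
    layout <- data.frame(
      probe_id = probe_ids,
      probeset_id = rep(probeset_ids, each = K),
      cluster_id = rep(cluster_ids, each = J * K),
      stringsAsFactors = FALSE
    )

    ct <- rep(config$ct_grid, each = config$n_reps)
    rep_idx <- rep(seq_len(config$n_reps), times = length(config$ct_grid))
    sample_ids <- sprintf("CT%02d_r%d", ct, rep_idx)
    design <- data.frame(
      sample_id = sample_ids,
      circadian_time = ct,
      tissue = "liver",
      feeding = "ad_libitum",
      genotype = "wt",
      replicate = rep_idx,
      stringsAsFactors = FALSE
    )

    draw_phase <- function(n) {
      if (config$phase_mode == "grid") {
        config$ct_grid[sample.int(length(config$ct_grid), n, replace = TRUE)]
      } else {
        stats::runif(n, 0, 24)
      }
    }

    # cluster-level transcript rhythms
    n_rhy <- frac_count(config$frac_rhythmic_transcripts, G)
    rhythmic <- rep(FALSE, G)
    rhythmic[sample.int(G, n_rhy)] <- TRUE
    cluster_phase <- rep(NA_real_, G)
    cluster_phase[rhythmic] <- draw_phase(sum(rhythmic))
    cluster_truth <- data.frame(
      cluster_id = cluster_ids,
      is_rhythmic = rhythmic,
      transcript_phase = cluster_phase,
      transcript_amp_log2 = ifelse(rhythmic, config$transcript_amp_log2, 0),
      stringsAsFactors = FALSE
    )

    # probeset-level splice departures (circadian and ultradian disjoint)
    n_circ <- frac_count(config$frac_circadian_splice, P)
    n_ultra <- frac_count(config$frac_ultradian_splice, P)
    flagged <- sample.int(P, n_circ + n_ultra)
    is_circ <- rep(FALSE, P)
    is_ultra <- rep(FALSE, P)
    if (n_circ > 0) is_circ[flagged[seq_len(n_circ)]] <- TRUE
    if (n_ultra > 0) is_ultra[flagged[n_circ + seq_len(n_ultra)]] <- TRUE
    splice_phase <- rep(NA_real_, P)
    splice_phase[is_circ | is_ultra] <- draw_phase(sum(is_circ | is_ultra))

    ps_cluster_idx <- rep(seq_len(G), each = J)
    truth <- data.frame(
      probeset_id = probeset_ids,
      cluster_id = cluster_ids[ps_cluster_idx],
      is_circadian_splice = is_circ,
      splice_phase = splice_phase,
      splice_amp_log2 = ifelse(is_circ | is_ultra, config$splice_amp_log2, 0),
      is_ultradian = is_ultra,
      cluster_is_rhythmic = rhythmic[ps_cluster_idx],
      transcript_phase = cluster_phase[ps_cluster_idx],
      stringsAsFactors = FALSE
    )

    n_samples <- length(sample_ids)
    n_probes <- nrow(layout)
    probe_affinity <- stats::rnorm(n_probes, 0, config$probe_affinity_sd)

    # transcript-level log2 signal per cluster x sample
    tc_signal <- matrix(config$baseline_log2, nrow = G, ncol = n_samples)
    if (any(rhythmic)) {
      for (g in which(rhythmic)) {
        tc_signal[g, ] <- tc_signal[g, ] + config$transcript_amp_log2 *
          cos(2 * pi * (ct - cluster_phase[g]) / 24)
      }
    }
    # probeset-level splice departure per probeset x sample
    ps_delta <- matrix(0, nrow = P, ncol = n_samples)
    for (j in which(is_circ | is_ultra)) {
      period <- if (is_circ[j]) 24 else 12
      ps_delta[j, ] <- truth$splice_amp_log2[j] *
        cos(2 * pi * (ct - splice_phase[j]) / period)
    }

    probe_ps_idx <- rep(seq_len(P), each = K)
    probe_cl_idx <- rep(seq_len(G), each = J * K)
    log2_int <- tc_signal[probe_cl_idx, , drop = FALSE] +
      ps_delta[probe_ps_idx, , drop = FALSE] +
      matrix(probe_affinity, nrow = n_probes, ncol = n_samples) +
      matrix(stats::rnorm(n_probes * n_samples, 0, config$noise_sd),
             nrow = n_probes)
    intensities <- 2^log2_int
    dimnames(intensities) <- list(probe_ids, sample_ids)

    structure(list(
      layout = layout,
      intensities = intensities,
      design = design,
      truth = truth,
      cluster_truth = cluster_truth,
      config = config
    ), class = "synthetic_dataset")
  })
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("synthetic exon-array dataset\n")
  cat(sprintf("  %d probes, %d probesets, %d clusters, %d samples\n",
              nrow(x$layout), length(unique(x$layout$probeset_id)),
              length(unique(x$layout$cluster_id)), ncol(x$intensities)))
  cat(sprintf("  planted: %d circadian-splice, %d ultradian probesets\n",
              sum(x$truth$is_circadian_splice), sum(x$truth$is_ultradian)))
  invisible(x)
}

# latent log2 signals for a probeset: transcript level and exon level,
# evaluated on the dataset's design. Used by the QPCR emulator.
latent_signals <- function(dataset, probeset_id) {
  tr <- dataset$truth[dataset$truth$probeset_id == probeset_id, ]
  if (nrow(tr) != 1L) {
    stop(sprintf("unknown probeset '%s'", probeset_id), call. = FALSE)
  }
  cfg <- dataset$config
  t <- dataset$design$circadian_time
  transcript <- rep(cfg$baseline_log2, length(t))
  if (tr$cluster_is_rhythmic) {
    transcript <- transcript + cfg$transcript_amp_log2 *
      cos(2 * pi * (t - tr$transcript_phase) / 24)
  }
  delta <- rep(0, length(t))
  if (tr$is_circadian_splice || tr$is_ultradian) {
    period <- if (tr$is_circadian_splice) 24 else 12
    delta <- tr$splice_amp_log2 * cos(2 * pi * (t - tr$splice_phase) / period)
  }
  list(transcript = transcript, exon = transcript + delta)
}

#' Emulate a QPCR validation experiment from a synthetic dataset
#'
#' For each target probeset, emits pseudo-Ct values for an exon-specific assay
#' and a transcript-level assay, consistent with the dataset's latent log2
#' signals via `Ct = offset - latent_log2 / log2(efficiency)`, plus a
#' constant-expression normalizer assay (`Actb`).
#'
#' @param dataset a `synthetic_dataset`.
#' @param targets character vector of probeset ids present in the layout.
#' @param efficiency per-cycle amplification gain (> 1; 2 = perfect doubling).
#' @param ct_offset Ct value of a hypothetical zero-log2 template.
#' @param ct_noise_sd Gaussian noise SD added to Ct values (default 0).
#' @param seed seed for the Ct noise.
#' @return Data frame with columns `sample_id`, `target`, `assay`
#'   (`exon` / `transcript` / `normalizer`), `mode` (`"Ct"`), `value`,
#'   `efficiency`.
#' @export
generate_qpcr <- function(dataset, targets, efficiency = 2,
                          ct_offset = 35, ct_noise_sd = 0, seed = 1L) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  if (efficiency <= 1) stop("`efficiency` must be > 1", call. = FALSE)
  missing_t <- setdiff(targets, dataset$truth$probeset_id)
  if (length(missing_t) > 0) {
    stop(sprintf("targets not in layout: %s",
                 paste(missing_t, collapse = ", ")), call. = FALSE)
  }
  with_seed(seed, {
    rows <- list()
    le <- log2(efficiency)
    n <- nrow(dataset$design)
    for (tgt in targets) {
      lat <- latent_signals(dataset, tgt)
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = dataset$design$sample_id,
        target = paste0(tgt, "_exon"),
        assay = "exon",
        mode = "Ct",
        value = ct_offset - lat$exon / le + stats::rnorm(n, 0, ct_noise_sd),
        efficiency = efficiency,
        stringsAsFactors = FALSE
      )
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = dataset$design$sample_id,
        target = paste0(tgt, "_transcript"),
        assay = "transcript",
        mode = "Ct",
        value = ct_offset - lat$transcript / le +
          stats::rnorm(n, 0, ct_noise_sd),
        efficiency = efficiency,
        stringsAsFactors = FALSE
      )
    }
    rows[[length(rows) + 1L]] <- data.frame(
      sample_id = dataset$design$sample_id,
      target = "Actb",
      assay = "normalizer",
      mode = "Ct",
      value = ct_offset - dataset$config$baseline_log2 / le +
        stats::rnorm(n, 0, ct_noise_sd),
      efficiency = efficiency,
      stringsAsFactors = FALSE
    )
    do.call(rbind, rows)
  })
}

#' Generate promoter sequence sets with a planted motif
#'
#' Builds uniform-random ACGT sequences and plants a consensus motif at a
#' random position and strand in stated fractions of a "foreground"
#' (rhythmic) and a "background" (control) set. The paired truth table makes
#' motif-scan and enrichment recovery testable.
#'
#' @param n_fg,n_bg number of foreground / background sequences.
#' @param length sequence length in bases (>= motif width).
#' @param planted_motif consensus to plant (ACGT string, default E-box).
#' @param frac_fg_with_motif,frac_bg_with_motif planting fractions in `[0,1]`.
#' @param seed integer seed.
#' @return List with `fg` and `bg` (named character vectors) and `truth`
#'   (data frame: `set`, `seq_id`, `planted`, `position` (1-based start),
#'   `strand`).
#' @export
generate_promoters <- function(n_fg, n_bg, length = 1000L,
                               planted_motif = "CACGTG",
                               frac_fg_with_motif = 1,
                               frac_bg_with_motif = 0,
                               seed) {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  n_fg <- check_count(n_fg, "n_fg")
  n_bg <- check_count(n_bg, "n_bg")
  check_frac(frac_fg_with_motif, "frac_fg_with_motif")
  check_frac(frac_bg_with_motif, "frac_bg_with_motif")
  motif <- toupper(planted_motif)
  if (!grepl("^[ACGT]+$", motif)) {
    stop("`planted_motif` must be an ACGT string", call. = FALSE)
  }
  w <- nchar(motif)
  if (length < w) stop("`length` must be >= motif width", call. = FALSE)

  with_seed(seed, {
    make_set <- function(n, frac, prefix) {
      n_plant <- frac_count(frac, n)
      planted <- rep(FALSE, n)
      if (n_plant > 0) planted[sample.int(n, n_plant)] <- TRUE
      seqs <- character(n)
      pos <- rep(NA_integer_, n)
      strand <- rep(NA_character_, n)
      for (i in seq_len(n)) {
        s <- paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
                   collapse = "")
        if (planted[i]) {
          p <- sample.int(length - w + 1L, 1L)
          st <- sample(c("+", "-"), 1L)
          ins <- if (st == "+") motif else revcomp_chr(motif)
          substr(s, p, p + w - 1L) <- ins
          pos[i] <- p
          strand[i] <- st
        }
        seqs[i] <- s
      }
      names(seqs) <- sprintf("%s%03d", prefix, seq_len(n))
      list(seqs = seqs,
           truth = data.frame(set = prefix, seq_id = names(seqs),
                              planted = planted, position = pos,
                              strand = strand, stringsAsFactors = FALSE))
    }
    fg <- make_set(n_fg, frac_fg_with_motif, "fg")
    bg <- make_set(n_bg, frac_bg_with_motif, "bg")
    list(fg = fg$seqs, bg = bg$seqs, truth = rbind(fg$truth, bg$truth))
  })
}
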