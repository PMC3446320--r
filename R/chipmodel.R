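# Probe-level preprocessing and modelling: quantile normalization,
# per-transcript-cluster median-polish (RMA-style) fits, transcript-level
# expression estimates, and FIRMA splice-departure scores.

#' Quantile-normalize a probe intensity matrix
#'
#' Forces every sample (column) to share the same empirical distribution: the
#' across-sample mean of order statistics. Rank order within each sample is
#' preserved; tied values receive the mean of the reference values their ranks
#' span. Applying the transform twice equals applying it once.
#'
#' @param matrix probe x sample numeric matrix of positive intensities.
#' @return Matrix of the same shape and dimnames, quantile-normalized.
#' @examples
#' quantile_normalize(cbind(a = c(1, 3, 5), b = c(2, 4, 6)))
#' @export
quantile_normalize <- function(matrix) {
  if (!is.matrix(matrix) || !is.numeric(matrix)) {
    stop("`matrix` must be a numeric matrix", call. = FALSE)
  }
  if (ncol(matrix) < 2L) stop("need >= 2 samples", call. = FALSE)
  if (anyNA(matrix) || any(!is.finite(matrix))) {
    stop("missing or non-finite intensities are not allowed", call. = FALSE)
  }
  if (any(matrix <= 0)) stop("intensities must be positive", call. = FALSE)
  ref <- rowMeans(apply(matrix, 2L, sort))
  out <- apply(matrix, 2L, function(x) {
    res <- numeric(length(x))
    res[order(x)] <- ref
    # ties: average the reference values the tied ranks span
    stats::ave(res, x, FUN = mean)
  })
  dimnames(out) <- dimnames(matrix)
  out
}

#' Tukey median polish of a log2 probe x sample table
#'
#' Iteratively sweeps row (probe) and column (chip) medians out of the table
#' until the largest absolute adjustment drops below `tol` or `max_iter` is
#' reached, starting with a row sweep. The returned decomposition
#' `overall + probe_effects + chip_effects + residuals` reconstructs the input
#' exactly at every cell (only mass is moved between components).
#'
#' @param table numeric matrix (rows = probes, columns = samples), finite.
#' @param max_iter maximum number of full row+column sweeps.
#' @param tol convergence bound on the largest absolute adjustment.
#' @return List with `overall` (scalar m), `probe_effects` (per-row p_k),
#'   `chip_effects` (per-column c_i), `residuals` (matrix r_ki),
#'   `iterations`, and `converged`.
#' @examples
#' median_polish(rbind(c(1, 2), c(3, 4)))
#' @export
median_polish <- function(table, max_iter = 10L, tol = 1e-8) {
  if (!is.matrix(table)) table <- as.matrix(table)
  if (!is.numeric(table) || anyNA(table) || any(!is.finite(table))) {
    stop("`table` must be a finite numeric matrix", call. = FALSE)
  }
  r <- table
  overall <- 0
  row_eff <- numeric(nrow(r))
  col_eff <- numeric(ncol(r))
  iter <- 0L
  converged <- FALSE
  repeat {
    iter <- iter + 1L
    # row sweep
    rd <- apply(r, 1L, stats::median)
    row_eff <- row_eff + rd
    r <- r - rd
    cm <- stats::median(col_eff)
    overall <- overall + cm
    col_eff <- col_eff - cm
    # column sweep
    cd <- apply(r, 2L, stats::median)
    col_eff <- col_eff + cd
    r <- sweep(r, 2L, cd)
    rm_ <- stats::median(row_eff)
    overall <- overall + rm_
    row_eff <- row_eff - rm_
    delta <- max(abs(c(rd, cd)))
    if (delta < tol) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
  }
  names(row_eff) <- rownames(table)
  names(col_eff) <- colnames(table)
  dimnames(r) <- dimnames(table)
  list(overall = overall, probe_effects = row_eff, chip_effects = col_eff,
       residuals = r, iterations = iter, converged = converged)
}

#' Fit per-cluster probe models and transcript-level expression
#'
#' Runs the probe-level pipeline: optional background subtraction, optional
#' quantile normalization, log2 transform, then a median-polish fit per
#' transcript cluster with samples as the column margin and all of the
#' cluster's probes (pooled across its probesets) as the row margin. The
#' transcript-level expression estimate for sample i is
#' `theta_i = overall + chip_effect_i`.
#'
#' @param intensities probe x sample matrix (linear scale); rownames are
#'   probe ids.
#' @param layout chip-layout data frame with columns `probe_id`,
#'   `probeset_id`, `cluster_id` covering all probes in `intensities`.
#' @param background `"none"` (default) or `"modal"`: subtract each sample's
#'   modal log2 intensity on the linear scale and floor at a small positive
#'   constant. A stand-in for RMA's convolution background.
#' @param normalize logical; apply [quantile_normalize()] first.
#' @param max_iter,tol passed to [median_polish()].
#' @return List with `fits` (named list of per-cluster median-polish fits),
#'   `expression` (cluster x sample matrix of theta, log2), and `layout`.
#' @export
fit_clusters <- function(intensities, layout,
                         background = c("none", "modal"),
                         normalize = TRUE, max_iter = 10L, tol = 1e-8) {
  background <- match.arg(background)
  validate_layout(layout)
  if (is.null(rownames(intensities))) {
    stop("`intensities` must have probe ids as rownames", call. = FALSE)
  }
  unknown <- setdiff(rownames(intensities), layout$probe_id)
  if (length(unknown) > 0) {
    stop(sprintf("probes not in layout: %s",
                 paste(utils::head(unknown, 5L), collapse = ", ")),
         call. = FALSE)
  }
  x <- intensities
  if (background == "modal") {
    x <- apply(x, 2L, function(col) {
      d <- stats::density(log2(col))
      pmax(col - 2^d$x[which.max(d$y)], 2^-4)
    })
    dimnames(x) <- dimnames(intensities)
  }
  if (normalize) x <- quantile_normalize(x)
  logx <- log2(x)

  lay <- layout[match(rownames(logx), layout$probe_id), ]
  clusters <- unique(lay$cluster_id)
  fits <- vector("list", length(clusters))
  names(fits) <- clusters
  expr <- matrix(NA_real_, nrow = length(clusters), ncol = ncol(logx),
                 dimnames = list(clusters, colnames(logx)))
  for (g in seq_along(clusters)) {
    idx <- which(lay$cluster_id == clusters[g])
    fit <- median_polish(logx[idx, , drop = FALSE],
                         max_iter = max_iter, tol = tol)
    fits[[g]] <- fit
    expr[g, ] <- fit$overall + fit$chip_effects
  }
  list(fits = fits, expression = expr, layout = layout)
}

#' FIRMA splice-departure scores
#'
#' For exon-probeset j in sample i, the FIRMA score is
#' `F_ji = 2 ^ median_k(r_ki)` over the probeset's probes' median-polish
#' residuals; a score of 1 means the probeset behaves exactly as the fitted
#' gene-level model predicts (no splice departure). Even probe counts use the
#' mean-of-middle-two median. With `standardize = TRUE` residuals are divided
#' by the cluster's residual MAD first (a scale-free variant).
#'
#' @param fits result of [fit_clusters()] (or its `fits` element plus a
#'   layout).
#' @param layout chip-layout data frame; defaults to the layout stored in
#'   `fits`.
#' @param standardize divide residuals by the per-cluster MAD before taking
#'   the median (default `FALSE`).
#' @return probeset x sample matrix of FIRMA scores (linear scale).
#' @export
firma_scores <- function(fits, layout = NULL, standardize = FALSE) {
  if (!is.null(fits$fits)) {
    if (is.null(layout)) layout <- fits$layout
    fits <- fits$fits
  }
  if (is.null(layout)) stop("`layout` is required", call. = FALSE)
  validate_layout(layout)
  ps_tab <- unique(layout[, c("probeset_id", "cluster_id")])
  missing_cl <- setdiff(ps_tab$cluster_id, names(fits))
  if (length(missing_cl) > 0) {
    stop(sprintf("no fit for cluster(s): %s",
                 paste(utils::head(missing_cl, 5L), collapse = ", ")),
         call. = FALSE)
  }
  n_samples <- length(fits[[1L]]$chip_effects)
  sample_ids <- names(fits[[1L]]$chip_effects)
  scores <- matrix(NA_real_, nrow = nrow(ps_tab), ncol = n_samples,
                   dimnames = list(ps_tab$probeset_id, sample_ids))
  probes_by_ps <- split(layout$probe_id, layout$probeset_id)
  for (r in seq_len(nrow(ps_tab))) {
    fit <- fits[[ps_tab$cluster_id[r]]]
    probes <- probes_by_ps[[ps_tab$probeset_id[r]]]
    res <- fit$residuals[probes, , drop = FALSE]
    if (standardize) {
      s <- stats::mad(fit$residuals)
      if (s > 0) res <- res / s
    }
    scores[r, ] <- 2^apply(res, 2L, stats::median)
  }
  scores
}

# Layout sanity checks shared by chipmodel and io.
validate_layout <- function(layout) {
  need <- c("probe_id", "probeset_id", "cluster_id")
  if (!is.data.frame(layout) || !all(need %in% names(layout))) {
    stop("layout must be a data frame with columns probe_id, probeset_id, cluster_id",
         call. = FALSE)
  }
  if (anyDuplicated(layout$probe_id)) {
    dup <- layout$probe_id[duplicated(layout$probe_id)][1L]
    stop(sprintf("duplicate probe id '%s' in layout", dup), call. = FALSE)
  }
  ps <- unique(layout[, c("probeset_id", "cluster_id")])
  if (anyDuplicated(ps$probeset_id)) {
    dup <- ps$probeset_id[duplicated(ps$probeset_id)][1L]
    stop(sprintf("probeset '%s' maps to more than one cluster", dup),
         call. = FALSE)
  }
  invisible(layout)
}
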