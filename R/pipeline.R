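# The orchestrating pipeline: probe model -> FIRMA scores -> circadian
# screen -> SOTA clustering of candidate profiles -> phase metrics; plus the
# command-line interface over all modules.

#' Assemble and validate a pipeline configuration
#'
#' Inputs are either a directory of `layout.tsv` / `intensities.tsv` /
#' `design.tsv` (`input_dir`) or a synthetic dataset generated on the fly
#' (`synthetic = TRUE`, parameters forwarded to [simulation_config()]).
#' Defaults mirror the study design: FDR alpha 0.05, moderated statistics,
#' 4 profile clusters, CT grid 0/6/12/18.
#'
#' @param input_dir directory with input TSVs (ignored when `synthetic`).
#' @param synthetic generate the input dataset with [generate_dataset()].
#' @param synth_params list of overrides for [simulation_config()].
#' @param alpha FDR level for the screen.
#' @param moderated use empirical-Bayes moderation.
#' @param k_clusters SOTA cluster count for the candidate profiles.
#' @param seed mandatory integer seed.
#' @param out_dir output directory.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input_dir = NULL, synthetic = is.null(input_dir),
                            synth_params = list(), alpha = 0.05,
                            moderated = TRUE, k_clusters = 4L, seed,
                            out_dir = NULL) {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  if (!synthetic && is.null(input_dir)) {
    stop("either `input_dir` or `synthetic = TRUE` is required",
         call. = FALSE)
  }
  check_frac(alpha, "alpha")
  k_clusters <- check_count(k_clusters, "k_clusters")
  structure(list(input_dir = input_dir, synthetic = synthetic,
                 synth_params = synth_params, alpha = alpha,
                 moderated = moderated, k_clusters = k_clusters,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full circadian alternative-splicing discovery pipeline
#'
#' Fits the per-cluster probe models, computes FIRMA scores, screens for
#' circadian variation with the ultradian-exclusion contrast, clusters the
#' candidates' z-scored log2 score profiles with [sota_cluster()], and
#' attaches the discrete acrophase and signed-fold amplitude of each
#' candidate. When `out_dir` is set, writes `screen.tsv`, `candidates.tsv`
#' and a plain-text run log sufficient to reproduce the run.
#'
#' @param config a [pipeline_config()].
#' @return List with `screen` (full test table), `candidates` (candidate
#'   table with cluster labels and phase metrics), `scores`, `expression`,
#'   `dataset` (when synthetic) and `log` (character vector).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  log_lines <- c(sprintf("circasplice %s",
                         as.character(utils::packageVersion("circasplice"))),
                 sprintf("seed: %d", config$seed),
                 sprintf("alpha: %g  moderated: %s  k: %d", config$alpha,
                         config$moderated, config$k_clusters))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  dataset <- NULL
  if (config$synthetic) {
    sp <- config$synth_params
    sp$seed <- config$seed
    scfg <- stage("simulate", do.call(simulation_config, sp))
    dataset <- stage("simulate", generate_dataset(scfg))
    layout <- dataset$layout
    intensities <- dataset$intensities
    design <- dataset$design
    log_lines <- c(log_lines, "input: synthetic",
                   sprintf("probesets: %d  samples: %d",
                           nrow(dataset$truth), ncol(intensities)))
  } else {
    layout <- stage("read", read_layout(file.path(config$input_dir,
                                                  "layout.tsv")))
    intensities <- stage("read",
                         read_intensities(file.path(config$input_dir,
                                                    "intensities.tsv"),
                                          layout))
    design <- stage("read", read_design(file.path(config$input_dir,
                                                  "design.tsv")))
    log_lines <- c(log_lines, sprintf("input: %s", config$input_dir))
  }

  fits <- stage("fit", fit_clusters(intensities, layout))
  scores <- stage("firma", firma_scores(fits))
  screen <- stage("screen",
                  screen_circadian(scores, design, alpha = config$alpha,
                                   moderated = config$moderated))
  cand_ids <- screen$probeset_id[screen$is_candidate]
  log_lines <- c(log_lines, sprintf("candidates: %d / %d", length(cand_ids),
                                    nrow(screen)))

  candidates <- screen[screen$is_candidate, , drop = FALSE]
  if (length(cand_ids) > 0L) {
    ct <- design$circadian_time[match(colnames(scores), design$sample_id)]
    # replicate-mean log2 score profile per candidate, z-scored over times
    prof <- t(vapply(cand_ids, function(ps) {
      tapply(log2(scores[ps, ]), ct, mean)
    }, numeric(length(unique(ct)))))
    colnames(prof) <- sort(unique(ct))
    psd <- apply(prof, 1L, stats::sd)
    z <- prof
    z[psd > 0, ] <- (prof[psd > 0, , drop = FALSE] -
                       rowMeans(prof[psd > 0, , drop = FALSE])) /
      psd[psd > 0]
    k <- min(config$k_clusters, nrow(z))
    cl <- if (nrow(z) >= 2L && k >= 2L) {
      stage("cluster", sota_cluster(z, k))$assignment
    } else {
      stats::setNames(rep(1L, nrow(z)), rownames(z))
    }
    phase <- t(vapply(cand_ids, function(ps) {
      pr <- temporal_profile(scores[ps, ], ct)
      pm <- acrophase_amplitude(fold_changes(pr))
      c(pm$acrophase, pm$amplitude)
    }, numeric(2)))
    candidates$sota_cluster <- unname(cl[candidates$probeset_id])
    candidates$acrophase <- phase[, 1L]
    candidates$amplitude <- phase[, 2L]
  } else {
    candidates$sota_cluster <- integer(0)
    candidates$acrophase <- numeric(0)
    candidates$amplitude <- numeric(0)
  }

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    # hash the scientific parameters only, so identical analyses written to
    # different directories stay byte-identical
    cfg_hash <- config[setdiff(names(config), "out_dir")]
    write_tsv_stamped(screen, file.path(config$out_dir, "screen.tsv"),
                      config$seed, cfg_hash)
    write_tsv_stamped(candidates, file.path(config$out_dir,
                                            "candidates.tsv"),
                      config$seed, cfg_hash)
    writeLines(log_lines, file.path(config$out_dir, "run_log.txt"))
  }
  list(screen = screen, candidates = candidates, scores = scores,
       expression = fits$expression, dataset = dataset, log = log_lines)
}

# ---- command-line interface ------------------------------------------------

parse_cli_args <- function(args) {
  flags <- list()
  pos <- character(0)
  i <- 1L
  while (i <= length(args)) {
    a <- args[[i]]
    if (startsWith(a, "--")) {
      key <- sub("^--", "", a)
      if (i + 1L <= length(args) && !startsWith(args[[i + 1L]], "--")) {
        flags[[key]] <- args[[i + 1L]]
        i <- i + 2L
      } else {
        flags[[key]] <- TRUE
        i <- i + 1L
      }
    } else {
      pos <- c(pos, a)
      i <- i + 1L
    }
  }
  list(flags = flags, positional = pos)
}

cli_num <- function(flags, key, default = NULL) {
  if (is.null(flags[[key]])) return(default)
  v <- suppressWarnings(as.numeric(flags[[key]]))
  if (is.na(v)) stop(sprintf("--%s: expected a number, got '%s'", key,
                             flags[[key]]), call. = FALSE)
  v
}

#' Command-line entry point
#'
#' Subcommands: `simulate`, `fit`, `screen`, `cluster`, `phase`, `compare`,
#' `validate`, `scan`, `nmd`, `run`. Invoke via the `circasplice` script in
#' `inst/cli/`, or directly:
#' `Rscript -e 'circasplice::circasplice_cli()' run --seed 1 --out out/`.
#' Errors abort with a message naming the offending parameter or stage; the
#' wrapper script converts them to a nonzero exit status.
#'
#' @param args character vector of arguments (default: the command line).
#' @return Invisibly, the main result of the subcommand.
#' @export
circasplice_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L) {
    stop("usage: circasplice <simulate|fit|screen|cluster|phase|compare|validate|scan|nmd|run> [--flags]",
         call. = FALSE)
  }
  cmd <- args[[1L]]
  pa <- parse_cli_args(args[-1L])
  fl <- pa$flags
  need <- function(key) {
    if (is.null(fl[[key]])) stop(sprintf("--%s is required for '%s'",
                                         key, cmd), call. = FALSE)
    fl[[key]]
  }
  out <- switch(
    cmd,
    simulate = {
      cfg <- simulation_config(seed = as.integer(need("seed")))
      ds <- generate_dataset(cfg)
      write_dataset(ds, need("out"))
      message(sprintf("wrote synthetic dataset to %s", fl$out))
      invisible(ds)
    },
    fit = {
      layout <- read_layout(file.path(need("in"), "layout.tsv"))
      ints <- read_intensities(file.path(fl$`in`, "intensities.tsv"), layout)
      fits <- fit_clusters(ints, layout)
      scores <- firma_scores(fits)
      df <- data.frame(probeset_id = rownames(scores), scores,
                       check.names = FALSE)
      write_tsv_stamped(df, need("out"))
      invisible(scores)
    },
    screen = {
      sc <- read_tsv_checked(need("scores"), "probeset_id")
      m <- as.matrix(sc[, -1, drop = FALSE]); rownames(m) <- sc$probeset_id
      design <- read_design(need("design"))
      res <- screen_circadian(m, design,
                              alpha = cli_num(fl, "alpha", 0.05),
                              moderated = !isTRUE(fl$plain),
                              anti_universe = fl$`anti-universe` %||% "all")
      write_tsv_stamped(res, need("out"))
      invisible(res)
    },
    cluster = {
      sc <- read_tsv_checked(need("profiles"), "profile_id")
      m <- as.matrix(sc[, -1, drop = FALSE]); rownames(m) <- sc$profile_id
      res <- sota_cluster(m, as.integer(cli_num(fl, "k", 4)))
      df <- data.frame(profile_id = names(res$assignment),
                       cluster = unname(res$assignment))
      write_tsv_stamped(df, need("out"))
      invisible(res)
    },
    phase = {
      sc <- read_tsv_checked(need("profiles"), "profile_id")
      m <- as.matrix(sc[, -1, drop = FALSE])
      times <- as.numeric(colnames(sc)[-1])
      rows <- lapply(seq_len(nrow(m)), function(i) {
        pm <- acrophase_amplitude(
          fold_changes(temporal_profile(m[i, ], times)))
        data.frame(profile_id = sc$profile_id[i],
                   acrophase = pm$acrophase, amplitude = pm$amplitude)
      })
      df <- do.call(rbind, rows)
      write_tsv_stamped(df, need("out"))
      invisible(df)
    },
    compare = {
      tab <- read_tsv_checked(need("in"),
                              c("value", "factor_A", "factor_B"))
      fit <- twoway_anova(tab$value, tab$factor_A, tab$factor_B)
      message(sprintf("p(A) = %.4g  p(B) = %.4g  p(AxB) = %.4g",
                      fit$p_main_A, fit$p_main_B, fit$p_interaction))
      invisible(fit)
    },
    validate = {
      tab <- read_tsv_checked(need("in"),
                              c("sample_id", "target", "mode", "value"))
      ref <- strsplit(need("reference"), ",", fixed = TRUE)[[1]]
      res <- relative_expression(tab, need("target"), need("normalizer"),
                                 ref)
      write_tsv_stamped(res, need("out"))
      invisible(res)
    },
    scan = {
      seqs <- read_fasta(need("fasta"))
      pssms <- if (is.null(fl$pssm)) clock_pssms() else
        read_pssm_file(fl$pssm)
      hits <- scan_sequences(seqs, pssms,
                             threshold = cli_num(fl, "threshold", 8))
      write_tsv_stamped(hits, need("out"))
      invisible(hits)
    },
    nmd = {
      models <- read_transcript_models(need("in"))
      rep_ <- batch_frame_report(models)
      write_tsv_stamped(rep_$table, need("out"))
      message(sprintf("%d of %d cassette exons are frame-shifting",
                      rep_$n_frame_shifting, nrow(rep_$table)))
      invisible(rep_)
    },
    run = {
      cfg <- pipeline_config(input_dir = fl$`in`,
                             alpha = cli_num(fl, "alpha", 0.05),
                             moderated = !isTRUE(fl$plain),
                             k_clusters = as.integer(cli_num(fl, "k", 4)),
                             seed = as.integer(need("seed")),
                             out_dir = need("out"))
      invisible(run_pipeline(cfg))
    },
    stop(sprintf("unknown subcommand '%s'", cmd), call. = FALSE)
  )
  invisible(out)
}
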