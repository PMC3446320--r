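# File formats: TSV tables (layout, intensities, design, scores, truth),
# FASTA sequence sets, the PSSM text format, and a flat key: value config.
# All tabular outputs are UTF-8 TSV with '#' comment headers.

read_tsv_checked <- function(path, required_cols) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  if (file.size(path) == 0L) stop(sprintf("empty file: %s", path),
                                  call. = FALSE)
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                          check.names = FALSE)
  if (nrow(df) == 0L) stop(sprintf("no data rows in %s", path),
                           call. = FALSE)
  missing_cols <- setdiff(required_cols, names(df))
  if (length(missing_cols) > 0L) {
    stop(sprintf("%s: missing column(s) %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  df
}

# header comment stamped on every output table
tsv_header <- function(seed = NULL, config = NULL) {
  # no timestamp: identical runs must produce byte-identical tables
  lines <- sprintf("# circasplice %s",
                   as.character(utils::packageVersion("circasplice")))
  if (!is.null(seed)) lines <- c(lines, sprintf("# seed %d", seed))
  if (!is.null(config)) {
    lines <- c(lines, sprintf("# config_hash %s",
                              config_hash(paste(deparse(config),
                                                collapse = ""))))
  }
  lines
}

write_tsv_stamped <- function(df, path, seed = NULL, config = NULL) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(tsv_header(seed, config), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a chip-layout table
#'
#' TSV with columns `probe_id`, `probeset_id`, `cluster_id`; validated for
#' unique probes and single-cluster probesets.
#'
#' @param path TSV path.
#' @return Validated layout data frame.
#' @export
read_layout <- function(path) {
  validate_layout(read_tsv_checked(path,
                                   c("probe_id", "probeset_id",
                                     "cluster_id")))
}

#' Read a probe-intensity matrix
#'
#' TSV with a `probe_id` column and one numeric column per sample; if a
#' layout is supplied, every probe must be known to it.
#'
#' @param path TSV path.
#' @param layout optional layout for probe validation.
#' @return Numeric matrix with probe rownames and sample colnames.
#' @export
read_intensities <- function(path, layout = NULL) {
  df <- read_tsv_checked(path, "probe_id")
  if (anyDuplicated(df$probe_id)) {
    stop(sprintf("duplicate probe id '%s' in %s",
                 df$probe_id[duplicated(df$probe_id)][1L], path),
         call. = FALSE)
  }
  if (!is.null(layout)) {
    unknown <- setdiff(df$probe_id, layout$probe_id)
    if (length(unknown) > 0L) {
      stop(sprintf("intensity row references unknown probe '%s'",
                   unknown[1L]), call. = FALSE)
    }
  }
  m <- as.matrix(df[, setdiff(names(df), "probe_id"), drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric intensity values", call. = FALSE)
  if (anyDuplicated(colnames(m))) stop("duplicate sample ids",
                                       call. = FALSE)
  rownames(m) <- df$probe_id
  m
}

#' Read a sample-design table
#'
#' TSV with columns `sample_id`, `circadian_time`, `tissue`, `feeding`,
#' `genotype`, `replicate`.
#'
#' @param path TSV path.
#' @return Design data frame.
#' @export
read_design <- function(path) {
  df <- read_tsv_checked(path, c("sample_id", "circadian_time", "tissue",
                                 "feeding", "genotype", "replicate"))
  if (anyDuplicated(df$sample_id)) stop("duplicate sample ids in design",
                                        call. = FALSE)
  key <- do.call(paste, c(df[c("circadian_time", "tissue", "feeding",
                               "genotype", "replicate")], sep = "\r"))
  if (anyDuplicated(key)) {
    stop("design rows are not jointly unique over (time, tissue, feeding, genotype, replicate)",
         call. = FALSE)
  }
  df
}

#' Write a synthetic dataset to a directory of TSV files
#'
#' Writes `layout.tsv`, `intensities.tsv`, `design.tsv` and `truth.tsv`.
#'
#' @param dataset a `synthetic_dataset`.
#' @param dir output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seed <- dataset$config$seed
  write_tsv_stamped(dataset$layout, file.path(dir, "layout.tsv"), seed,
                    dataset$config)
  idf <- data.frame(probe_id = rownames(dataset$intensities),
                    dataset$intensities, check.names = FALSE)
  write_tsv_stamped(idf, file.path(dir, "intensities.tsv"), seed,
                    dataset$config)
  write_tsv_stamped(dataset$design, file.path(dir, "design.tsv"), seed,
                    dataset$config)
  write_tsv_stamped(dataset$truth, file.path(dir, "truth.tsv"), seed,
                    dataset$config)
  invisible(dir)
}

#' Read sequences from a FASTA file
#'
#' Backed by `Biostrings::readDNAStringSet`. Ids must be unique; lower-case
#' input is uppercased with a message.
#'
#' @param path FASTA path.
#' @return Named character vector of upper-case sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  ss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate FASTA id '%s'", ids[duplicated(ids)][1L]),
         call. = FALSE)
  }
  seqs <- as.character(ss)
  if (any(grepl("[a-z]", seqs))) {
    message("lower-case bases uppercased on read")
    seqs <- toupper(seqs)
  }
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    stop(sprintf("non-ACGTN characters in sequence '%s'", ids[bad][1L]),
         call. = FALSE)
  }
  stats::setNames(seqs, ids)
}

#' Write sequences to a FASTA file (60-column wrap)
#'
#' @param seqs named character vector.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (is.null(names(seqs)) || anyDuplicated(names(seqs))) {
    stop("sequences must have unique names", call. = FALSE)
  }
  ss <- Biostrings::DNAStringSet(unlist(seqs))
  names(ss) <- names(seqs)
  Biostrings::writeXStringSet(ss, path, width = 60L)
  invisible(path)
}

#' Read PSSMs from the text exchange format
#'
#' Format: a `>name` header line, then one row per motif position with 4
#' whitespace-separated columns (A C G T counts or probabilities); several
#' motifs per file allowed.
#'
#' @param path file path.
#' @param pseudocount passed to [build_pssm()].
#' @return Named list of `pssm` objects.
#' @export
read_pssm_file <- function(path, pseudocount = 0.01) {
  lines <- trimws(readLines(path))
  lines <- lines[lines != "" & !startsWith(lines, "#")]
  if (length(lines) == 0L || !startsWith(lines[1L], ">")) {
    stop("PSSM file must start with a '>name' header", call. = FALSE)
  }
  idx <- cumsum(startsWith(lines, ">"))
  out <- list()
  for (block in split(lines, idx)) {
    name <- sub("^>\\s*", "", block[1L])
    rows <- lapply(block[-1L], function(l) {
      v <- as.numeric(strsplit(l, "\\s+")[[1]])
      if (length(v) != 4L || anyNA(v)) {
        stop(sprintf("motif '%s': each row needs 4 numeric columns (A C G T)",
                     name), call. = FALSE)
      }
      v
    })
    if (length(rows) == 0L) stop(sprintf("motif '%s' has no rows", name),
                                 call. = FALSE)
    counts <- t(do.call(rbind, rows))
    rownames(counts) <- BASES
    out[[name]] <- build_pssm(counts, pseudocount = pseudocount, name = name)
  }
  out
}

#' Read a flat key: value configuration file
#'
#' A minimal YAML-like subset: one `key: value` pair per line, `#` comments
#' and blank lines ignored; values parsed as numbers when possible, with
#' comma-separated numeric lists supported. (A full YAML parser is
#' deliberately not a dependency.)
#'
#' @param path config path.
#' @return Named list.
#' @export
read_config <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[lines != "" & !startsWith(lines, "#")]
  out <- list()
  for (l in lines) {
    m <- regmatches(l, regexec("^([A-Za-z0-9_.]+)\\s*:\\s*(.*)$", l))[[1]]
    if (length(m) != 3L) {
      stop(sprintf("bad config line: '%s'", l), call. = FALSE)
    }
    val <- m[3L]
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    nums <- suppressWarnings(as.numeric(parts))
    parsed <- if (!anyNA(nums)) {
      nums
    } else if (val %in% c("true", "TRUE", "yes")) {
      TRUE
    } else if (val %in% c("false", "FALSE", "no")) {
      FALSE
    } else {
      val
    }
    out[[m[2L]]] <- parsed
  }
  out
}
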