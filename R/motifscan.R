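# Clock transcription-factor binding-site prediction: PSSM construction,
# promoter extraction, log-odds scanning of both strands, per-gene presence
# calls, and Fisher enrichment between rhythmic and control gene sets.

BASES <- c("A", "C", "G", "T")

#' Build a position-specific scoring matrix
#'
#' Adds a pseudocount to a 4 x width count (or probability) table and
#' renormalizes each position to a probability vector over A/C/G/T.
#'
#' @param counts numeric matrix with 4 rows (A, C, G, T order; rownames are
#'   honoured if present) and one column per motif position; non-negative
#'   with at least one positive entry per position.
#' @param pseudocount added to every cell before renormalization.
#' @param name motif name.
#' @return A `pssm` object: list with `name`, `width` and `prob` (4 x width
#'   column-stochastic matrix).
#' @export
build_pssm <- function(counts, pseudocount = 0.01, name = "motif") {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4L) stop("counts must have 4 rows (A, C, G, T)",
                               call. = FALSE)
  if (!is.null(rownames(counts))) {
    if (!setequal(rownames(counts), BASES)) {
      stop("rownames must be A, C, G, T", call. = FALSE)
    }
    counts <- counts[BASES, , drop = FALSE]
  } else {
    rownames(counts) <- BASES
  }
  if (ncol(counts) < 1L) stop("zero-width motif", call. = FALSE)
  if (any(counts < 0)) stop("negative entries", call. = FALSE)
  if (any(colSums(counts) == 0)) {
    stop("all-zero position in the count table", call. = FALSE)
  }
  if (pseudocount == 0 && any(counts == 0)) {
    stop("zero entries require a positive pseudocount", call. = FALSE)
  }
  p <- counts + pseudocount
  p <- sweep(p, 2L, colSums(p), "/")
  structure(list(name = name, width = ncol(p), prob = p), class = "pssm")
}

# PSSM from a consensus string with IUPAC two-fold codes; stand-in matrices
# for the clock elements when no curated PSSM file is supplied.
pssm_from_consensus <- function(consensus, name = consensus,
                                match_prob = 0.85, pseudocount = 0) {
  iupac <- list(A = "A", C = "C", G = "G", T = "T",
                R = c("A", "G"), Y = c("C", "T"), W = c("A", "T"),
                S = c("C", "G"), K = c("G", "T"), M = c("A", "C"),
                N = BASES)
  chars <- strsplit(toupper(consensus), "", fixed = TRUE)[[1]]
  cols <- vapply(chars, function(ch) {
    allowed <- iupac[[ch]]
    if (is.null(allowed)) stop(sprintf("bad consensus symbol '%s'", ch),
                               call. = FALSE)
    p <- stats::setNames(rep((1 - match_prob) / (4 - length(allowed)), 4L),
                         BASES)
    if (length(allowed) == 4L) {
      p[] <- 0.25
    } else {
      p[allowed] <- match_prob / length(allowed)
    }
    p
  }, numeric(4))
  build_pssm(cols, pseudocount = pseudocount, name = name)
}

#' Default clock transcription-factor PSSMs (synthetic stand-ins)
#'
#' Consensus-derived matrices for the four canonical clock elements: E-box
#' (CACGTG; CLOCK/BMAL1), E'-box (CACGTT), D-box (TTATGYAA; DBP/E4BP4) and
#' RRE (WAWNTRGGTCA; REV-ERB/ROR). These are synthetic stand-ins built from
#' published consensus sequences, not curated alignment-derived matrices;
#' supply your own via [read_pssm_file()] for real analyses.
#'
#' @return Named list of `pssm` objects.
#' @export
clock_pssms <- function() {
  list(
    Ebox = pssm_from_consensus("CACGTG", "Ebox"),
    EpBox = pssm_from_consensus("CACGTT", "EpBox"),
    Dbox = pssm_from_consensus("TTATGYAA", "Dbox"),
    RRE = pssm_from_consensus("WAWNTRGGTCA", "RRE")
  )
}

#' Extract a promoter region: 5 kb upstream of the TSS to the first intron end
#'
#' Given a transcript's genomic exon coordinates (in transcript order) on a
#' chromosome sequence, returns the sense-strand sequence from
#' `upstream` bases before the transcription start site to the last base of
#' the first intron. Minus-strand transcripts are reverse-complemented.
#' Regions are truncated at chromosome edges with a warning.
#'
#' @param chrom_seq chromosome sequence (character or `Biostrings::DNAString`).
#' @param exon_starts,exon_ends genomic 1-based inclusive exon coordinates in
#'   transcript order (>= 2 exons).
#' @param strand `"+"` or `"-"`.
#' @param upstream bases upstream of the TSS (default 5000).
#' @return List with `sequence`, `start`, `end` (genomic 1-based inclusive)
#'   and `strand`.
#' @export
extract_promoter <- function(chrom_seq, exon_starts, exon_ends, strand = "+",
                             upstream = 5000L) {
  if (length(exon_starts) < 2L || length(exon_starts) != length(exon_ends)) {
    stop("need >= 2 exons with matching starts/ends (no first intron otherwise)",
         call. = FALSE)
  }
  chrom <- toupper(as.character(chrom_seq))
  L <- nchar(chrom)
  if (strand == "+") {
    gstart <- exon_starts[1L] - upstream
    gend <- exon_starts[2L] - 1L          # last base of intron 1
  } else if (strand == "-") {
    gstart <- exon_ends[2L] + 1L          # last base of intron 1, sense-wise
    gend <- exon_ends[1L] + upstream
  } else {
    stop("strand must be '+' or '-'", call. = FALSE)
  }
  if (gend < gstart) stop("degenerate promoter region", call. = FALSE)
  if (gend < 1L || gstart > L) {
    stop("region entirely off the chromosome", call. = FALSE)
  }
  if (gstart < 1L || gend > L) {
    warning("promoter region truncated at chromosome edge")
    gstart <- max(1L, gstart)
    gend <- min(L, gend)
  }
  s <- substr(chrom, gstart, gend)
  if (strand == "-") s <- revcomp_chr(s)
  list(sequence = s, start = gstart, end = gend, strand = strand)
}

# log2-odds score matrix for a pssm against a background vector
pssm_log_odds <- function(pssm, background) {
  log2(pssm$prob / background)
}

#' Scan a sequence with a PSSM on both strands
#'
#' Scores every window of motif width on both strands with the log-likelihood
#' ratio (bits) `sum log2(p_motif(base) / p_background(base))` and reports
#' windows scoring at or above the threshold. Windows containing N are
#' skipped. Positions are 1-based starts on the given (forward) sequence for
#' both strands.
#'
#' @param seq sequence (character over A/C/G/T/N; lower case accepted).
#' @param pssm a `pssm` object.
#' @param background base frequencies over A/C/G/T (positive, summing to 1);
#'   default uniform.
#' @param threshold minimum score in bits (default 8).
#' @param seq_id id recorded in the hit table.
#' @return Data frame: `seq_id`, `motif`, `position`, `strand`, `score`,
#'   sorted by ascending position.
#' @export
scan_sequence <- function(seq, pssm, background = rep(0.25, 4),
                          threshold = 8, seq_id = "seq") {
  stopifnot(inherits(pssm, "pssm"))
  if (any(background <= 0) || abs(sum(background) - 1) > 1e-9) {
    stop("background must be positive and sum to 1", call. = FALSE)
  }
  if (is.na(threshold)) stop("threshold must be a number", call. = FALSE)
  s <- toupper(as.character(seq))
  w <- pssm$width
  n <- nchar(s)
  empty <- data.frame(seq_id = character(0), motif = character(0),
                      position = integer(0), strand = character(0),
                      score = numeric(0), stringsAsFactors = FALSE)
  if (n < w) return(empty)
  background <- stats::setNames(as.numeric(background), BASES)
  lo_fwd <- pssm_log_odds(pssm, background)
  # the reverse strand of window [i, i+w-1] reads the reverse complement;
  # scoring it (motif and background both applied to the complemented read)
  # equals indexing the reverse-complemented log-odds matrix with the
  # forward-strand bases
  lo_rev <- lo_fwd[4:1, w:1, drop = FALSE]
  rownames(lo_rev) <- BASES
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  code <- match(chars, BASES)               # NA for N and anything else
  nw <- n - w + 1L
  hits <- list()
  for (i in seq_len(nw)) {
    idx <- code[i:(i + w - 1L)]
    if (anyNA(idx)) next
    flat <- idx + 4L * (seq_len(w) - 1L)
    sc_f <- sum(lo_fwd[flat])
    sc_r <- sum(lo_rev[flat])
    if (sc_f >= threshold) {
      hits[[length(hits) + 1L]] <- list(i, "+", sc_f)
    }
    if (sc_r >= threshold) {
      hits[[length(hits) + 1L]] <- list(i, "-", sc_r)
    }
  }
  if (length(hits) == 0L) return(empty)
  data.frame(
    seq_id = seq_id, motif = pssm$name,
    position = vapply(hits, function(h) h[[1L]], integer(1)),
    strand = vapply(hits, function(h) h[[2L]], character(1)),
    score = vapply(hits, function(h) h[[3L]], numeric(1)),
    stringsAsFactors = FALSE
  )
}

#' Scan a set of sequences with a set of PSSMs
#'
#' @param seqs named character vector of sequences.
#' @param pssms list of `pssm` objects.
#' @inheritParams scan_sequence
#' @return Combined hit data frame (see [scan_sequence()]).
#' @export
scan_sequences <- function(seqs, pssms, background = rep(0.25, 4),
                           threshold = 8) {
  if (inherits(pssms, "pssm")) pssms <- list(pssms)
  out <- list()
  for (id in names(seqs)) {
    for (p in pssms) {
      out[[length(out) + 1L]] <-
        scan_sequence(seqs[[id]], p, background, threshold, seq_id = id)
    }
  }
  do.call(rbind, out)
}

#' Per-gene motif presence from sequence-level hits
#'
#' A gene is flagged when any of its (deduplicated) sequences carries at
#' least one hit for any motif in the set.
#'
#' @param hits hit data frame from [scan_sequences()].
#' @param seq_to_gene named character vector mapping `seq_id` to gene id,
#'   covering every scanned sequence.
#' @param genes optional gene universe; defaults to the genes in the map.
#' @return Named logical vector over `genes`.
#' @export
gene_motif_presence <- function(hits, seq_to_gene, genes = NULL) {
  if (is.null(genes)) genes <- unique(unname(seq_to_gene))
  flags <- stats::setNames(rep(FALSE, length(genes)), genes)
  if (nrow(hits) > 0L) {
    unmapped <- setdiff(unique(hits$seq_id), names(seq_to_gene))
    if (length(unmapped) > 0L) {
      stop(sprintf("sequence(s) not mapped to a gene: %s",
                   paste(utils::head(unmapped, 5L), collapse = ", ")),
           call. = FALSE)
    }
    hit_genes <- unique(unname(seq_to_gene[unique(hits$seq_id)]))
    flags[intersect(hit_genes, genes)] <- TRUE
  }
  flags
}

#' Drop duplicate sequences within a promoter set
#'
#' Keeps the first of any group of identical sequences (e.g. two mRNAs of a
#' gene sharing a promoter region), preserving names.
#'
#' @param seqs named character vector.
#' @return The deduplicated vector.
#' @export
dedup_sequences <- function(seqs) {
  seqs[!duplicated(unname(seqs))]
}

#' Seeded sampling of a control gene set without replacement
#'
#' @param pool character vector of candidate genes.
#' @param n subset size (<= pool size).
#' @param seed integer seed.
#' @return Character vector of `n` genes; deterministic per seed.
#' @export
sample_control_set <- function(pool, n, seed) {
  n <- check_count(n, "n")
  if (n > length(pool)) stop("n exceeds pool size", call. = FALSE)
  with_seed(seed, pool[sample.int(length(pool), n)])
}

#' One-tailed Fisher exact enrichment test
#'
#' Builds the 2x2 table (rhythmic/control x with/without motif) and tests for
#' over-representation of the motif in the rhythmic set with the
#' hypergeometric upper tail (Fisher's exact test, one tail). The sample odds
#' ratio is reported as is (infinite or zero with empty cells, no continuity
#' adjustment).
#'
#' @param flags_rhythmic,flags_control logical vectors of per-gene motif
#'   presence in the two sets (both non-empty).
#' @return List with `table` (2x2 matrix), `odds_ratio` and `p` (one-tailed).
#' @export
enrichment_test <- function(flags_rhythmic, flags_control) {
  if (length(flags_rhythmic) == 0L || length(flags_control) == 0L) {
    stop("both gene sets must be non-empty", call. = FALSE)
  }
  a <- sum(flags_rhythmic)                 # rhythmic with motif
  b <- sum(!flags_rhythmic)
  c <- sum(flags_control)
  d <- sum(!flags_control)
  tab <- matrix(c(a, b, c, d), nrow = 2L,
                dimnames = list(c("with_motif", "without_motif"),
                                c("rhythmic", "control")))
  # hypergeometric upper tail: P(X >= a) with white = a + c, black = b + d,
  # drawn = a + b
  p <- stats::phyper(a - 1L, a + c, b + d, a + b, lower.tail = FALSE)
  or <- if (b * c == 0) {
    if (a * d == 0) NaN else Inf
  } else {
    (a * d) / (b * c)
  }
  list(table = tab, odds_ratio = or, p = p)
}
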