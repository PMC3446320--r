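# Reading-frame consequences of skipping a cassette exon: frame preservation,
# new terminal sequence, or candidacy for nonsense-mediated decay (NMD).

#' Build a transcript model for cassette-exon analysis
#'
#' @param transcript_id id string.
#' @param exon_lengths ordered exon lengths in nucleotides (> 0).
#' @param cassette_index 1-based index of the cassette exon; must be internal
#'   (not the first or last exon).
#' @param cds_start,cds_end CDS bounds in transcript coordinates (1-based
#'   inclusive); the CDS length must be a multiple of 3.
#' @return A `transcript_model` list.
#' @export
transcript_model <- function(transcript_id, exon_lengths, cassette_index,
                             cds_start, cds_end) {
  exon_lengths <- as.integer(exon_lengths)
  if (any(exon_lengths <= 0)) stop("exon lengths must be > 0", call. = FALSE)
  ne <- length(exon_lengths)
  cassette_index <- check_count(cassette_index, "cassette_index")
  if (cassette_index > ne) stop("cassette index out of range", call. = FALSE)
  tx_len <- sum(exon_lengths)
  if (cds_start >= cds_end || cds_start < 1L || cds_end > tx_len) {
    stop("need 1 <= cds_start < cds_end <= transcript length", call. = FALSE)
  }
  if ((cds_end - cds_start + 1L) %% 3L != 0L) {
    stop("CDS length must be a multiple of 3", call. = FALSE)
  }
  structure(list(transcript_id = transcript_id,
                 exon_lengths = exon_lengths,
                 cassette_index = as.integer(cassette_index),
                 cds_start = as.integer(cds_start),
                 cds_end = as.integer(cds_end)),
            class = "transcript_model")
}

#' Classify the consequence of skipping a cassette exon
#'
#' Structural rules, applied in order to the cassette exon:
#' 1. no overlap with the CDS: `noncoding_region` (UTR-only exon);
#' 2. length divisible by 3: `frame_preserving`;
#' otherwise the skip shifts the reading frame, and
#' 3. the exon contains the CDS start: `new_n_terminus`;
#' 4. the exon is the penultimate exon of the transcript:
#'    `nmd_insensitive_penultimate` — any premature termination codon created
#'    downstream of the last exon-exon junction escapes NMD recognition;
#' 5. the exon is the last CDS-containing exon before the stop-containing
#'    exon: `new_c_terminus`;
#' 6. otherwise: `nmd_candidate`.
#'
#' An exon straddling both the CDS start and the CDS end is rejected as
#' malformed, as is a first- or last-exon cassette (not an internal exon).
#'
#' @param model a [transcript_model()].
#' @return List with `transcript_id`, `frame_shifting` (flag; meaningful for
#'   CDS-overlapping exons) and `category`.
#' @export
classify_skip <- function(model) {
  stopifnot(inherits(model, "transcript_model"))
  ne <- length(model$exon_lengths)
  ci <- model$cassette_index
  if (ci == 1L || ci == ne) {
    stop("cassette exon must be internal (not first or last)", call. = FALSE)
  }
  ends <- cumsum(model$exon_lengths)
  starts <- ends - model$exon_lengths + 1L
  ex_start <- starts[ci]; ex_end <- ends[ci]
  len <- model$exon_lengths[ci]
  has_cds_start <- ex_start <= model$cds_start && model$cds_start <= ex_end
  has_cds_end <- ex_start <= model$cds_end && model$cds_end <= ex_end
  if (has_cds_start && has_cds_end) {
    stop("cassette exon contains the entire CDS: malformed model",
         call. = FALSE)
  }
  overlaps_cds <- ex_start <= model$cds_end && ex_end >= model$cds_start
  if (!overlaps_cds) {
    cat_out <- "noncoding_region"
    frame_shifting <- FALSE
  } else if (len %% 3L == 0L) {
    cat_out <- "frame_preserving"
    frame_shifting <- FALSE
  } else {
    frame_shifting <- TRUE
    stop_exon <- which(starts <= model$cds_end & model$cds_end <= ends)
    if (has_cds_start) {
      cat_out <- "new_n_terminus"
    } else if (ci == ne - 1L) {
      cat_out <- "nmd_insensitive_penultimate"
    } else if (ci == stop_exon - 1L) {
      cat_out <- "new_c_terminus"
    } else {
      cat_out <- "nmd_candidate"
    }
  }
  list(transcript_id = model$transcript_id, frame_shifting = frame_shifting,
       category = cat_out)
}

#' Batch reading-frame report for a set of cassette exons
#'
#' Classifies each model with [classify_skip()], continuing past per-record
#' errors, and summarizes counts by category and by the frame-shifting flag.
#'
#' @param models list of [transcript_model()] objects (>= 1).
#' @return List with `table` (per-transcript data frame: `transcript_id`,
#'   `exon_length`, `frame_shifting`, `category`, `error`),
#'   `category_counts` and `n_frame_shifting`.
#' @export
batch_frame_report <- function(models) {
  if (length(models) == 0L) stop("need >= 1 model", call. = FALSE)
  rows <- lapply(models, function(m) {
    res <- tryCatch(classify_skip(m), error = function(e) e)
    if (inherits(res, "error")) {
      data.frame(transcript_id = m$transcript_id,
                 exon_length = m$exon_lengths[m$cassette_index],
                 frame_shifting = NA, category = NA_character_,
                 error = conditionMessage(res), stringsAsFactors = FALSE)
    } else {
      data.frame(transcript_id = res$transcript_id,
                 exon_length = m$exon_lengths[m$cassette_index],
                 frame_shifting = res$frame_shifting,
                 category = res$category, error = NA_character_,
                 stringsAsFactors = FALSE)
    }
  })
  tab <- do.call(rbind, rows)
  ok <- !is.na(tab$category)
  list(table = tab,
       category_counts = table(tab$category[ok]),
       n_frame_shifting = sum(tab$frame_shifting[ok]))
}

#' Read transcript models from a TSV file
#'
#' Expects columns `transcript_id`, `exon_index`, `exon_length`,
#' `is_cassette`, `cds_start`, `cds_end`, one row per exon, exons ordered by
#' `exon_index` within a transcript, exactly one cassette exon per
#' transcript.
#'
#' @param path TSV path (`#` comments allowed).
#' @return List of [transcript_model()] objects.
#' @export
read_transcript_models <- function(path) {
  df <- read_tsv_checked(path, c("transcript_id", "exon_index", "exon_length",
                                 "is_cassette", "cds_start", "cds_end"))
  lapply(split(df, df$transcript_id), function(d) {
    d <- d[order(d$exon_index), ]
    cas <- which(as.logical(d$is_cassette))
    if (length(cas) != 1L) {
      stop(sprintf("transcript '%s' must flag exactly one cassette exon",
                   d$transcript_id[1L]), call. = FALSE)
    }
    transcript_model(d$transcript_id[1L], d$exon_length, cas,
                     d$cds_start[1L], d$cds_end[1L])
  })
}
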