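# QPCR / RT-PCR validation arithmetic: efficiency-corrected relative
# quantification, normalization to a reference gene, the exon/transcript
# splicing index, and gel-band percent inclusion.

#' Relative expression from Ct or relative-concentration tables
#'
#' Converts each measurement to a relative quantity (`efficiency^-Ct` for Ct
#' mode, the value itself for relative-concentration mode), normalizes the
#' target quantity to the normalizer quantity within each sample, and
#' expresses the result as fold change versus the geometric mean of a
#' reference sample group (e.g. CT0).
#'
#' @param table data frame with columns `sample_id`, `target`, `mode`
#'   (`"Ct"` or `"rel"`), `value`, and optionally `efficiency` (default 2).
#' @param target target assay label.
#' @param normalizer normalizer assay label (e.g. `"Actb"`).
#' @param reference_group character vector of sample ids forming the
#'   reference (fold = 1) group.
#' @return Data frame: `sample_id`, `target`, `normalized`, `fold`.
#' @export
relative_expression <- function(table, target, normalizer, reference_group) {
  need <- c("sample_id", "target", "mode", "value")
  if (!all(need %in% names(table))) {
    stop("table must have columns sample_id, target, mode, value",
         call. = FALSE)
  }
  if (length(reference_group) == 0L) {
    stop("reference group is empty", call. = FALSE)
  }
  quantify <- function(rows) {
    eff <- if ("efficiency" %in% names(rows)) rows$efficiency else 2
    if (any(eff <= 1)) stop("efficiency must be > 1", call. = FALSE)
    q <- ifelse(rows$mode == "Ct", eff^(-rows$value), rows$value)
    if (any(q <= 0)) stop("non-positive quantity", call. = FALSE)
    stats::setNames(q, rows$sample_id)
  }
  tgt <- quantify(table[table$target == target, , drop = FALSE])
  nrm <- quantify(table[table$target == normalizer, , drop = FALSE])
  samples <- names(tgt)
  if (!all(samples %in% names(nrm))) {
    stop(sprintf("missing normalizer measurement for sample(s): %s",
                 paste(utils::head(setdiff(samples, names(nrm)), 5L),
                       collapse = ", ")), call. = FALSE)
  }
  normalized <- tgt / nrm[samples]
  ref <- normalized[samples %in% reference_group]
  if (length(ref) == 0L) {
    stop("no samples in the reference group", call. = FALSE)
  }
  gm <- exp(mean(log(ref)))
  data.frame(sample_id = samples, target = target,
             normalized = unname(normalized),
             fold = unname(normalized / gm),
             stringsAsFactors = FALSE)
}

#' Exon/transcript splicing index
#'
#' The alternative-splicing (AS) measure: the exon-specific normalized
#' quantity divided by the transcript-level normalized quantity in the same
#' sample. Any common normalizer (Actb) cancels algebraically, so the ratio
#' is taken on the normalized values and either input form works. Folds are
#' computed versus the geometric mean of the reference group.
#'
#' @param exon_expr,transcript_expr outputs of [relative_expression()] for
#'   the exon-specific and transcript-level assays, with paired samples.
#' @param reference_group sample ids of the fold reference group.
#' @return Data frame: `sample_id`, `as_value`, `fold`.
#' @export
splicing_index <- function(exon_expr, transcript_expr, reference_group) {
  idx <- match(exon_expr$sample_id, transcript_expr$sample_id)
  if (anyNA(idx) || nrow(exon_expr) != nrow(transcript_expr)) {
    stop("exon and transcript tables must cover the same samples",
         call. = FALSE)
  }
  as_value <- exon_expr$normalized / transcript_expr$normalized[idx]
  ref <- as_value[exon_expr$sample_id %in% reference_group]
  if (length(ref) == 0L) stop("no samples in the reference group",
                              call. = FALSE)
  gm <- exp(mean(log(ref)))
  data.frame(sample_id = exon_expr$sample_id, as_value = as_value,
             fold = as_value / gm, stringsAsFactors = FALSE)
}

#' Percent exon inclusion from RT-PCR gel bands
#'
#' Size-corrects each band's area by its fragment length (molar signal =
#' area / length in bp) and reports
#' `100 * molar_included / (molar_included + molar_skipped)`.
#'
#' @param bands data frame for one lane pair with columns `isoform`
#'   (`"included"` / `"skipped"`), `area` (>= 0) and `length` (bp, > 0).
#' @return Percent inclusion in `[0, 100]`.
#' @examples
#' percent_inclusion(data.frame(isoform = c("included", "skipped"),
#'                              area = c(300, 100), length = c(300, 200)))
#' @export
percent_inclusion <- function(bands) {
  need <- c("isoform", "area", "length")
  if (!all(need %in% names(bands))) {
    stop("bands must have columns isoform, area, length", call. = FALSE)
  }
  inc <- bands[bands$isoform == "included", , drop = FALSE]
  skp <- bands[bands$isoform == "skipped", , drop = FALSE]
  if (nrow(inc) != 1L || nrow(skp) != 1L) {
    stop("need exactly one included and one skipped band", call. = FALSE)
  }
  if (any(bands$length <= 0) || any(bands$area < 0)) {
    stop("lengths must be > 0 and areas >= 0", call. = FALSE)
  }
  mi <- inc$area / inc$length
  ms <- skp$area / skp$length
  if (mi + ms == 0) stop("both molar signals are zero", call. = FALSE)
  100 * mi / (mi + ms)
}
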