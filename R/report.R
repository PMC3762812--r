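# Headline accounting: overlap subtraction between tandem and interspersed
# annotations, combined per-mode content reports, and genome-fraction
# arithmetic.

#' Subtract interspersed overlap from tandem annotations
#'
#' Tandem intervals are intersected against the union of the interspersed
#' intervals; overlapping bases are removed (intervals trimmed or split).
#'
#' @param tandem_annotations,interspersed_annotations interval
#'   `data.frame`s (`seq_id`, `start`, `end`, 0-based half-open) on the
#'   same set.
#' @param set the `SequenceSet`.
#' @return a list with `annotations` (residual tandem intervals), `bp`
#'   (residual total) and `pct` (residual percent of the set's non-N
#'   length).
#' @export
subtract_overlap <- function(tandem_annotations, interspersed_annotations,
                             set) {
  set <- as_sequence_set(set)
  denom <- summarize_set(set)$total_len
  if (is.null(tandem_annotations) || nrow(tandem_annotations) == 0L) {
    return(list(annotations = data.frame(
      seq_id = character(0), start = integer(0), end = integer(0),
      stringsAsFactors = FALSE
    ), bp = 0, pct = 0))
  }
  check_bounds(tandem_annotations, set)
  if (!is.null(interspersed_annotations) &&
        nrow(interspersed_annotations) > 0L) {
    check_bounds(interspersed_annotations, set)
  }
  out <- list()
  for (sid in unique(tandem_annotations$seq_id)) {
    t_iv <- tandem_annotations[tandem_annotations$seq_id == sid, ,
                               drop = FALSE]
    tr <- IRanges::IRanges(t_iv$start + 1L, t_iv$end)
    ir <- IRanges::IRanges()
    if (!is.null(interspersed_annotations) &&
          nrow(interspersed_annotations) > 0L) {
      i_iv <- interspersed_annotations[
        interspersed_annotations$seq_id == sid, , drop = FALSE]
      if (nrow(i_iv)) {
        ir <- IRanges::reduce(IRanges::IRanges(i_iv$start + 1L, i_iv$end))
      }
    }
    res <- IRanges::setdiff(IRanges::reduce(tr), ir)
    if (length(res)) {
      out[[length(out) + 1L]] <- data.frame(
        seq_id = sid, start = IRanges::start(res) - 1L,
        end = IRanges::end(res), stringsAsFactors = FALSE
      )
    }
  }
  ann <- if (length(out)) do.call(rbind, out) else data.frame(
    seq_id = character(0), start = integer(0), end = integer(0),
    stringsAsFactors = FALSE
  )
  bp <- sum(ann$end - ann$start)
  list(annotations = ann, bp = bp, pct = 100 * bp / denom)
}

# annotation df from instance/array-like frames
spans_of <- function(df) {
  if (is.null(df) || nrow(df) == 0L) {
    return(data.frame(seq_id = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  }
  data.frame(seq_id = df$seq_id %||% df$query_id,
             start = df$start %||% df$qstart,
             end = df$end %||% df$qend, stringsAsFactors = FALSE)
}

#' Combined repetitive-content report
#'
#' Combines tandem and interspersed annotations into per-mode totals.
#' `interspersed` is a named list of annotation `data.frame`s per mode
#' (e.g. `filtered`, `unfiltered`); within a mode the class-level rows are
#' summed to a mode total, the union of the mode's intervals gives the
#' interspersed coverage, tandem coverage is reported both raw and after
#' [subtract_overlap()] against that union, and total repetitive content
#' is the interspersed total plus the non-overlapping tandem remainder.
#'
#' @param set the `SequenceSet`.
#' @param tandem_arrays overlap-resolved tandem arrays (or `NULL`).
#' @param interspersed named list of modes; each mode is itself a named
#'   list of category annotation `data.frame`s (category name ->
#'   intervals), e.g. `list(filtered = list("Class I" = df1, Other = df2))`.
#' @param digits decimals for printed percentages.
#' @return a list with `categories` (per mode x category bp/pct,
#'   class-level rows summed to a `total` row) and `totals` (per mode:
#'   interspersed, raw tandem, non-overlapping tandem and total
#'   repetitive percentages).
#' @export
content_report <- function(set, tandem_arrays, interspersed, digits = 2L) {
  set <- as_sequence_set(set)
  denom <- summarize_set(set)$total_len
  t_spans <- spans_of(tandem_arrays)
  cat_rows <- list()
  tot_rows <- list()
  for (mode in names(interspersed)) {
    cats <- interspersed[[mode]]
    bp <- vapply(cats, function(df) {
      merged_coverage(spans_of(df), set)
    }, numeric(1))
    union_df <- do.call(rbind, lapply(cats, spans_of))
    union_bp <- merged_coverage(union_df, set)
    cat_rows[[mode]] <- data.frame(
      mode = mode,
      category = c(names(cats), "total"),
      bp = c(as.numeric(bp), sum(bp)),
      pct = round(100 * c(as.numeric(bp), sum(bp)) / denom, digits),
      stringsAsFactors = FALSE
    )
    sub <- subtract_overlap(t_spans, union_df, set)
    tandem_raw_bp <- merged_coverage(t_spans, set)
    tot_rows[[mode]] <- data.frame(
      mode = mode,
      interspersed_pct = round(100 * union_bp / denom, digits),
      tandem_pct_raw = round(100 * tandem_raw_bp / denom, digits),
      tandem_pct_nonoverlapping = round(sub$pct, digits),
      total_repetitive_pct = round(100 * (union_bp + sub$bp) / denom,
                                   digits),
      stringsAsFactors = FALSE
    )
  }
  list(categories = do.call(rbind, cat_rows),
       totals = do.call(rbind, tot_rows))
}

#' Fraction of a genome represented by a sequence set
#'
#' Uses the raw (N-included) assembled length against an externally
#' estimated genome size.
#'
#' @param set the `SequenceSet`, or directly the assembled length in bp
#'   (for sets too large to hold, e.g. published totals).
#' @param genome_size_bp estimated genome size in bp.
#' @param digits decimals.
#' @return percentage of the genome.
#' @export
genome_fraction <- function(set, genome_size_bp, digits = 2L) {
  stopifnot(genome_size_bp > 0)
  total <- if (is.numeric(set)) sum(set) else
    sum(Biostrings::width(as_sequence_set(set)$records))
  round(100 * total / genome_size_bp, digits)
}
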