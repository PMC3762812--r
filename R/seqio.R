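# FASTA I/O, sequence-set statistics, interval arithmetic and annotation
# export. Lengths and GC statistics exclude unresolved 'N' residues, and all
# "% of sequence set" denominators use the non-N total length.

#' Construct a sequence set
#'
#' A `SequenceSet` bundles a named [Biostrings::DNAStringSet] with a free-text
#' label. Sequence identifiers must be unique and residues are restricted to
#' the A/C/G/T/N alphabet (uppercase).
#'
#' @param records a named `DNAStringSet`, or a named character vector.
#' @param label free-text description of the set.
#' @return an object of class `SequenceSet` with elements `records` and
#'   `label`.
#' @export
sequence_set <- function(records, label = "") {
  if (is.character(records)) {
    records <- Biostrings::DNAStringSet(records)
  }
  ids <- names(records)
  if (is.null(ids) || any(!nzchar(ids))) {
    stop("all records must have non-empty ids")
  }
  if (anyDuplicated(ids)) {
    stop("duplicate sequence id: ", ids[duplicated(ids)][1L])
  }
  if (any(Biostrings::width(records) < 1L)) {
    stop("zero-length record in set")
  }
  structure(list(records = records, label = label), class = "SequenceSet")
}

#' @export
print.SequenceSet <- function(x, ...) {
  cat(sprintf(
    "SequenceSet%s: %d sequence(s), %s bp total\n",
    if (nzchar(x$label)) paste0(" '", x$label, "'") else "",
    length(x$records), format(sum(Biostrings::width(x$records)), big.mark = ",")
  ))
  invisible(x)
}

#' @export
length.SequenceSet <- function(x) length(x$records)

# accept a SequenceSet or a bare DNAStringSet/character vector
as_sequence_set <- function(set, label = "") {
  if (inherits(set, "SequenceSet")) return(set)
  sequence_set(set, label)
}

set_seqlens <- function(set) {
  stats::setNames(Biostrings::width(set$records), names(set$records))
}

#' Read genomic sequences from a FASTA file
#'
#' Residues are uppercased; characters outside A/C/G/T/N are mapped to N
#' (a message reports how many were replaced). Duplicate identifiers and
#' empty files are errors.
#'
#' @param path path to a FASTA file.
#' @param label optional label stored on the returned set.
#' @return a [sequence_set()].
#' @export
read_fasta <- function(path, label = basename(path)) {
  if (!file.exists(path)) stop("no such file: ", path)
  recs <- Biostrings::readBStringSet(path)
  if (length(recs) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(recs))
  if (anyDuplicated(ids)) {
    stop("duplicate sequence id in ", path, ": ", ids[duplicated(ids)][1L])
  }
  chars <- toupper(as.character(recs))
  n_before <- vapply(gregexpr("[^ACGTN]", chars), function(m) {
    if (m[1L] == -1L) 0L else length(m)
  }, integer(1))
  if (sum(n_before) > 0L) {
    message(sum(n_before), " non-ACGTN residue(s) replaced with N")
    chars <- gsub("[^ACGTN]", "N", chars)
  }
  recs <- Biostrings::DNAStringSet(chars)
  names(recs) <- ids
  sequence_set(recs, label)
}

#' Write a sequence set (or named sequences) to FASTA
#'
#' @param set a `SequenceSet`, `DNAStringSet` or named character vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(set, path) {
  recs <- if (inherits(set, "SequenceSet")) set$records else
    Biostrings::DNAStringSet(set)
  Biostrings::writeXStringSet(recs, path, width = 70L)
  invisible(path)
}

# per-record length excluding N
nonN_lengths <- function(set) {
  freq <- Biostrings::alphabetFrequency(set$records, baseOnly = TRUE)
  rowSums(freq[, c("A", "C", "G", "T"), drop = FALSE])
}

#' Summary statistics of a sequence set
#'
#' Unresolved residues ('N') are not counted: `total_len` and the length
#' quantiles are based on N-excluded lengths, and `gc` is the fraction of
#' non-N residues that are G or C. `n50` is the length L such that records of
#' (N-excluded) length >= L cumulatively contain at least half of
#' `total_len`. Mean and median lengths are truncated toward zero.
#'
#' @param set a `SequenceSet`.
#' @return a one-row `data.frame` with columns `count`, `total_len`,
#'   `mean_len`, `median_len`, `n50`, `shortest`, `longest`, `gc`.
#' @export
summarize_set <- function(set) {
  set <- as_sequence_set(set)
  if (length(set) == 0L) stop("empty sequence set")
  lens <- nonN_lengths(set)
  total <- sum(lens)
  freq <- Biostrings::alphabetFrequency(set$records, baseOnly = TRUE)
  gc <- sum(freq[, c("C", "G")]) / total
  sorted <- sort(lens, decreasing = TRUE)
  n50 <- sorted[which(cumsum(sorted) >= total / 2)[1L]]
  data.frame(
    count = length(set),
    total_len = total,
    mean_len = trunc_int(total / length(set)),
    median_len = trunc_int(stats::median(lens)),
    n50 = n50,
    shortest = min(lens),
    longest = max(lens),
    gc = gc
  )
}

#' GC content of a single sequence
#'
#' Fraction of non-N residues that are G or C. An all-N sequence is an error.
#'
#' @param x a single DNA sequence (character or `DNAString`).
#' @return a fraction in \[0, 1\].
#' @export
gc_content <- function(x) {
  x <- as.character(x)
  stopifnot(length(x) == 1L)
  iv <- seq_to_int(toupper(x))
  acgt <- sum(iv >= 0L)
  if (acgt == 0L) stop("sequence has no non-N residues")
  sum(iv == 1L | iv == 2L) / acgt
}

# ---- intervals ------------------------------------------------------------

#' Build an annotation/interval table
#'
#' Intervals are 0-based half-open. `category` is a free-text hierarchical
#' label and `score` a non-negative numeric.
#'
#' @param seq_id,start,end,strand,category,score vectors (recycled).
#' @return a `data.frame` with one row per interval.
#' @export
annotation_table <- function(seq_id, start, end, strand = ".",
                             category = "region", score = 0) {
  df <- data.frame(
    seq_id = as.character(seq_id), start = as.integer(start),
    end = as.integer(end), strand = strand, category = category,
    score = score, stringsAsFactors = FALSE
  )
  if (any(df$start < 0L) || any(df$end <= df$start)) {
    stop("invalid interval: need 0 <= start < end")
  }
  df
}

check_bounds <- function(intervals, set) {
  lens <- set_seqlens(as_sequence_set(set))
  unknown <- setdiff(intervals$seq_id, names(lens))
  if (length(unknown)) stop("unknown seq_id: ", unknown[1L])
  if (any(intervals$end > lens[intervals$seq_id])) {
    stop("interval out of sequence bounds")
  }
  invisible(TRUE)
}

#' Total merged (union) coverage of a set of intervals
#'
#' Overlapping intervals are unioned per sequence before summation, so
#' double-covered bases are counted once.
#'
#' @param intervals a `data.frame` with `seq_id`, `start`, `end` (0-based
#'   half-open).
#' @param set the `SequenceSet` the intervals refer to (for bounds checking).
#' @return total covered bp (integer).
#' @export
merged_coverage <- function(intervals, set) {
  if (is.null(intervals) || nrow(intervals) == 0L) return(0L)
  check_bounds(intervals, set)
  by_seq <- split(intervals, intervals$seq_id)
  total <- 0L
  for (iv in by_seq) {
    ir <- IRanges::IRanges(start = iv$start + 1L, end = iv$end)
    total <- total + sum(IRanges::width(IRanges::reduce(ir)))
  }
  total
}

# internal: annotations data.frame -> GRanges (1-based)
ann_to_granges <- function(ann, set) {
  set <- as_sequence_set(set)
  check_bounds(ann, set)
  lens <- set_seqlens(set)
  strand <- ifelse(ann$strand %in% c("+", "-"), ann$strand, "*")
  gr <- GenomicRanges::GRanges(
    seqnames = factor(ann$seq_id, levels = names(lens)),
    ranges = IRanges::IRanges(start = ann$start + 1L, end = ann$end),
    strand = strand,
    seqlengths = lens
  )
  gr$type <- ann$category
  gr$score <- as.numeric(ann$score)
  extra <- setdiff(names(ann), c("seq_id", "start", "end", "strand",
                                 "category", "score"))
  for (col in extra) S4Vectors::mcols(gr)[[col]] <- ann[[col]]
  gr
}

granges_to_ann <- function(gr) {
  strand <- as.character(GenomicRanges::strand(gr))
  strand[strand == "*"] <- "."
  category <- S4Vectors::mcols(gr)$type
  if (is.null(category)) category <- S4Vectors::mcols(gr)$name
  score <- S4Vectors::mcols(gr)$score
  annotation_table(
    seq_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = strand,
    category = if (is.null(category)) "region" else as.character(category),
    score = if (is.null(score)) 0 else ifelse(is.na(score), 0, score)
  )
}

#' Export annotations to GFF3 or BED
#'
#' GFF3 uses 1-based inclusive coordinates, BED 0-based half-open; internal
#' intervals are converted at the boundary. Round-tripping through the
#' corresponding reader preserves intervals exactly.
#'
#' @param annotations an [annotation_table()].
#' @param set the `SequenceSet` the annotations refer to.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(annotations, set, path) {
  gr <- ann_to_granges(annotations, set)
  rtracklayer::export(gr, path, format = "GFF3")
  invisible(path)
}

#' @rdname write_gff3
#' @export
write_bed <- function(annotations, set, path) {
  gr <- ann_to_granges(annotations, set)
  gr$name <- gr$type
  # BED scores are integers in [0, 1000]
  gr$score <- pmin(1000, pmax(0, round(gr$score)))
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read annotations from GFF3 or BED into the internal interval convention
#'
#' @param path input path.
#' @return an [annotation_table()] (0-based half-open).
#' @export
read_gff3 <- function(path) {
  granges_to_ann(rtracklayer::import(path, format = "GFF3"))
}

#' @rdname read_gff3
#' @export
read_bed <- function(path) {
  granges_to_ann(rtracklayer::import(path, format = "BED"))
}
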