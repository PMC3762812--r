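# Homology-based interspersed repeat annotation: alignment of a sequence
# set against a classified repeat library, the gap-adjusted sim similarity,
# the modified 80-80-80 full-length filter, redundant/non-redundant
# annotation modes and per-category coverage accounting.

#' Gap-adjusted alignment similarity (sim)
#'
#' `sim = match_count / (alignment_length - query_gap_length -
#' subject_gap_length + gap_count)`, where the gap lengths count gap
#' residues on each side and `gap_count` counts gap openings. For a
#' gap-free alignment all gap terms vanish and sim reduces to fraction
#' identity.
#'
#' @param match_count,alignment_length,query_gap_length,subject_gap_length,gap_count
#'   alignment statistics (vectors recycled to a common length), or a hit
#'   `data.frame` with those columns as the first argument.
#' @return numeric vector of similarities.
#' @export
sim_metric <- function(match_count, alignment_length = NULL,
                       query_gap_length = NULL, subject_gap_length = NULL,
                       gap_count = NULL) {
  if (is.data.frame(match_count)) {
    h <- match_count
    return(sim_metric(h$match_count, h$alignment_length, h$query_gap_length,
                      h$subject_gap_length, h$gap_count))
  }
  denom <- alignment_length - query_gap_length - subject_gap_length +
    gap_count
  if (any(denom <= 0)) stop("non-positive sim denominator")
  match_count / denom
}

#' Full-length (80-80-80) filter parameters
#'
#' The modified 80-80-80 standard: a hit must span strictly more than
#' `min_len` bp on the library (reference) element, have `sim` of at least
#' `min_sim`, and cover at least `min_subject_cov` of the reference.
#'
#' @param min_len minimum reference span in bp (strict >).
#' @param min_sim minimum sim.
#' @param min_subject_cov minimum fraction of the reference covered.
#' @return a parameter list.
#' @export
filter_params <- function(min_len = 80L, min_sim = 0.80,
                          min_subject_cov = 0.80) {
  stopifnot(min_sim > 0, min_sim <= 1, min_subject_cov > 0,
            min_subject_cov <= 1)
  list(min_len = min_len, min_sim = min_sim,
       min_subject_cov = min_subject_cov)
}

# ---- repeat library -------------------------------------------------------

#' Read a classified repeat library from FASTA
#'
#' Headers use the dialect `name#Class/Order/Superfamily/Family@species`;
#' classification fields and species may be omitted and default to
#' `"unknown"`.
#'
#' @param path FASTA path.
#' @return a `RepeatLibrary`: list with `seqs` (named character vector) and
#'   `info` (`data.frame` of classifications).
#' @export
read_repeat_library <- function(path) {
  recs <- Biostrings::readBStringSet(path)
  if (length(recs) == 0L) stop("empty repeat library: ", path)
  headers <- names(recs)
  repeat_library(stats::setNames(toupper(as.character(recs)), headers))
}

#' Construct a repeat library from named sequences
#'
#' @param seqs named character vector; names follow the
#'   `name#Class/Order/Superfamily/Family@species` dialect.
#' @return a `RepeatLibrary`.
#' @export
repeat_library <- function(seqs) {
  headers <- sub("\\s.*$", "", names(seqs))
  name <- sub("#.*$", "", headers)
  rest <- ifelse(grepl("#", headers), sub("^[^#]*#", "", headers), "")
  species <- ifelse(grepl("@", rest), sub("^.*@", "", rest), "unknown")
  rest <- sub("@.*$", "", rest)
  parts <- strsplit(rest, "/", fixed = TRUE)
  field <- function(i) vapply(parts, function(p) {
    if (length(p) >= i && nzchar(p[i])) p[i] else "unknown"
  }, character(1))
  if (anyDuplicated(name)) {
    stop("duplicate library entry name: ", name[duplicated(name)][1L])
  }
  info <- data.frame(
    name = name, class_ = field(1L), order = field(2L),
    superfamily = field(3L), family = field(4L), species = species,
    length = nchar(seqs), stringsAsFactors = FALSE, row.names = NULL
  )
  structure(list(seqs = stats::setNames(toupper(seqs), name), info = info),
            class = "RepeatLibrary")
}

#' Write a repeat library to FASTA with classification headers
#'
#' @param library a `RepeatLibrary`.
#' @param path output path.
#' @export
write_repeat_library <- function(library, path) {
  hdr <- with(library$info, paste0(
    name, "#", class_, "/", order, "/", superfamily, "/", family,
    "@", species
  ))
  write_fasta(stats::setNames(library$seqs, hdr), path)
  invisible(path)
}

#' Read BLAST tabular (12-column, outfmt 6 / -m 8) hits
#'
#' Per-side gap residues are reconstructed as alignment columns minus each
#' aligned span; `match_count` is approximated from the percent-identity
#' column and `gap_count` is the gap-opening count. Minus-strand hits are
#' encoded by `sstart > send` and are normalized to an ascending subject
#' interval with strand `-`.
#'
#' @param path path to a tabular BLAST report.
#' @param library a `RepeatLibrary` providing subject lengths.
#' @return a hit `data.frame` (see [local_align()]).
#' @export
read_blast_m8 <- function(path, library) {
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(raw) != 12L) {
    stop("expected 12 tab-separated columns, found ", ncol(raw))
  }
  names(raw) <- c("qid", "sid", "pident", "length", "mismatch", "gapopen",
                  "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  minus <- raw$sstart > raw$send
  s1 <- ifelse(minus, raw$send, raw$sstart)
  s2 <- ifelse(minus, raw$sstart, raw$send)
  match_count <- as.integer(round(raw$pident * raw$length / 100))
  qgap <- raw$length - (raw$qend - raw$qstart + 1L)
  sgap <- raw$length - (s2 - s1 + 1L)
  slen <- library$info$length[match(raw$sid, library$info$name)]
  if (anyNA(slen)) {
    stop("subject not in library: ", raw$sid[is.na(slen)][1L])
  }
  hits <- data.frame(
    query_id = raw$qid, qstart = raw$qstart - 1L, qend = raw$qend,
    subject_name = raw$sid, sstart = s1, send = s2,
    strand = ifelse(minus, "-", "+"), match_count = match_count,
    alignment_length = raw$length, query_gap_length = qgap,
    subject_gap_length = sgap, gap_count = raw$gapopen,
    score = raw$bitscore, sim = NA_real_, subject_len = slen,
    stringsAsFactors = FALSE
  )
  hits$sim <- sim_metric(hits)
  hits
}

# ---- filtering ------------------------------------------------------------

#' Apply the modified 80-80-80 full-length filter
#'
#' Keeps hits whose span on the library (reference) element is strictly
#' greater than `min_len` bp, whose sim is at least `min_sim`, and whose
#' reference span covers at least `min_subject_cov` of the full reference
#' length.
#'
#' @param hits a hit `data.frame`.
#' @param library a `RepeatLibrary` (used for subject lengths when the
#'   hits lack a `subject_len` column).
#' @param params a [filter_params()] list.
#' @return the retained hits.
#' @export
full_length_filter <- function(hits, library = NULL,
                               params = filter_params()) {
  if (nrow(hits) == 0L) return(hits)
  slen <- hits$subject_len
  if (is.null(slen) || anyNA(slen)) {
    if (is.null(library)) stop("need a library or subject_len column")
    slen <- library$info$length[match(hits$subject_name,
                                      library$info$name)]
    if (anyNA(slen)) {
      stop("subject not in library: ",
           hits$subject_name[is.na(slen)][1L])
    }
  }
  span <- hits$send - hits$sstart + 1L
  keep <- span > params$min_len & hits$sim >= params$min_sim &
    span / slen >= params$min_subject_cov
  hits[keep, , drop = FALSE]
}

#' Reduce hits to a non-redundant annotation
#'
#' Greedy selection by descending score (ties: longer query span, then
#' lexicographic subject name). A hit whose query span overlaps already
#' accepted hits by more than half of its own span is discarded.
#'
#' @param hits a hit `data.frame`.
#' @param max_overlap overlap tolerance as a fraction of the candidate's
#'   own query span.
#' @return the retained hits, ordered by position.
#' @export
nonredundant <- function(hits, max_overlap = 0.5) {
  if (nrow(hits) == 0L) return(hits)
  o <- order(-hits$score, -(hits$qend - hits$qstart), hits$subject_name)
  hits <- hits[o, , drop = FALSE]
  keep <- logical(nrow(hits))
  acc <- list()
  for (i in seq_len(nrow(hits))) {
    h <- hits[i, ]
    ivs <- acc[[h$query_id]]
    ov <- 0L
    if (!is.null(ivs)) {
      ov <- sum(IRanges::width(IRanges::intersect(
        IRanges::IRanges(h$qstart + 1L, h$qend), ivs
      )))
    }
    if (ov <= max_overlap * (h$qend - h$qstart)) {
      keep[i] <- TRUE
      acc[[h$query_id]] <- IRanges::union(
        if (is.null(ivs)) IRanges::IRanges() else ivs,
        IRanges::IRanges(h$qstart + 1L, h$qend)
      )
    }
  }
  out <- hits[keep, , drop = FALSE]
  out[order(out$query_id, out$qstart), , drop = FALSE]
}

# ---- annotation and coverage ----------------------------------------------

#' Annotate a sequence set against a repeat library
#'
#' Aligns every sequence against the library (seeded search with exact
#' alignment of candidate regions), optionally reduces the hits to a
#' non-redundant annotation, optionally applies the full-length
#' [full_length_filter()], and accounts merged coverage per classification
#' category.
#'
#' @param set a `SequenceSet`.
#' @param library a `RepeatLibrary`.
#' @param params [filter_params()] for the filtered mode.
#' @param redundancy `"nonredundant"` (highest-scoring annotation per
#'   region) or `"redundant"` (a region may be annotated more than once).
#' @param filtered apply the full-length filter.
#' @param scoring,min_score alignment scoring (see [align_scoring()]).
#' @return a list with `hits` (annotation hits), `coverage` (per-category
#'   coverage `data.frame` with `level`, `name`, `bp`, `pct`), and the
#'   mode flags.
#' @export
annotate_set <- function(set, library, params = filter_params(),
                         redundancy = c("nonredundant", "redundant"),
                         filtered = FALSE, scoring = align_scoring(),
                         min_score = 50) {
  redundancy <- match.arg(redundancy)
  set <- as_sequence_set(set)
  if (length(library$seqs) == 0L) stop("empty repeat library")
  qseqs <- stats::setNames(as.character(set$records), names(set$records))
  hits <- seeded_search(qseqs, library$seqs, scoring = scoring,
                        min_score = min_score)
  if (filtered) hits <- full_length_filter(hits, library, params)
  if (redundancy == "nonredundant") hits <- nonredundant(hits)
  cov <- coverage_report(hits, library, set)
  list(hits = hits, coverage = cov, redundancy = redundancy,
       filtered = filtered)
}

#' Per-category merged coverage of annotation hits
#'
#' Coverage is computed as merged (union) bp of the query spans per family
#' and aggregated upward by summation to superfamily, order and class;
#' percentages use the non-N total length of the set.
#'
#' @param hits a hit `data.frame`.
#' @param library the `RepeatLibrary` the hits refer to.
#' @param set the annotated `SequenceSet`.
#' @return a `data.frame` with columns `level` (class/order/superfamily/
#'   family/total), `name`, `bp`, `pct`.
#' @export
coverage_report <- function(hits, library, set) {
  set <- as_sequence_set(set)
  denom <- summarize_set(set)$total_len
  if (nrow(hits) == 0L) {
    return(data.frame(level = "total", name = "total", bp = 0, pct = 0,
                      stringsAsFactors = FALSE))
  }
  info <- library$info
  idx <- match(hits$subject_name, info$name)
  key <- data.frame(
    class_ = info$class_[idx], order = info$order[idx],
    superfamily = info$superfamily[idx], family = info$family[idx],
    stringsAsFactors = FALSE
  )
  # family-level names fall back to the library entry name
  key$family <- ifelse(key$family == "unknown", info$name[idx], key$family)
  fine <- paste(key$class_, key$order, key$superfamily, key$family,
                sep = "\r")
  groups <- unique(data.frame(key, fine = fine,
                              stringsAsFactors = FALSE))
  bp_fine <- vapply(groups$fine, function(g) {
    sel <- fine == g
    merged_coverage(data.frame(seq_id = hits$query_id[sel],
                               start = hits$qstart[sel],
                               end = hits$qend[sel]), set)
  }, numeric(1))
  groups$bp <- as.numeric(bp_fine)
  agg <- function(level) {
    s <- stats::aggregate(bp ~ name, data = data.frame(
      name = groups[[level]], bp = groups$bp
    ), FUN = sum)
    data.frame(level = level, name = s$name, bp = s$bp,
               stringsAsFactors = FALSE)
  }
  fam <- data.frame(level = "family", name = groups$family,
                    bp = groups$bp, stringsAsFactors = FALSE)
  if (anyDuplicated(fam$name)) {
    fam <- agg2 <- stats::aggregate(bp ~ name, data = fam, FUN = sum)
    fam <- data.frame(level = "family", name = agg2$name, bp = agg2$bp,
                      stringsAsFactors = FALSE)
  }
  names(groups)[names(groups) == "class_"] <- "class"
  out <- rbind(
    agg("class"), agg("order"), agg("superfamily"), fam,
    data.frame(level = "total", name = "total", bp = sum(groups$bp),
               stringsAsFactors = FALSE)
  )
  out$pct <- 100 * out$bp / denom
  rownames(out) <- NULL
  out
}

#' Gypsy to Copia coverage ratio
#'
#' @param report a [coverage_report()] `data.frame`.
#' @param digits decimals for rounding.
#' @return the ratio of Gypsy to Copia percent coverage, rounded; `NA` if
#'   Copia coverage is zero (undefined).
#' @export
gypsy_copia_ratio <- function(report, digits = 1L) {
  sf <- report[report$level == "superfamily", , drop = FALSE]
  g <- sum(sf$pct[sf$name == "Gypsy"])
  c_ <- sum(sf$pct[sf$name == "Copia"])
  if (c_ == 0) return(NA_real_)
  round(g / c_, digits)
}

# hits -> annotation_table for export
hits_to_annotations <- function(hits, library = NULL) {
  if (nrow(hits) == 0L) {
    return(annotation_table(character(0), integer(0), integer(0)))
  }
  category <- hits$subject_name
  if (!is.null(library)) {
    idx <- match(hits$subject_name, library$info$name)
    category <- paste(library$info$class_[idx], library$info$order[idx],
                      library$info$superfamily[idx], hits$subject_name,
                      sep = "/")
  }
  annotation_table(
    seq_id = hits$query_id, start = hits$qstart, end = hits$qend,
    strand = hits$strand, category = category, score = hits$score
  )
}
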