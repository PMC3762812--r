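# Pairwise alignment surface. Optimal local/global alignments are computed
# with Biostrings (Smith-Waterman / Needleman-Wunsch, affine gaps); every
# reported hit carries exact match and gap counts recomputed from the
# alignment traceback. Genome-scale searches first locate candidate regions
# by exact k-mer seeding and diagonal chaining, then align candidates
# exactly within windows.

#' Alignment scoring parameters
#'
#' Defaults emulate the BLASTN-style scoring used for nucleotide repeat
#' annotation: match +3, mismatch -4, affine gaps costing
#' `gap_open + gap_extend * L` for a gap of length L.
#'
#' @param match,mismatch substitution scores.
#' @param gap_open,gap_extend positive gap costs.
#' @return a list of scoring parameters.
#' @export
align_scoring <- function(match = 3, mismatch = -4, gap_open = 5,
                          gap_extend = 2) {
  stopifnot(match > 0, mismatch < 0, gap_open >= 0, gap_extend > 0)
  list(match = match, mismatch = mismatch, gap_open = gap_open,
       gap_extend = gap_extend)
}

# substitution matrix over ACGTN; N is effectively unalignable so that
# iterated masking with N excludes previous hits
scoring_matrix <- function(scoring) {
  letters <- c("A", "C", "G", "T", "N")
  m <- matrix(scoring$mismatch, 5, 5, dimnames = list(letters, letters))
  diag(m) <- scoring$match
  m["N", ] <- -1000
  m[, "N"] <- -1000
  m
}

# exact statistics from a pair of aligned strings (with '-' gaps)
aligned_stats <- function(pat, sub, scoring) {
  p <- strsplit(pat, "", fixed = TRUE)[[1L]]
  s <- strsplit(sub, "", fixed = TRUE)[[1L]]
  gap_p <- p == "-"
  gap_s <- s == "-"
  match_count <- sum(p == s & !gap_p)
  alen <- length(p)
  qgap <- sum(gap_p)
  sgap <- sum(gap_s)
  mismatch_count <- alen - match_count - qgap - sgap
  runs_p <- rle(gap_p)
  runs_s <- rle(gap_s)
  gap_lens <- c(runs_p$lengths[runs_p$values], runs_s$lengths[runs_s$values])
  score <- scoring$match * match_count + scoring$mismatch * mismatch_count -
    sum(scoring$gap_open + scoring$gap_extend * gap_lens)
  list(
    match_count = match_count, alignment_length = alen,
    query_gap_length = qgap, subject_gap_length = sgap,
    gap_count = length(gap_lens), score = score
  )
}

empty_hits <- function() {
  data.frame(
    query_id = character(0), qstart = integer(0), qend = integer(0),
    subject_name = character(0), sstart = integer(0), send = integer(0),
    strand = character(0), match_count = integer(0),
    alignment_length = integer(0), query_gap_length = integer(0),
    subject_gap_length = integer(0), gap_count = integer(0),
    score = numeric(0), sim = numeric(0), subject_len = integer(0),
    stringsAsFactors = FALSE
  )
}

#' Local alignment of two sequences with affine gaps
#'
#' Computes optimal Smith-Waterman local alignments on both strands.
#' Multiple non-overlapping hits are reported by iterated masking: after
#' each hit, its query span is masked and the search repeated until the
#' best remaining score drops below `min_score`. Each hit carries exact
#' match/gap counts from its traceback, the alignment score under the
#' given scoring scheme, and the gap-adjusted [sim_metric()].
#'
#' Query coordinates are 0-based half-open; subject coordinates are 1-based
#' inclusive on the (plus strand of the) subject. A minus-strand hit means
#' the query matches the reverse complement of the reported subject span.
#'
#' @param query,subject DNA sequences (character or `DNAString`).
#' @param scoring an [align_scoring()] list.
#' @param min_score minimum reported score.
#' @param both_strands also search the reverse complement of the subject.
#' @param max_hits cap on the number of reported hits.
#' @param query_id,subject_name identifiers stored on the hits.
#' @return a `data.frame` of alignment hits, ordered by decreasing score.
#' @export
local_align <- function(query, subject, scoring = align_scoring(),
                        min_score = 50, both_strands = TRUE, max_hits = 20L,
                        query_id = "query", subject_name = "subject") {
  query <- toupper(as.character(query))
  subject <- toupper(as.character(subject))
  if (nchar(query) == 0L || nchar(subject) == 0L) {
    stop("empty sequence in local_align")
  }
  mat <- scoring_matrix(scoring)
  slen <- nchar(subject)
  subj_fwd <- Biostrings::DNAString(subject)
  subj_rev <- if (both_strands) Biostrings::reverseComplement(subj_fwd)
  hits <- list()
  masked <- query
  for (i in seq_len(max_hits)) {
    q <- Biostrings::DNAString(masked)
    best <- NULL
    best_strand <- "+"
    for (strand in if (both_strands) c("+", "-") else "+") {
      s <- if (strand == "+") subj_fwd else subj_rev
      aln <- Biostrings::pairwiseAlignment(
        q, s, type = "local", substitutionMatrix = mat,
        gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend
      )
      if (is.null(best) || Biostrings::score(aln) > Biostrings::score(best)) {
        best <- aln
        best_strand <- strand
      }
    }
    pat <- as.character(Biostrings::alignedPattern(best))
    sub <- as.character(Biostrings::alignedSubject(best))
    st <- aligned_stats(pat, sub, scoring)
    if (st$score < min_score) break
    q1 <- Biostrings::start(Biostrings::pattern(best))
    q2 <- Biostrings::end(Biostrings::pattern(best))
    s1 <- Biostrings::start(Biostrings::subject(best))
    s2 <- Biostrings::end(Biostrings::subject(best))
    if (best_strand == "-") {
      tmp <- s1
      s1 <- slen - s2 + 1L
      s2 <- slen - tmp + 1L
    }
    hits[[length(hits) + 1L]] <- data.frame(
      query_id = query_id, qstart = q1 - 1L, qend = q2,
      subject_name = subject_name, sstart = s1, send = s2,
      strand = best_strand, match_count = st$match_count,
      alignment_length = st$alignment_length,
      query_gap_length = st$query_gap_length,
      subject_gap_length = st$subject_gap_length,
      gap_count = st$gap_count, score = st$score,
      sim = sim_metric(st$match_count, st$alignment_length,
                       st$query_gap_length, st$subject_gap_length,
                       st$gap_count),
      subject_len = slen, stringsAsFactors = FALSE
    )
    # mask the hit's query span and search again
    substr(masked, q1, q2) <- strrep("N", q2 - q1 + 1L)
  }
  if (length(hits) == 0L) return(empty_hits())
  out <- do.call(rbind, hits)
  out[order(-out$score), , drop = FALSE]
}

#' Global alignment identity of two sequences
#'
#' Needleman-Wunsch with end gaps penalized (the two sequences are assumed
#' comparable in extent); identity is matches over alignment columns.
#' Computed with the banded kernel, with a band wide enough to be exact at
#' the divergence levels relevant to the clustering thresholds.
#'
#' @inheritParams local_align
#' @return a fraction in \[0, 1\].
#' @export
global_identity <- function(query, subject, scoring = align_scoring()) {
  res <- band_global(query, subject, scoring)
  res$matches / res$aln_len
}

# ---- k-mer seeding --------------------------------------------------------

# k-mer position tables for a set of sequences; strand "-" positions are in
# reverse-complement coordinates
kmer_index <- function(seqs, k, both_strands = FALSE) {
  ids <- names(seqs)
  out <- vector("list", length(seqs) * (1L + both_strands))
  n <- 0L
  for (i in seq_along(seqs)) {
    iv <- seq_to_int(seqs[[i]])
    dt <- kmer_table(iv, k)
    dt[, `:=`(seq_id = ids[i], strand = "+")]
    n <- n + 1L
    out[[n]] <- dt
    if (both_strands) {
      dtr <- kmer_table(seq_to_int(revcomp(seqs[[i]])), k)
      dtr[, `:=`(seq_id = ids[i], strand = "-")]
      n <- n + 1L
      out[[n]] <- dtr
    }
  }
  rbindlist(out[seq_len(n)])
}

#' Seed-and-chain candidate regions between two sequence sets
#'
#' Exact k-mer matches are collected (k-mers occurring more than `max_occ`
#' times in either set are dropped, which skips low-complexity regions),
#' grouped by sequence pair and strand, and chained along diagonals with a
#' drift tolerance of `band` bp and a positional gap tolerance of
#' `max_gap` bp. Chains supported by at least `min_chain` k-mer matches
#' become candidate regions for exact alignment.
#'
#' With `self = TRUE` the two sets are the same object: matches on the
#' trivial self-diagonal are removed and symmetric pairs deduplicated.
#'
#' @param qseqs,sseqs named character vectors of sequences.
#' @param k k-mer size (<= 15).
#' @param max_occ occurrence cap per k-mer.
#' @param min_chain minimum k-mer matches per chain.
#' @param band diagonal drift tolerance (bp).
#' @param max_gap maximum positional gap within a chain (bp).
#' @param both_strands search the minus strand of the subject set too.
#' @param self the query and subject sets are the same sequences.
#' @return a `data.frame` of chains: `qseq`, `sseq`, `strand`, `qlo`, `qhi`,
#'   `slo`, `shi` (0-based half-open; minus-strand subject coordinates are
#'   in reverse-complement space), `n_kmers`.
#' @keywords internal
seed_chains <- function(qseqs, sseqs, k = 12L, max_occ = 40L, min_chain = 4L,
                        band = 32L, max_gap = 600L, both_strands = TRUE,
                        self = FALSE) {
  qdt <- kmer_index(qseqs, k, both_strands = FALSE)
  sdt <- kmer_index(sseqs, k, both_strands = both_strands)
  if (nrow(qdt) == 0L || nrow(sdt) == 0L) return(empty_chains())
  # drop over-frequent k-mers (tandem/low-complexity regions)
  scnt <- sdt[, .N, by = hash]
  qcnt <- qdt[, .N, by = hash]
  bad <- unique(c(scnt[N > max_occ, hash], qcnt[N > max_occ, hash]))
  if (length(bad)) {
    sdt <- sdt[!hash %in% bad]
    qdt <- qdt[!hash %in% bad]
  }
  data.table::setnames(qdt, c("pos", "seq_id", "strand"),
                       c("qpos", "qseq", "qstrand"))
  data.table::setnames(sdt, c("pos", "seq_id", "strand"),
                       c("spos", "sseq", "sstrand"))
  pairs <- merge(qdt[, .(hash, qpos, qseq)],
                 sdt[, .(hash, spos, sseq, sstrand)],
                 by = "hash", allow.cartesian = TRUE)
  if (nrow(pairs) == 0L) return(empty_chains())
  if (self) {
    qidx <- match(pairs$qseq, names(qseqs))
    sidx <- match(pairs$sseq, names(sseqs))
    slen <- nchar(sseqs)[sidx]
    same <- qidx == sidx
    plus <- pairs$sstrand == "+"
    keep <- (!same & qidx < sidx) |
      (same & plus & pairs$spos - pairs$qpos >= 40L) |
      (same & !plus & pairs$qpos < slen - pairs$spos - k)
    pairs <- pairs[keep]
  }
  if (nrow(pairs) == 0L) return(empty_chains())
  pairs[, diag_ := spos - qpos]
  setorder(pairs, qseq, sseq, sstrand, diag_, qpos)
  grp <- pairs[, paste(qseq, sseq, sstrand, sep = "\r")]
  new_grp <- c(TRUE, grp[-1L] != grp[-length(grp)])
  d_jump <- c(TRUE, diff(pairs$diag_) > band)
  cl1 <- cumsum(new_grp | d_jump)
  pairs[, chain_id := cl1]
  setorder(pairs, chain_id, qpos)
  p_jump <- c(TRUE, diff(pairs$qpos) > max_gap)
  new_cl <- c(TRUE, pairs$chain_id[-1L] != pairs$chain_id[-nrow(pairs)])
  pairs[, chain_id := cumsum(new_cl | p_jump)]
  chains <- pairs[, .(
    qseq = qseq[1L], sseq = sseq[1L], strand = sstrand[1L],
    qlo = min(qpos), qhi = max(qpos) + k,
    slo = min(spos), shi = max(spos) + k,
    n_kmers = .N
  ), by = chain_id]
  chains <- chains[n_kmers >= min_chain]
  as.data.frame(chains[, -"chain_id"])
}

# merge chains of the same (qseq, sseq, strand) that belong to one
# candidate locus: their query intervals must overlap (or nearly touch)
# AND their subject intervals must be consistent, so sub-chains (e.g. a
# terminal repeat match nested in a full-element match) collapse while
# adjacent distinct copies stay separate
merge_chains <- function(chains, qseqs, sseqs, project = TRUE,
                         pad = 100L, tol = 30L) {
  if (nrow(chains) <= 1L) return(chains)
  key <- paste(chains$qseq, chains$sseq, chains$strand, sep = "\r")
  o <- order(key, chains$qlo)
  chains <- chains[o, , drop = FALSE]
  key <- key[o]
  grp <- integer(nrow(chains))
  cur <- 0L
  cur_qhi <- -1L
  cur_slo <- 0L
  cur_shi <- -1L
  cur_key <- ""
  for (i in seq_len(nrow(chains))) {
    q_over <- chains$qlo[i] <= cur_qhi + tol
    s_over <- chains$slo[i] <= cur_shi + tol &&
      chains$shi[i] >= cur_slo - tol
    if (key[i] != cur_key || !q_over || !s_over) {
      cur <- cur + 1L
      cur_key <- key[i]
      cur_qhi <- chains$qhi[i]
      cur_slo <- chains$slo[i]
      cur_shi <- chains$shi[i]
    } else {
      cur_qhi <- max(cur_qhi, chains$qhi[i])
      cur_slo <- min(cur_slo, chains$slo[i])
      cur_shi <- max(cur_shi, chains$shi[i])
    }
    grp[i] <- cur
  }
  dt <- as.data.table(cbind(chains, grp = grp))
  out <- dt[, .(
    qseq = qseq[1L], sseq = sseq[1L], strand = strand[1L],
    qlo = min(qlo), qhi = max(qhi), slo = min(slo), shi = max(shi),
    n_kmers = sum(n_kmers)
  ), by = grp]
  as.data.frame(out[, -"grp"])
}

empty_chains <- function() {
  data.frame(qseq = character(0), sseq = character(0), strand = character(0),
             qlo = integer(0), qhi = integer(0), slo = integer(0),
             shi = integer(0), n_kmers = integer(0), stringsAsFactors = FALSE)
}

# Align one chained candidate region exactly; returns hits in genome
# coordinates (query 0-based half-open, subject 1-based inclusive on the
# plus strand). With project = TRUE the query window is extended so that the
# full extent of the subject could fit (used when mapping library/seed
# elements to find full-length copies).
align_chain <- function(chain, qseqs, sseqs, scoring = align_scoring(),
                        min_score = 50, pad = 100L, project = FALSE,
                        max_hits = 1L) {
  qs <- qseqs[[chain$qseq]]
  ss <- sseqs[[chain$sseq]]
  qlen <- nchar(qs)
  slen <- nchar(ss)
  if (project) {
    w1 <- max(0L, chain$qlo - chain$slo - pad)
    w2 <- min(qlen, chain$qhi + (slen - chain$shi) + pad)
  } else {
    w1 <- max(0L, chain$qlo - pad)
    w2 <- min(qlen, chain$qhi + pad)
  }
  qwin <- substr(qs, w1 + 1L, w2)
  v1 <- max(0L, chain$slo - pad)
  v2 <- min(slen, chain$shi + pad)
  if (chain$strand == "-") {
    swin <- substr(revcomp(ss), v1 + 1L, v2)
  } else {
    swin <- substr(ss, v1 + 1L, v2)
  }
  # band: diagonal range implied by the chain (window coordinates) plus a
  # drift margin
  margin <- 150L
  lo <- (chain$slo - v1) - (chain$qhi - w1) - margin
  hi <- (chain$shi - v1) - (chain$qlo - w1) + margin
  res <- band_local(qwin, swin, lo, hi, scoring)
  if (res$score < min_score) return(empty_hits())
  hits <- band_hit_row(res, query_id = chain$qseq,
                       subject_name = chain$sseq)
  hits$qstart <- hits$qstart + w1
  hits$qend <- hits$qend + w1
  if (chain$strand == "-") {
    # subject window coordinates are in revcomp space: map back to plus
    a <- hits$sstart + v1
    b <- hits$send + v1
    hits$sstart <- slen - b + 1L
    hits$send <- slen - a + 1L
    hits$strand <- "-"
  } else {
    hits$sstart <- hits$sstart + v1
    hits$send <- hits$send + v1
  }
  hits$subject_len <- slen
  hits
}

# Seeded search of a query set against a subject library: chain, then align
# each candidate region. Hits deduplicated by (query span, subject) keeping
# the best score.
seeded_search <- function(qseqs, sseqs, scoring = align_scoring(),
                          min_score = 50, k = 12L, max_occ = 40L,
                          min_chain = 4L, project = TRUE, pad = 100L) {
  chains <- seed_chains(qseqs, sseqs, k = k, max_occ = max_occ,
                        min_chain = min_chain, both_strands = TRUE)
  if (nrow(chains) == 0L) return(empty_hits())
  chains <- merge_chains(chains, qseqs, sseqs, project = project, pad = pad)
  hits <- lapply(seq_len(nrow(chains)), function(i) {
    align_chain(chains[i, ], qseqs, sseqs, scoring = scoring,
                min_score = min_score, pad = pad, project = project)
  })
  hits <- do.call(rbind, hits)
  if (is.null(hits) || nrow(hits) == 0L) return(empty_hits())
  # near-duplicate hits can arise from overlapping chains: keep best score
  # among hits with ~identical query spans on the same subject
  setorder(setDT <- as.data.table(hits), -score)
  hits <- as.data.frame(setDT)
  keep <- rep(TRUE, nrow(hits))
  for (i in seq_len(nrow(hits))) {
    if (!keep[i]) next
    if (i == nrow(hits)) break
    j <- which(keep & seq_len(nrow(hits)) > i &
                 hits$query_id == hits$query_id[i] &
                 hits$subject_name == hits$subject_name[i] &
                 hits$strand == hits$strand[i])
    if (length(j)) {
      ov <- pmax(0L, pmin(hits$qend[j], hits$qend[i]) -
                   pmax(hits$qstart[j], hits$qstart[i]))
      span_j <- hits$qend[j] - hits$qstart[j]
      keep[j[ov > 0.9 * span_j]] <- FALSE
    }
  }
  hits[keep, , drop = FALSE]
}
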