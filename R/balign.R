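# R surface over the banded affine-gap aligner (src/balign.cpp). Banded
# alignment is exact whenever the optimal path stays within the band; it
# is used where a k-mer seeding stage (or the sequence lengths themselves)
# constrain the alignment diagonal, which is the case for all genome-scale
# searches in this package.

# exact global (NW, end gaps penalized) statistics via the banded kernel;
# the band is centered on the length-difference diagonal with a margin
# generous enough for the indel densities this package works at
band_global <- function(a, b, scoring = align_scoring(), margin = NULL) {
  ia <- seq_to_int(toupper(as.character(a)))
  ib <- seq_to_int(toupper(as.character(b)))
  n <- length(ia)
  m <- length(ib)
  if (n == 0L || m == 0L) stop("empty sequence in band_global")
  d <- m - n
  if (is.null(margin)) margin <- max(150L, ceiling(0.2 * max(n, m)))
  .band_align(ia, ib, 0L, min(0L, d) - margin, max(0L, d) + margin,
              scoring$match, scoring$mismatch, scoring$gap_open,
              scoring$gap_extend)
}

# banded local alignment of two windows given a diagonal range
band_local <- function(a, b, lo, hi, scoring = align_scoring()) {
  ia <- seq_to_int(toupper(as.character(a)))
  ib <- seq_to_int(toupper(as.character(b)))
  lo <- max(lo, -length(ia))
  hi <- min(hi, length(ib))
  .band_align(ia, ib, 1L, lo, hi, scoring$match, scoring$mismatch,
              scoring$gap_open, scoring$gap_extend)
}

# res from .band_align -> one hit row (window coordinates)
band_hit_row <- function(res, query_id = "query",
                         subject_name = "subject", subject_len = NA_integer_) {
  data.frame(
    query_id = query_id, qstart = res$q1 - 1L, qend = res$q2,
    subject_name = subject_name, sstart = res$s1, send = res$s2,
    strand = "+", match_count = res$matches,
    alignment_length = res$aln_len, query_gap_length = res$qgap,
    subject_gap_length = res$sgap, gap_count = res$gap_count,
    score = res$score,
    sim = sim_metric(res$matches, res$aln_len, res$qgap, res$sgap,
                     res$gap_count),
    subject_len = subject_len, stringsAsFactors = FALSE
  )
}

# ---- k-mer containment prefilter ------------------------------------------

# sorted unique k-mer hash set of a sequence
kmer_set <- function(seq, k = 12L) {
  dt <- kmer_table(seq_to_int(toupper(seq)), k)
  sort(unique(dt$hash))
}

# shared k-mer fraction relative to the smaller set; a cheap upper-bound
# screen for sequence identity (at 80% identity ~ 0.8^12 = 7% of k-mers
# survive exactly, so thresholds well below that are safe)
kmer_containment <- function(set_a, set_b) {
  if (length(set_a) == 0L || length(set_b) == 0L) return(0)
  length(intersect(set_a, set_b)) / min(length(set_a), length(set_b))
}
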