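# Low-level sequence helpers shared across modules.
# Internal coordinates are 0-based half-open throughout; conversions to
# 1-based inclusive happen only at format boundaries (GFF3, TRF, BLAST).

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of a DNA string
#'
#' @param x a character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# character sequence -> integer code vector (A=0, C=1, G=2, T=3, other=-1)
seq_to_int <- function(x) {
  v <- utf8ToInt(x)
  out <- rep.int(-1L, length(v))
  out[v == 65L] <- 0L   # A
  out[v == 67L] <- 1L   # C
  out[v == 71L] <- 2L   # G
  out[v == 84L] <- 3L   # T
  out
}

int_to_seq <- function(v) {
  paste(DNA_BASES[v + 1L], collapse = "")
}

# Rolling k-mer hash over an integer-coded sequence. Windows containing a
# non-ACGT code are dropped. Returns data.table(pos, hash) with pos 0-based.
# Requires 4^k < 2^31 (k <= 15).
kmer_table <- function(iv, k) {
  n <- length(iv) - k + 1L
  if (n < 1L) {
    return(data.table(pos = integer(0), hash = integer(0)))
  }
  h <- iv[seq_len(n)]
  for (j in 2:k) {
    h <- h * 4L + iv[j:(n + j - 1L)]
  }
  bad <- cumsum(iv < 0L)
  nbad <- bad[k:(n + k - 1L)] - c(0L, bad)[seq_len(n)]
  keep <- nbad == 0L
  data.table(pos = which(keep) - 1L, hash = h[keep])
}

# uniform random DNA with a given GC fraction
random_dna <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(DNA_BASES, n, replace = TRUE, prob = p), collapse = "")
}

# majority base per column of a character matrix over {A,C,G,T,-};
# ties resolved in favor of `prefer` (a character vector, one per column).
majority_consensus <- function(mat, prefer = NULL) {
  apply_col <- function(j) {
    col <- mat[, j]
    tab <- table(factor(col, levels = c(DNA_BASES, "-")))
    top <- max(tab)
    winners <- names(tab)[tab == top]
    if (!is.null(prefer) && prefer[j] %in% winners) {
      return(prefer[j])
    }
    winners[1L]
  }
  vapply(seq_len(ncol(mat)), apply_col, character(1))
}

trunc_int <- function(x) trunc(x)

`%||%` <- function(a, b) if (is.null(a)) b else a
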