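# Independent oracles used to cross-check the package's alignment and
# interval machinery on small inputs. These are deliberately naive
# implementations, written without reference to the package internals.

# best local alignment score by plain-R affine-gap DP (Gotoh), full
# matrices, no banding, no traceback
oracle_local_score <- function(a, b, match = 3, mismatch = -4,
                               gap_open = 5, gap_extend = 2) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av)
  m <- length(bv)
  NEG <- -1e9
  M <- matrix(0, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)
  Y <- matrix(NEG, n + 1, m + 1)
  best <- 0
  for (i in 1:n) {
    for (j in 1:m) {
      s <- if (av[i] == bv[j]) match else mismatch
      M[i + 1, j + 1] <- max(0, M[i, j], X[i, j], Y[i, j]) + s
      X[i + 1, j + 1] <- max(M[i, j + 1] - gap_open - gap_extend,
                             X[i, j + 1] - gap_extend)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - gap_open - gap_extend,
                             Y[i + 1, j] - gap_extend)
      best <- max(best, M[i + 1, j + 1])
    }
  }
  best
}

# union coverage of intervals by per-base boolean mask
oracle_mask_coverage <- function(intervals, seqlens) {
  total <- 0L
  for (sid in names(seqlens)) {
    mask <- logical(seqlens[[sid]])
    rows <- intervals[intervals$seq_id == sid, , drop = FALSE]
    for (r in seq_len(nrow(rows))) {
      if (rows$end[r] > rows$start[r]) {
        mask[(rows$start[r] + 1):rows$end[r]] <- TRUE
      }
    }
    total <- total + sum(mask)
  }
  total
}

# residual tandem bp after removing interspersed overlap, by mask
oracle_mask_subtract <- function(tandem, interspersed, seqlens) {
  total <- 0L
  for (sid in names(seqlens)) {
    tmask <- logical(seqlens[[sid]])
    imask <- logical(seqlens[[sid]])
    tr <- tandem[tandem$seq_id == sid, , drop = FALSE]
    ir <- interspersed[interspersed$seq_id == sid, , drop = FALSE]
    for (r in seq_len(nrow(tr))) tmask[(tr$start[r] + 1):tr$end[r]] <- TRUE
    for (r in seq_len(nrow(ir))) imask[(ir$start[r] + 1):ir$end[r]] <- TRUE
    total <- total + sum(tmask & !imask)
  }
  total
}

# exhaustive greedy-rule oracle for score-ordered overlap resolution:
# replays the stated greedy rule literally over all candidates, used to
# confirm the package's (possibly optimized) implementation agrees
oracle_greedy_keep <- function(df, max_overlap_frac, tie_cols) {
  ord <- do.call(order, c(list(-df$score), lapply(tie_cols, function(cn) {
    if (cn == "span") -(df$end - df$start) else df[[cn]]
  })))
  df <- df[ord, , drop = FALSE]
  kept <- df[0, ]
  for (i in seq_len(nrow(df))) {
    cand <- df[i, ]
    acc <- kept[kept$seq_id == cand$seq_id, , drop = FALSE]
    ov <- 0L
    if (nrow(acc)) {
      covered <- logical(cand$end - cand$start)
      for (r in seq_len(nrow(acc))) {
        lo <- max(acc$start[r], cand$start) - cand$start
        hi <- min(acc$end[r], cand$end) - cand$start
        if (hi > lo) covered[(lo + 1):hi] <- TRUE
      }
      ov <- sum(covered)
    }
    if (ov <= max_overlap_frac * (cand$end - cand$start)) {
      kept <- rbind(kept, cand)
    }
  }
  kept
}

# random DNA string helper
rand_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}
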