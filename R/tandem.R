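# Tandem repeat detection, ingestion, overlap resolution, classification
# into microsatellite (2-8 bp), minisatellite (9-100 bp) and satellite
# (>100 bp) bins, and the associated set-level statistics. Mononucleotide
# arrays (period 1) are excluded throughout: single-base runs are prone to
# collapse during assembly and are not informative here.

#' Tandem detection parameters
#'
#' Scoring follows the Tandem Repeat Finder convention: match +2,
#' mismatch -7, indel -7, minimum reported alignment score 50. Periods from
#' `min_period` to `max_period` are considered and arrays must span at
#' least `min_copies` copies.
#'
#' @param min_period,max_period period (repeat unit) size range in bp.
#' @param match,mismatch,indel alignment weights.
#' @param min_score minimum array alignment score.
#' @param min_copies minimum (fractional) copy number.
#' @return a parameter list.
#' @export
tandem_params <- function(min_period = 2L, max_period = 500L, match = 2L,
                          mismatch = -7L, indel = -7L, min_score = 50L,
                          min_copies = 1.8) {
  stopifnot(min_period >= 2L, max_period <= 500L, min_period <= max_period)
  list(min_period = as.integer(min_period),
       max_period = as.integer(max_period),
       match = as.integer(match), mismatch = as.integer(mismatch),
       indel = as.integer(indel), min_score = as.integer(min_score),
       min_copies = min_copies)
}

empty_tandem <- function() {
  data.frame(
    seq_id = character(0), start = integer(0), end = integer(0),
    period_size = integer(0), copy_number = numeric(0),
    consensus_motif = character(0), percent_matches = numeric(0),
    score = numeric(0), at_fraction = numeric(0), stringsAsFactors = FALSE
  )
}

# candidate (position, period) votes from k-mer recurrence distances:
# h[i] == h[i+d] votes for period d at position i. k = 5 for periods >= 5,
# k = period for shorter periods.
tandem_votes <- function(iv, params) {
  votes <- list()
  n <- length(iv)
  for (k in 2:4) {
    if (k < params$min_period || k > params$max_period) next
    ht <- kmer_hash_vec(iv, k)
    m <- length(ht) - k
    if (m < 1L) next
    hit <- which(!is.na(ht[1:m]) & !is.na(ht[(1 + k):(m + k)]) &
                   ht[1:m] == ht[(1 + k):(m + k)])
    if (length(hit)) {
      votes[[length(votes) + 1L]] <- data.table(pos = hit - 1L, period = k)
    }
  }
  ht <- kmer_hash_vec(iv, 5L)
  if (length(ht) > 5L) {
    dt <- data.table(pos = seq_along(ht) - 1L, hash = ht)[!is.na(hash)]
    setorder(dt, hash, pos)
    d <- c(diff(dt$pos), 0L)
    same <- c(dt$hash[-1L] == dt$hash[-nrow(dt)], FALSE)
    lo <- max(5L, params$min_period)
    sel <- same & d >= lo & d <= params$max_period
    if (any(sel)) {
      votes[[length(votes) + 1L]] <-
        data.table(pos = dt$pos[sel], period = d[sel])
    }
  }
  if (length(votes) == 0L) return(data.table(pos = integer(0),
                                             period = integer(0)))
  rbindlist(votes)
}

# plain hash vector (NA where the window covers a non-ACGT base)
kmer_hash_vec <- function(iv, k) {
  n <- length(iv) - k + 1L
  if (n < 1L) return(integer(0))
  h <- iv[seq_len(n)]
  for (j in 2:k) h <- h * 4L + iv[j:(n + j - 1L)]
  bad <- cumsum(iv < 0L)
  nbad <- bad[k:(n + k - 1L)] - c(0L, bad)[seq_len(n)]
  h[nbad > 0L] <- NA_integer_
  h
}

# group votes of one period into candidate windows
vote_regions <- function(votes, params) {
  if (nrow(votes) == 0L) return(NULL)
  setorder(votes, period, pos)
  # short periods recur by chance every 4^p positions, so their chains
  # must be split much more aggressively than long-period (k = 5) votes
  gap_lim <- ifelse(votes$period <= 4L, 2L * votes$period + 4L,
                    pmax(2L * votes$period + 20L, 40L))
  new_p <- c(TRUE, votes$period[-1L] != votes$period[-nrow(votes)])
  jump <- c(TRUE, diff(votes$pos) > gap_lim[-1L])
  votes[, chain_id := cumsum(new_p | jump)]
  regions <- votes[, .(
    period = period[1L], lo = min(pos), hi = max(pos) + period[1L] + 5L,
    n_votes = .N
  ), by = chain_id]
  # prune implausible candidates before the (comparatively expensive)
  # wraparound verification: votes must span most of a second period copy
  # (an array needs >= ~1.8 copies) and occur at a density far above the
  # random-recurrence background
  vote_span <- regions$hi - regions$lo - regions$period - 5L
  regions <- regions[n_votes >= 3L &
                       vote_span >= 0.6 * regions$period &
                       n_votes >= 0.25 * vote_span]
  if (nrow(regions) == 0L) return(NULL)
  regions[, -"chain_id"]
}

# majority consensus of the complete period-chunks of a window
phase_consensus <- function(iv_win, p) {
  m <- length(iv_win) %/% p
  if (m < 1L) return(NULL)
  chunk <- matrix(iv_win[seq_len(m * p)], nrow = p)
  cons <- integer(p)
  for (j in seq_len(p)) {
    row <- chunk[j, ]
    row <- row[row >= 0L]
    if (length(row) == 0L) return(NULL)
    tab <- tabulate(row + 1L, nbins = 4L)
    cons[j] <- which.max(tab) - 1L
  }
  cons
}

#' Detect tandem repeats in a sequence set
#'
#' A simplified tandem-array detector: candidate periods are proposed from
#' exact k-mer recurrence distances (k = 5 for periods >= 5, k = period for
#' shorter periods), and each candidate window is verified by local
#' wraparound dynamic programming against its majority period consensus,
#' which extends the array maximally and yields the array score, matches
#' and fractional copy number. Arrays with score >= `min_score` and
#' copy number >= `min_copies` are reported; harmonic duplicates (the same
#' span re-detected at a multiple of its period) are removed, preferring
#' the smaller period on ties.
#'
#' @param set a `SequenceSet` (or named character vector).
#' @param params a [tandem_params()] list.
#' @return a `data.frame` of tandem arrays with columns `seq_id`, `start`,
#'   `end` (0-based half-open), `period_size`, `copy_number` (one decimal),
#'   `consensus_motif`, `percent_matches`, `score`, `at_fraction`.
#' @export
detect_tandem <- function(set, params = tandem_params()) {
  set <- as_sequence_set(set)
  out <- lapply(names(set$records), function(id) {
    detect_tandem_one(as.character(set$records[[id]]), id, params)
  })
  out <- do.call(rbind, out)
  if (is.null(out) || nrow(out) == 0L) return(empty_tandem())
  out
}

detect_tandem_one <- function(seq, seq_id, params) {
  n <- nchar(seq)
  if (n < 2L * params$min_period) return(empty_tandem())
  iv <- seq_to_int(seq)
  votes <- tandem_votes(iv, params)
  regions <- vote_regions(votes, params)
  if (is.null(regions) || nrow(regions) == 0L) return(empty_tandem())
  arrays <- vector("list", nrow(regions))
  for (i in seq_len(nrow(regions))) {
    p <- regions$period[i]
    w1 <- max(0L, regions$lo[i] - p - 5L)
    w2 <- min(n, regions$hi[i] + p + 5L)
    win <- iv[(w1 + 1L):w2]
    cons <- phase_consensus(win, p)
    if (is.null(cons)) next
    res <- .wrap_align(win, cons, params$match, params$mismatch,
                       params$indel)
    if (res$score < params$min_score) next
    copies <- round(res$cons_cols / p, 1L)
    if (copies < params$min_copies) next
    idx <- if (res$cstart == 0L) seq_len(p) else
      c((res$cstart + 1L):p, seq_len(res$cstart))
    motif <- int_to_seq(cons[idx])
    span <- win[(res$qstart + 1L):res$qend]
    at <- sum(span == 0L | span == 3L) / sum(span >= 0L)
    arrays[[i]] <- data.frame(
      seq_id = seq_id, start = w1 + res$qstart, end = w1 + res$qend,
      period_size = p, copy_number = copies, consensus_motif = motif,
      percent_matches = res$matches / res$aln_cols, score = res$score,
      at_fraction = at, stringsAsFactors = FALSE
    )
  }
  arrays <- do.call(rbind, arrays)
  if (is.null(arrays) || nrow(arrays) == 0L) return(empty_tandem())
  dedup_harmonics(arrays)
}

# drop re-detections of the same span at a period multiple; prefer higher
# score, then smaller period, then leftmost
dedup_harmonics <- function(arrays) {
  o <- order(-arrays$score, arrays$period_size, arrays$start)
  arrays <- arrays[o, , drop = FALSE]
  keep <- rep(TRUE, nrow(arrays))
  for (i in seq_len(nrow(arrays))) {
    if (!keep[i]) next
    j <- which(keep & seq_len(nrow(arrays)) > i)
    if (!length(j)) break
    ov <- pmax(0L, pmin(arrays$end[j], arrays$end[i]) -
                 pmax(arrays$start[j], arrays$start[i]))
    span_j <- arrays$end[j] - arrays$start[j]
    harmonic <- arrays$period_size[j] %% arrays$period_size[i] == 0L |
      arrays$period_size[i] %% arrays$period_size[j] == 0L
    keep[j[ov > 0.5 * span_j & harmonic]] <- FALSE
  }
  arrays <- arrays[keep, , drop = FALSE]
  arrays[order(arrays$seq_id, arrays$start), , drop = FALSE]
}

#' Read a Tandem Repeat Finder .dat file
#'
#' Parses the TRF data-line dialect (`Sequence:` headers followed by
#' whitespace-separated records). TRF's 1-based inclusive coordinates are
#' converted to the internal 0-based half-open convention; period-1
#' (mononucleotide) records are dropped with a message.
#'
#' @param path path to a TRF `.dat` file.
#' @return a tandem array `data.frame` (see [detect_tandem()]).
#' @export
read_trf_dat <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  cur <- NA_character_
  rows <- list()
  dropped <- 0L
  for (ln in seq_along(lines)) {
    line <- trimws(lines[ln])
    if (!nzchar(line)) next
    if (startsWith(line, "Sequence:")) {
      cur <- trimws(sub("^Sequence:\\s*", "", line))
      cur <- sub("\\s.*$", "", cur)
      next
    }
    if (grepl("^[0-9]", line)) {
      f <- strsplit(line, "\\s+")[[1L]]
      if (length(f) < 15L) {
        stop("malformed TRF data line ", ln, ": expected 15 fields")
      }
      num <- suppressWarnings(as.numeric(f[1:13]))
      if (anyNA(num)) stop("malformed TRF data line ", ln)
      if (is.na(cur)) stop("TRF data line ", ln, " before any Sequence header")
      if (num[3L] == 1) {
        dropped <- dropped + 1L
        next
      }
      at <- (num[9L] + num[12L]) / 100
      rows[[length(rows) + 1L]] <- data.frame(
        seq_id = cur, start = as.integer(num[1L]) - 1L,
        end = as.integer(num[2L]), period_size = as.integer(num[3L]),
        copy_number = num[4L], consensus_motif = f[14L],
        percent_matches = num[6L] / 100, score = num[8L],
        at_fraction = at, stringsAsFactors = FALSE
      )
    }
  }
  if (dropped > 0L) message(dropped, " period-1 record(s) dropped")
  if (length(rows) == 0L) return(empty_tandem())
  do.call(rbind, rows)
}

#' Resolve overlapping tandem arrays by alignment score
#'
#' Greedy selection by descending score (ties: longer array, then
#' leftmost, then smaller period). An array overlapping an already accepted
#' array by more than `max_overlap` of its own length is discarded.
#'
#' @param arrays a tandem array `data.frame`.
#' @param max_overlap overlap tolerance as a fraction of the candidate's
#'   own length.
#' @return the retained arrays, sorted by position.
#' @export
resolve_tandem_overlaps <- function(arrays, max_overlap = 0.1) {
  if (nrow(arrays) == 0L) return(arrays)
  o <- order(-arrays$score, -(arrays$end - arrays$start), arrays$start,
             arrays$period_size)
  arrays <- arrays[o, , drop = FALSE]
  keep <- logical(nrow(arrays))
  acc <- list()
  for (i in seq_len(nrow(arrays))) {
    a <- arrays[i, ]
    ivs <- acc[[a$seq_id]]
    ov <- 0L
    if (!is.null(ivs)) {
      ov <- sum(IRanges::width(IRanges::intersect(
        IRanges::IRanges(a$start + 1L, a$end), ivs
      )))
    }
    if (ov <= max_overlap * (a$end - a$start)) {
      keep[i] <- TRUE
      acc[[a$seq_id]] <- IRanges::union(
        if (is.null(ivs)) IRanges::IRanges() else ivs,
        IRanges::IRanges(a$start + 1L, a$end)
      )
    }
  }
  out <- arrays[keep, , drop = FALSE]
  out[order(out$seq_id, out$start), , drop = FALSE]
}

#' Canonical form of a tandem repeat motif
#'
#' The lexicographically smallest string among all cyclic rotations of the
#' motif and of its reverse complement, so that e.g. AT/TA arrays or the
#' six AT-rich trinucleotide spellings collapse to one motif class.
#'
#' @param motif character vector of motifs (A/C/G/T, length >= 2).
#' @return character vector of canonical motifs.
#' @export
canonical_motif <- function(motif) {
  motif <- toupper(motif)
  u <- unique(motif)
  if (any(nchar(u) < 2L)) stop("motif length must be >= 2")
  bad <- grepl("[^ACGT]", u)
  if (any(bad)) stop("non-ACGT character in motif: ", u[bad][1L])
  urc <- revcomp(u)
  canon <- vapply(seq_along(u), function(i) {
    n <- nchar(u[i])
    rot <- function(x) {
      d <- paste0(x, x)
      substring(d, seq_len(n), seq_len(n) + n - 1L)
    }
    min(c(rot(u[i]), rot(urc[i])))
  }, character(1))
  canon[match(motif, u)]
}

tandem_class_of <- function(period) {
  ifelse(period <= 8L, "micro", ifelse(period <= 100L, "mini", "sat"))
}

tandem_subbin_of <- function(period) {
  micro <- c("di", "tri", "tetra", "penta", "hexa", "hepta", "octa")
  ifelse(period <= 8L, micro[pmin(period, 8L) - 1L],
  ifelse(period <= 30L, "9-30",
  ifelse(period <= 50L, "31-50",
  ifelse(period <= 70L, "51-70",
  ifelse(period <= 100L, "71-100",
  ifelse(period <= 200L, "101-200",
  ifelse(period <= 300L, "201-300",
  ifelse(period <= 400L, "301-400", ">400"))))))))
}

tandem_bin_levels <- function() {
  list(
    micro = c("di", "tri", "tetra", "penta", "hexa", "hepta", "octa"),
    mini = c("9-30", "31-50", "51-70", "71-100"),
    sat = c("101-200", "201-300", "301-400", ">400")
  )
}

#' Classify tandem arrays and summarize by class bin
#'
#' Arrays are binned into microsatellites (periods 2-8 bp, sub-bins di- to
#' octanucleotide), minisatellites (9-100 bp) and satellites (>100 bp).
#' Per bin the summary reports locus counts, summed copy number, the number
#' of distinct canonical motifs ("variants"), total array length and the
#' percentage of the sequence set (non-N denominator). Class totals and the
#' grand total are computed by summation over their bins.
#'
#' @param arrays overlap-resolved tandem arrays.
#' @param set the `SequenceSet` the arrays belong to.
#' @param denominator_bp optional non-N set length to use for the
#'   percentage column instead of measuring `set` (useful when tabulating
#'   arrays from an external run whose sequences are not at hand).
#' @return a `data.frame` with one row per sub-bin, class totals and a
#'   grand total (`level` column distinguishes them).
#' @export
classify_and_summarize <- function(arrays, set, denominator_bp = NULL) {
  denom <- denominator_bp %||% summarize_set(as_sequence_set(set))$total_len
  bins <- tandem_bin_levels()
  all_bins <- data.frame(
    class_ = rep(names(bins), lengths(bins)),
    sub_bin = unlist(bins, use.names = FALSE), stringsAsFactors = FALSE
  )
  if (nrow(arrays) > 0L) {
    arrays$class_ <- tandem_class_of(arrays$period_size)
    arrays$sub_bin <- tandem_subbin_of(arrays$period_size)
    arrays$canon <- canonical_motif(arrays$consensus_motif)
  }
  per_bin <- lapply(seq_len(nrow(all_bins)), function(i) {
    sel <- if (nrow(arrays) == 0L) logical(0) else
      arrays$class_ == all_bins$class_[i] &
      arrays$sub_bin == all_bins$sub_bin[i]
    a <- arrays[sel, , drop = FALSE]
    data.frame(
      level = "sub_bin", class_ = all_bins$class_[i],
      sub_bin = all_bins$sub_bin[i], total_loci = nrow(a),
      copy_number = round(sum(a$copy_number), 1L),
      variants = length(unique(a$canon)),
      total_length = sum(a$end - a$start),
      stringsAsFactors = FALSE
    )
  })
  per_bin <- do.call(rbind, per_bin)
  class_tot <- do.call(rbind, lapply(names(bins), function(cl) {
    b <- per_bin[per_bin$class_ == cl, , drop = FALSE]
    sel <- if (nrow(arrays) == 0L) logical(0) else arrays$class_ == cl
    data.frame(
      level = "class_total", class_ = cl, sub_bin = "total",
      total_loci = sum(b$total_loci),
      copy_number = round(sum(b$copy_number), 1L),
      variants = length(unique(arrays$canon[sel])),
      total_length = sum(b$total_length), stringsAsFactors = FALSE
    )
  }))
  grand <- data.frame(
    level = "grand_total", class_ = "all", sub_bin = "total",
    total_loci = sum(class_tot$total_loci),
    copy_number = round(sum(class_tot$copy_number), 1L),
    variants = if (nrow(arrays)) length(unique(arrays$canon)) else 0L,
    total_length = sum(class_tot$total_length), stringsAsFactors = FALSE
  )
  out <- rbind(per_bin, class_tot, grand)
  out$pct_of_set <- 100 * out$total_length / denom
  out
}

#' Microsatellite density per sub-bin
#'
#' Number of microsatellite arrays per Mbp of (non-N) sequence, for each
#' sub-bin from dinucleotide to octanucleotide.
#'
#' @param arrays tandem arrays.
#' @param set the `SequenceSet`.
#' @return named numeric vector of loci per Mbp.
#' @export
microsat_density <- function(arrays, set) {
  set <- as_sequence_set(set)
  mbp <- summarize_set(set)$total_len / 1e6
  levels <- tandem_bin_levels()$micro
  micro <- arrays[arrays$period_size <= 8L, , drop = FALSE]
  counts <- table(factor(tandem_subbin_of(micro$period_size),
                         levels = levels))
  as.numeric(counts) / mbp -> d
  stats::setNames(d, levels)
}

#' Fraction of tandem arrays that are AT-rich
#'
#' AT-richness uses the strict definition A% + T% > 60% computed on the
#' array's genomic span.
#'
#' @param arrays tandem arrays (with `at_fraction`).
#' @return fraction of arrays with A+T strictly above 60%.
#' @export
at_richness <- function(arrays) {
  if (nrow(arrays) == 0L) return(NaN)
  mean(arrays$at_fraction > 0.6)
}
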