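# brute-force verification of a single candidate window: best ungapped
# phase alignment score over all periods, used as an oracle for the
# detector's period call on clean planted arrays
oracle_best_period <- function(win, max_period = 30) {
  best <- list(score = -Inf, period = NA)
  n <- nchar(win)
  chars <- strsplit(win, "")[[1]]
  for (p in 2:min(max_period, n %/% 2)) {
    m <- n %/% p
    mat <- matrix(chars[1:(m * p)], nrow = p)
    cons <- apply(mat, 1, function(r) names(which.max(table(r))))
    tiled <- rep(cons, length.out = n)
    sc <- sum(ifelse(chars == tiled, 2, -7))
    if (sc > best$score) best <- list(score = sc, period = p)
  }
  best
}

test_that("detect_tandem finds a planted dinucleotide array", {
  set.seed(31)
  s <- paste0(rand_dna(500, 0.38), strrep("AT", 20), rand_dna(460, 0.38))
  arr <- detect_tandem(setNames(s, "s1"))
  expect_equal(nrow(arr), 1L)
  expect_equal(arr$period_size, 2L)
  expect_equal(canonical_motif(arr$consensus_motif), "AT")
  expect_lt(abs(arr$copy_number - 20), 1.0)
  # the 40 bp window's best period by exhaustive phase scan is also 2
  win <- substr(s, 501, 540)
  expect_equal(oracle_best_period(win)$period, 2L)
})

test_that("random sequence rarely yields arrays at the default threshold", {
  hits <- 0L
  for (seed in 1:100) {
    set.seed(seed)
    arr <- detect_tandem(setNames(rand_dna(500, 0.38), "r"))
    if (nrow(arr) > 0L) hits <- hits + 1L
  }
  expect_lte(hits, 5L)
})

test_that("a high-copy 25 bp satellite is recovered with exact copy number", {
  set.seed(32)
  motif <- "TGCTTTGCTGCTTAGTCTCTCATAG"
  s <- paste0(rand_dna(1000, 0.38), strrep(motif, 654), rand_dna(1000, 0.38))
  arr <- detect_tandem(setNames(s, "fosmid"))
  arr <- arr[which.max(arr$score), ]
  expect_equal(arr$period_size, 25L)
  expect_lt(abs(arr$copy_number - 654), 1.0)
  expect_equal(arr$consensus_motif, motif)
})

test_that("diverged planted arrays across the period range are recovered", {
  set.seed(33)
  plan <- list(c(3, 25), c(7, 12), c(15, 9), c(51, 5), c(120, 4),
               c(250, 3))
  pieces <- character(0)
  truth <- integer(0)
  for (pc in plan) {
    motif <- rand_dna(pc[1])
    arr <- strrep(motif, pc[2])
    ch <- strsplit(arr, "")[[1]]
    mut <- runif(length(ch)) < 0.03
    ch[mut] <- sample(c("A", "C", "G", "T"), sum(mut), replace = TRUE)
    pieces <- c(pieces, rand_dna(700, 0.38), paste(ch, collapse = ""))
    truth <- c(truth, pc[1])
  }
  s <- paste0(paste(pieces, collapse = ""), rand_dna(700, 0.38))
  arr <- resolve_tandem_overlaps(detect_tandem(setNames(s, "g")))
  found <- vapply(truth, function(p) {
    any(arr$period_size %% p == 0 | p %% arr$period_size == 0)
  }, logical(1))
  expect_gte(mean(found), 0.9)
})

test_that("read_trf_dat parses the .dat dialect and drops period-1 records", {
  dat <- tempfile(fileext = ".dat")
  writeLines(c(
    "Tandem Repeats Finder Program written by some author",
    "",
    "Sequence: chrA some description",
    "",
    "Parameters: 2 7 7 80 10 50 500",
    "",
    "1 12 2 6.0 2 100 0 24 50 0 0 50 1.00 AT ATATATATATAT",
    "500 519 1 20.0 1 100 0 40 100 0 0 0 0.00 A AAAAAAAAAAAAAAAAAAAA",
    "Sequence: chrB",
    "30 59 10 3.0 10 95 0 51 30 20 20 30 1.90 ACGTACGTAA ACGTACGTAAACGTACGTAAACGTACGTAA"
  ), dat)
  expect_message(arr <- read_trf_dat(dat), "period-1")
  expect_equal(nrow(arr), 2L)
  expect_equal(arr$seq_id, c("chrA", "chrB"))
  # TRF is 1-based inclusive; internal convention is 0-based half-open
  expect_equal(arr$start[1], 0L)
  expect_equal(arr$end[1], 12L)
  expect_equal(arr$period_size[1], 2L)
  expect_equal(arr$copy_number[1], 6.0)
  expect_equal(arr$at_fraction[2], 0.6)

  writeLines(c("Sequence: x", "5 abc"), dat)
  expect_error(read_trf_dat(dat), "line 2")
  writeLines(character(0), dat)
  expect_equal(nrow(read_trf_dat(dat)), 0L)
})

test_that("overlap resolution keeps high-scoring arrays", {
  arr <- function(start, end, score, period = 2, seq_id = "s") {
    data.frame(seq_id = seq_id, start = start, end = end,
               period_size = period, copy_number = (end - start) / period,
               consensus_motif = "AT", percent_matches = 1, score = score,
               at_fraction = 1, stringsAsFactors = FALSE)
  }
  two <- rbind(arr(0, 100, 100), arr(0, 100, 80))
  kept <- resolve_tandem_overlaps(two)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$score, 100)

  disjoint <- rbind(arr(0, 100, 100), arr(200, 300, 80))
  expect_equal(nrow(resolve_tandem_overlaps(disjoint)), 2L)

  # chain A > B > C with only A-B and B-C overlaps: B is discarded
  # against A, C survives because it only overlapped B
  chain <- rbind(arr(0, 100, 100), arr(80, 180, 90), arr(160, 260, 80))
  kept <- resolve_tandem_overlaps(chain)
  expect_equal(sort(kept$score), c(80, 100))
})

test_that("overlap resolution matches the greedy-rule oracle on random inputs", {
  set.seed(34)
  for (rep in 1:15) {
    n <- sample(3:10, 1)
    start <- sample(0:500, n, replace = TRUE)
    df <- data.frame(
      seq_id = "s", start = start, end = start + sample(20:200, n, TRUE),
      period_size = sample(2:10, n, TRUE), copy_number = 5,
      consensus_motif = "AT", percent_matches = 1,
      score = sample(50:500, n), at_fraction = 1, stringsAsFactors = FALSE
    )
    kept <- resolve_tandem_overlaps(df)
    want <- oracle_greedy_keep(df, 0.1, list("span", "start"))
    expect_setequal(paste(kept$start, kept$end, kept$score),
                    paste(want$start, want$end, want$score))
  }
})

test_that("canonical_motif minimizes over rotations and reverse complement", {
  expect_equal(canonical_motif("TA"), "AT")
  expect_equal(canonical_motif("TTA"), "AAT")
  expect_equal(canonical_motif(c("AAT", "ATA", "TAT", "TTA", "TAA", "ATT")),
               rep("AAT", 6))
  expect_error(canonical_motif("ANT"), "non-ACGT")
  set.seed(35)
  for (i in 1:20) {
    m <- rand_dna(sample(2:12, 1))
    canon <- canonical_motif(m)
    # idempotent, rotation-invariant, reverse-complement-invariant
    expect_equal(canonical_motif(canon), canon)
    rot <- paste0(substr(m, 3, nchar(m)), substr(m, 1, 2))
    if (nchar(m) > 2) expect_equal(canonical_motif(rot), canon)
    expect_equal(canonical_motif(revcomp(m)), canon)
  }
})

test_that("classification bins follow the micro/mini/satellite boundaries", {
  arr <- function(period, len) {
    data.frame(seq_id = "s", start = 0, end = len, period_size = period,
               copy_number = round(len / period, 1),
               consensus_motif = substr(strrep("ACGTACGTAC", 60), 1, period),
               percent_matches = 1, score = 100, at_fraction = 0.5,
               stringsAsFactors = FALSE)
  }
  arrays <- rbind(arr(2, 40), arr(8, 64), arr(9, 90), arr(100, 400),
                  arr(101, 404), arr(500, 1500))
  set <- sequence_set(c(s = strrep("A", 2000)))
  s <- classify_and_summarize(arrays, set)
  cls <- s[s$level == "class_total", ]
  expect_equal(cls$total_loci[cls$class_ == "micro"], 2L)
  expect_equal(cls$total_loci[cls$class_ == "mini"], 2L)
  expect_equal(cls$total_loci[cls$class_ == "sat"], 2L)
  grand <- s[s$level == "grand_total", ]
  expect_equal(grand$total_loci, 6L)
  expect_equal(grand$total_length, sum(cls$total_length))
  expect_equal(grand$copy_number, round(sum(arrays$copy_number), 1))
})

test_that("summary totals reproduce published class-level arithmetic", {
  # one synthetic array per class bin carrying the published per-class
  # totals as its loci/copy/length mass is impossible (loci are counted
  # per row), so the published table is reproduced row-by-row: 5,143
  # micro + 51,997 mini + 6,482 sat loci with class lengths 241,822 /
  # 4,323,361 / 2,650,740 bp must sum to 63,622 loci and 7,215,923 bp
  mk <- function(n, period, total_len, copy_total) {
    len <- rep(total_len %/% n, n)
    len[1] <- len[1] + total_len - sum(len)
    cp <- rep(round(copy_total / n, 1), n)
    data.frame(seq_id = "s", start = 0, end = len, period_size = period,
               copy_number = cp, consensus_motif = strrep("ACGTA", period)[1],
               percent_matches = 1, score = 100, at_fraction = 0.5,
               stringsAsFactors = FALSE)
  }
  arrays <- rbind(
    mk(5143, 2, 241822, 89986.1),
    mk(51997, 21, 4323361, 137633),
    mk(6482, 123, 2650740, 15828)
  )
  arrays$consensus_motif <- c(strrep("AC", 1), strrep("ACGTACGTACGTACGTACGTA", 1),
                              strrep("ACG", 41))[
    c(rep(1, 5143), rep(2, 51997), rep(3, 6482))]
  s <- classify_and_summarize(arrays, NULL, denominator_bp = 277338566)
  grand <- s[s$level == "grand_total", ]
  expect_equal(grand$total_loci, 63622L)
  expect_equal(grand$total_length, 7215923)
  cls <- s[s$level == "class_total", ]
  expect_equal(sum(cls$total_loci), grand$total_loci)
  expect_equal(round(100 * grand$total_length / 277338566, 3), 2.602)
})

test_that("microsatellite density scales with set size", {
  arr <- data.frame(seq_id = "s", start = seq(0, 900, by = 100),
                    end = seq(40, 940, by = 100), period_size = 2,
                    copy_number = 20, consensus_motif = "AT",
                    percent_matches = 1, score = 100, at_fraction = 1,
                    stringsAsFactors = FALSE)
  set1 <- sequence_set(c(s = strrep("A", 1000000)))
  d <- microsat_density(arr, set1)
  expect_equal(unname(d["di"]), 10)
  expect_equal(unname(d["tri"]), 0)
  set2 <- sequence_set(c(s = strrep("A", 1000000),
                         t = strrep("A", 1000000)))
  expect_equal(unname(microsat_density(arr, set2)["di"]), 5)
  empty <- arr[0, ]
  expect_true(all(microsat_density(empty, set1) == 0))
})

test_that("AT-richness uses the strict 60% rule", {
  arr <- data.frame(at_fraction = c(1, 0.6, 0))
  expect_equal(at_richness(arr), 1 / 3)
  arr2 <- data.frame(at_fraction = 6 / 10)  # exactly 60% is not AT-rich
  expect_equal(at_richness(arr2), 0)
})
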