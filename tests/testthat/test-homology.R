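test_that("sim metric evaluates the gap-adjusted formula", {
  # ungapped: reduces to identity
  expect_equal(sim_metric(90, 100, 0, 0, 0), 0.9)
  # 95 matches over 105 columns with a single 5 bp query gap opening
  expect_equal(sim_metric(95, 105, 5, 0, 1), 95 / 101)
  # perfect 80-column alignment
  expect_equal(sim_metric(80, 80, 0, 0, 0), 1.0)
  expect_error(sim_metric(10, 10, 6, 6, 1), "denominator")
})

test_that("sim reduces to fraction identity for every gap-free traceback", {
  set.seed(41)
  for (i in 1:50) {
    len <- sample(10:300, 1)
    matches <- sample(0:len, 1)
    expect_equal(sim_metric(matches, len, 0, 0, 0), matches / len)
  }
})

test_that("sim on real gapped tracebacks matches hand accounting", {
  set.seed(42)
  a <- rand_dna(400)
  mc <- mutate_copy(a, 0.05, 0.01)
  h <- local_align(a, mc$seq)
  expect_equal(
    h$sim,
    h$match_count / (h$alignment_length - h$query_gap_length -
                       h$subject_gap_length + h$gap_count)
  )
})

test_that("repeat library headers parse the classification dialect", {
  lib <- repeat_library(c(
    "TPE1#I/LTR/Copia/TPE1@Pinus_elliottii" = "ACGTACGTAC",
    "mystery" = "GGGTTTACGT",
    "halfway#I/LINE" = "TTTACGTACG"
  ))
  expect_equal(lib$info$name, c("TPE1", "mystery", "halfway"))
  expect_equal(lib$info$superfamily, c("Copia", "unknown", "unknown"))
  expect_equal(lib$info$order, c("LTR", "unknown", "LINE"))
  expect_equal(lib$info$species, c("Pinus_elliottii", "unknown", "unknown"))
  fa <- tempfile(fileext = ".fa")
  write_repeat_library(lib, fa)
  back <- read_repeat_library(fa)
  expect_equal(back$info$superfamily, lib$info$superfamily)
  expect_equal(unname(back$seqs), unname(lib$seqs))
})

test_that("read_blast_m8 reconstructs gap and strand information", {
  lib <- repeat_library(c("elem#I/LTR/Gypsy/elem@x" = strrep("ACGT", 60)))
  m8 <- tempfile(fileext = ".tsv")
  rows <- c(
    # pident length mismatch gapopen qstart qend sstart send
    paste(c("q1", "elem", 100, 80, 0, 0, 1, 80, 1, 80, "1e-30", 160),
          collapse = "\t"),
    paste(c("q1", "elem", 95, 105, 5, 1, 200, 299, 1, 105, "1e-20", 150),
          collapse = "\t"),
    paste(c("q2", "elem", 98, 100, 2, 0, 10, 109, 200, 101, "1e-25", 155),
          collapse = "\t")
  )
  writeLines(rows, m8)
  hits <- read_blast_m8(m8, lib)
  expect_equal(hits$match_count[1], 80L)
  expect_equal(hits$sim[1], 1.0)
  # alignment columns minus query span = query gap residues
  expect_equal(hits$query_gap_length[2], 5L)
  expect_equal(hits$gap_count[2], 1L)
  # sstart > send encodes the minus strand
  expect_equal(hits$strand[3], "-")
  expect_equal(c(hits$sstart[3], hits$send[3]), c(101L, 200L))

  writeLines("only\tfour\tcolumns\there", m8)
  expect_error(read_blast_m8(m8, lib), "12")
})

test_that("the three 80-80-80 clauses reject boundary cases independently", {
  lib <- repeat_library(c("ref#I/LTR/Gypsy/ref@x" = strrep("ACGT", 60)))
  hit <- function(span, sim, slen = 240L) {
    data.frame(
      query_id = "q", qstart = 0L, qend = span, subject_name = "ref",
      sstart = 1L, send = span, strand = "+", match_count = 1L,
      alignment_length = span, query_gap_length = 0L,
      subject_gap_length = 0L, gap_count = 0L, score = 100,
      sim = sim, subject_len = slen, stringsAsFactors = FALSE
    )
  }
  # 79 and 80 bp spans are both rejected (strict > 80), 81 bp passes the
  # length clause but fails coverage on a 240 bp reference
  expect_equal(nrow(full_length_filter(hit(79, 0.95), lib)), 0L)
  expect_equal(nrow(full_length_filter(hit(80, 0.95), lib)), 0L)
  expect_equal(nrow(full_length_filter(hit(81, 0.95), lib)), 0L)
  # span 200/240 = 0.833 coverage with sim 0.85: kept
  expect_equal(nrow(full_length_filter(hit(200, 0.85), lib)), 1L)
  # sim just below threshold: rejected
  expect_equal(nrow(full_length_filter(hit(200, 0.799), lib)), 0L)
  # coverage just below threshold: rejected
  expect_equal(nrow(full_length_filter(hit(191, 0.95), lib)), 0L)
  expect_equal(nrow(full_length_filter(hit(192, 0.95), lib)), 1L)
})

test_that("nonredundant keeps the best-scoring annotation per region", {
  hit <- function(qstart, qend, score, subject = "a") {
    data.frame(query_id = "q", qstart = qstart, qend = qend,
               subject_name = subject, sstart = 1L,
               send = qend - qstart, strand = "+", match_count = 1L,
               alignment_length = qend - qstart, query_gap_length = 0L,
               subject_gap_length = 0L, gap_count = 0L, score = score,
               sim = 0.9, subject_len = 100L, stringsAsFactors = FALSE)
  }
  co <- rbind(hit(0, 100, 500), hit(0, 100, 300, "b"))
  expect_equal(nonredundant(co)$score, 500)
  disjoint <- rbind(hit(0, 100, 500), hit(200, 300, 300))
  expect_equal(nrow(nonredundant(disjoint)), 2L)
  # A > B > C chain where B overlaps A by 60% (discarded) and C only
  # overlapped B, so C survives
  chain <- rbind(hit(0, 100, 500), hit(40, 140, 400), hit(120, 220, 300))
  kept <- nonredundant(chain)
  expect_setequal(kept$score, c(500, 300))
})

test_that("nonredundant agrees with the greedy-rule oracle on random hits", {
  set.seed(43)
  for (rep in 1:15) {
    n <- sample(3:10, 1)
    qs <- sample(0:400, n, replace = TRUE)
    hits <- data.frame(
      query_id = "q", qstart = qs, qend = qs + sample(30:150, n, TRUE),
      subject_name = sample(letters[1:3], n, TRUE), sstart = 1L,
      send = 50L, strand = "+", match_count = 40L,
      alignment_length = 50L, query_gap_length = 0L,
      subject_gap_length = 0L, gap_count = 0L,
      score = sample(100:900, n), sim = 0.9, subject_len = 100L,
      stringsAsFactors = FALSE
    )
    kept <- nonredundant(hits)
    df <- data.frame(seq_id = hits$query_id, start = hits$qstart,
                     end = hits$qend, score = hits$score,
                     subject_name = hits$subject_name)
    want <- oracle_greedy_keep(df, 0.5, list("span", "subject_name"))
    expect_setequal(paste(kept$qstart, kept$qend, kept$score),
                    paste(want$start, want$end, want$score))
  }
})

test_that("filtered annotations are a subset of unfiltered ones", {
  sim <- small_sim()
  lib <- small_library()
  unf <- annotate_set(sim$set, lib, redundancy = "nonredundant",
                      filtered = FALSE)
  fil <- annotate_set(sim$set, lib, redundancy = "nonredundant",
                      filtered = TRUE)
  expect_lte(nrow(fil$hits), nrow(unf$hits))
  tot_u <- unf$coverage$bp[unf$coverage$level == "total"]
  tot_f <- fil$coverage$bp[fil$coverage$level == "total"]
  expect_lte(tot_f, tot_u)
  # every category is no larger after filtering
  for (lev in c("class", "order", "superfamily", "family")) {
    f <- fil$coverage[fil$coverage$level == lev, ]
    u <- unf$coverage[unf$coverage$level == lev, ]
    for (nm in f$name) {
      expect_lte(f$bp[f$name == nm], sum(u$bp[u$name == nm]) + 1e-9)
    }
  }
})

test_that("homology annotation recovers planted family coverage", {
  sim <- small_sim()
  lib <- small_library()
  ann <- annotate_set(sim$set, lib, redundancy = "nonredundant",
                      filtered = TRUE)
  fam <- ann$coverage[ann$coverage$level == "family" &
                        ann$coverage$name == "famA", ]
  truth <- sim$truth[sim$truth$kind == "TE", ]
  truth_bp <- merged_coverage(truth[, c("seq_id", "start", "end")],
                              sim$set)
  expect_lt(abs(fam$bp - truth_bp) / truth_bp, 0.15)
  # class totals are sums over orders within the class
  cov <- ann$coverage
  expect_equal(sum(cov$bp[cov$level == "class"]),
               sum(cov$bp[cov$level == "order"]))
})

test_that("a library with nothing similar annotates nothing", {
  set.seed(44)
  set <- sequence_set(c(r = rand_dna(20000, 0.38)))
  lib <- repeat_library(c("x#I/LTR/Gypsy/x@y" = rand_dna(2000)))
  ann <- annotate_set(set, lib, filtered = TRUE)
  expect_equal(ann$coverage$bp[ann$coverage$level == "total"], 0)
  expect_error(annotate_set(set, repeat_library(character(0))), "empty")
})

test_that("gypsy_copia_ratio reproduces published superfamily arithmetic", {
  rep_df <- data.frame(
    level = c("superfamily", "superfamily", "total"),
    name = c("Gypsy", "Copia", "total"),
    bp = c(0, 0, 0), pct = c(11.97, 6.27, 27.50),
    stringsAsFactors = FALSE
  )
  expect_equal(gypsy_copia_ratio(rep_df), 1.9)
  rep_df$pct <- c(5, 5, 10)
  expect_equal(gypsy_copia_ratio(rep_df), 1.0)
  rep_df$pct <- c(5, 0, 5)
  expect_true(is.na(gypsy_copia_ratio(rep_df)))
})
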