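test_that("seed discovery finds the planted family and no more", {
  sim <- small_sim()
  seeds <- small_seeds()
  expect_gte(nrow(seeds), 1L)
  master <- sim$masters[["famA"]]
  ids <- vapply(seeds$consensus, function(s) {
    max(global_identity(s, master), global_identity(s, revcomp(master)))
  }, numeric(1))
  expect_gte(max(ids), 0.8)
  # every seed is either the element or one of its terminal repeats
  expect_true(all(nchar(seeds$consensus) >= 80))
})

test_that("a repeat-free random genome yields no self-alignment seeds", {
  for (seed in 1:10) {
    set.seed(seed)
    set <- sequence_set(c(a = rand_dna(30000, 0.38),
                          b = rand_dna(30000, 0.38)))
    seeds <- discover_seeds(set)
    expect_equal(nrow(seeds[seeds$method == "selfalign", ]), 0L,
                 info = paste("seed", seed))
  }
})

test_that("two unrelated families give separate seeds", {
  spec <- genome_spec(
    n_sequences = 2L, length_range = c(60000L, 70000L), gc = 0.38,
    seed = 61,
    families = list(
      family_spec("f1", "LTR", element_length = 2000L, ltr_length = 250L,
                  copy_number = 8L),
      family_spec("f2", "LTR", element_length = 1500L, ltr_length = 200L,
                  copy_number = 8L)
    )
  )
  sim <- simulate_genome(spec)
  seeds <- discover_seeds(sim$set)
  hit <- function(master) {
    any(vapply(seeds$consensus, function(s) {
      max(global_identity(s, master),
          global_identity(s, revcomp(master))) >= 0.8
    }, logical(1)))
  }
  expect_true(hit(sim$masters[["f1"]]))
  expect_true(hit(sim$masters[["f2"]]))
})

test_that("mapping recovers the planted copies as full-length instances", {
  sim <- small_sim()
  inst <- small_instances()
  truth <- sim$truth[sim$truth$kind == "TE", ]
  expect_equal(nrow(inst), nrow(truth))
  # every instance overlaps exactly one truth copy
  matched <- vapply(seq_len(nrow(inst)), function(i) {
    sum(truth$seq_id == inst$seq_id[i] & truth$start < inst$end[i] &
          truth$end > inst$start[i])
  }, numeric(1))
  expect_true(all(matched == 1))
  expect_true(all(inst$sim >= 0.8))
})

test_that("seeds matching nothing produce no instances", {
  sim <- small_sim()
  set.seed(62)
  fake <- data.frame(id = "seedX", consensus = rand_dna(1500),
                     n_support = 3L, method = "selfalign",
                     stringsAsFactors = FALSE)
  inst <- map_seeds(fake, sim$set)
  expect_equal(nrow(inst), 0L)
})

test_that("a half-truncated copy fails the reference-coverage clause", {
  set.seed(63)
  master <- rand_dna(2000)
  g <- paste0(rand_dna(5000, 0.38), master, rand_dna(4000, 0.38),
              substr(master, 1001, 2000), rand_dna(4000, 0.38))
  seeds <- data.frame(id = "s1", consensus = master, n_support = 3L,
                      method = "selfalign", stringsAsFactors = FALSE)
  inst <- map_seeds(seeds, sequence_set(c(g = g)))
  expect_equal(nrow(inst), 1L)  # only the full copy survives
  expect_equal(inst$start, 5000L)
})

test_that("greedy clustering honors the identity threshold deterministically", {
  ident <- strrep("ACGTTGCA", 40)
  five <- data.frame(
    instance_id = paste0("i", 1:5), seq_id = "s",
    start = seq(0, 4000, by = 1000), end = seq(320, 4320, by = 1000),
    strand = "+", seed_id = "s1", sim = 1,
    sequence = ident, stringsAsFactors = FALSE
  )
  cl <- cluster_instances(five)
  expect_length(cl, 1L)
  expect_equal(nrow(cl[[1]]$members), 5L)
  expect_equal(cl[[1]]$consensus, ident)

  set.seed(64)
  a <- rand_dna(500)
  b <- strsplit(a, "")[[1]]
  swap <- sample(500, 150)  # ~70% identity
  b[swap] <- vapply(b[swap], function(x) {
    sample(setdiff(c("A", "C", "G", "T"), x), 1)
  }, character(1))
  b <- paste(b, collapse = "")
  expect_lt(global_identity(a, b), 0.8)
  two <- data.frame(
    instance_id = c("i1", "i2"), seq_id = "s", start = c(0, 1000),
    end = c(500, 1500), strand = "+", seed_id = "s1", sim = 1,
    sequence = c(a, b), stringsAsFactors = FALSE
  )
  cl2 <- cluster_instances(two)
  expect_length(cl2, 2L)

  # deterministic under permutation of input rows (fixed sort order)
  cl3 <- cluster_instances(two[2:1, ])
  expect_equal(vapply(cl3, function(x) nrow(x$members), integer(1)),
               vapply(cl2, function(x) nrow(x$members), integer(1)))
})

test_that("cluster consensus is a majority vote anchored on the centroid", {
  base <- strrep("ACGTACGTAC", 30)
  v1 <- base
  v2 <- base
  substr(v2, 51, 51) <- "G"
  v3 <- base
  substr(v3, 51, 51) <- "G"
  cl <- list(centroid = "i1",
             members = data.frame(
               instance_id = c("i1", "i2", "i3"),
               sequence = c(v1, v2, v3), stringsAsFactors = FALSE
             ))
  cons <- cluster_consensus(cl)
  expect_equal(substr(cons, 51, 51), "G")   # 2-of-3 majority
  expect_equal(nchar(cons), nchar(base))

  single <- list(centroid = "i1",
                 members = data.frame(instance_id = "i1", sequence = v2,
                                      stringsAsFactors = FALSE))
  expect_equal(cluster_consensus(single), v2)
})

test_that("consensus of diverged members tracks the family master", {
  sim <- small_sim()
  clusters <- small_clusters()
  big <- clusters[[which.max(vapply(clusters, function(cl) {
    nrow(cl$members)
  }, integer(1)))]]
  master <- sim$masters[["famA"]]
  cons_id <- max(global_identity(big$consensus, master),
                 global_identity(big$consensus, revcomp(master)))
  member_ids <- vapply(big$members$sequence, function(s) {
    max(global_identity(s, master), global_identity(s, revcomp(master)))
  }, numeric(1))
  # majority voting reduces per-copy errors
  expect_gte(cons_id, max(member_ids) - 1e-9)
})

test_that("families merge clusters of one repeat and conserve coverage", {
  clusters <- small_clusters()
  fams <- build_families(clusters)
  # full-element clusters and terminal-repeat clusters of the same
  # family merge through the shorter-reference 80-80-80 rule
  main <- fams[[1]]
  expect_equal(main$copy_count,
               sum(vapply(main$clusters, function(cl) nrow(cl$members),
                          integer(1))))
  expect_equal(main$coverage_bp,
               sum(vapply(main$clusters, function(cl) {
                 sum(nchar(cl$members$sequence))
               }, numeric(1))))
  # partition property: each instance sits in exactly one cluster and
  # each cluster in exactly one family
  all_ids <- unlist(lapply(fams, function(f) {
    unlist(lapply(f$clusters, function(cl) cl$members$instance_id))
  }))
  expect_equal(sort(all_ids), sort(small_instances()$instance_id))
})

test_that("family_report reproduces published totals by summation", {
  tab <- data.frame(
    family = c("TPE1", "PtPiedmont", "IFG7", "PtOuachita", "Corky",
               "PtCumberland", "PtBastrop", "PtOzark", "PtAppalachian",
               "PtPineywoods", "PtAngelina", "Gymny", "PtConagree",
               "PtTalladega"),
    copies = c(159, 133, 162, 47, 78, 67, 38, 32, 67, 68, 24, 24, 50, 33),
    length_bp = c(1077598, 969109, 956018, 576871, 469286, 431492,
                  378631, 378020, 367653, 322632, 309248, 291479,
                  285850, 274826),
    stringsAsFactors = FALSE
  )
  rep <- family_report(tab, denominator_bp = 11858447 + 265480119)
  total <- rep[rep$family == "Total", ]
  expect_equal(total$copies, 982)
  expect_equal(total$length_bp, 7088713)
  expect_equal(total$pct_of_set, 2.56)
})

test_that("family_report on empty input is an all-zero table", {
  set <- sequence_set(c(s = strrep("A", 1000)))
  rep <- family_report(list(), set)
  expect_equal(rep$copies, 0L)
  expect_equal(rep$length_bp, 0)
})
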