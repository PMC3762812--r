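# De novo repeat family discovery: self-alignment seed discovery plus a
# structural LTR scan, re-mapping of seeds onto the reference to extract
# full-length instances, greedy identity clustering, consensus building,
# and all-vs-all family merging with coverage accounting.

#' Seed discovery parameters
#'
#' @param min_hsp_score minimum verified HSP score.
#' @param min_hsp_span minimum HSP span in bp.
#' @param min_support minimum verified HSPs per occurrence cluster.
#' @param recip_overlap reciprocal-overlap fraction for single-linkage
#'   clustering of HSP intervals.
#' @param k,max_occ,min_chain k-mer seeding parameters (see
#'   [seed_chains()]).
#' @param max_tandem_frac drop seeds whose consensus is mostly a tandem
#'   array (fraction of consensus covered by detected tandem repeats).
#' @param dedup_identity collapse seeds at this global identity before
#'   re-mapping.
#' @return a parameter list.
#' @export
seed_params <- function(min_hsp_score = 100, min_hsp_span = 80L,
                        min_support = 3L, recip_overlap = 0.8,
                        k = 12L, max_occ = 40L, min_chain = 4L,
                        max_tandem_frac = 0.5, dedup_identity = 0.8) {
  list(min_hsp_score = min_hsp_score, min_hsp_span = min_hsp_span,
       min_support = min_support, recip_overlap = recip_overlap,
       k = k, max_occ = max_occ, min_chain = min_chain,
       max_tandem_frac = max_tandem_frac, dedup_identity = dedup_identity)
}

# single-linkage clustering of intervals by reciprocal overlap
recip_cluster <- function(iv, frac) {
  n <- nrow(iv)
  if (n == 0L) return(integer(0))
  o <- order(iv$seq_id, iv$start)
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (a in seq_len(n - 1L)) {
    i <- o[a]
    for (b in (a + 1L):n) {
      j <- o[b]
      if (iv$seq_id[j] != iv$seq_id[i] || iv$start[j] >= iv$end[i]) break
      ov <- min(iv$end[i], iv$end[j]) - max(iv$start[i], iv$start[j])
      if (ov >= frac * (iv$end[i] - iv$start[i]) &&
            ov >= frac * (iv$end[j] - iv$start[j])) {
        parent[find(i)] <- find(j)
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

empty_seeds <- function() {
  data.frame(id = character(0), consensus = character(0),
             n_support = integer(0), method = character(0),
             stringsAsFactors = FALSE)
}

#' Discover repeat seeds by self-alignment and structural scanning
#'
#' All-vs-all self-alignment of the set (k-mer seeded, trivial
#' self-diagonal removed): chained candidate regions are single-linkage
#' clustered into occurrence loci by reciprocal overlap (intervals at
#' different loci never overlap, so clusters correspond to genomic
#' occurrences), each locus is supported by exact local alignments (HSPs
#' with score >= `min_hsp_score` and span >= `min_hsp_span`), and loci
#' with at least `min_support` verified HSPs qualify. Qualifying loci
#' linked by verified HSPs are grouped, and each group emits one
#' consensus seed (star alignment of the distinct member intervals of its
#' widest locus), which removes the redundancy of per-copy consensi
#' before re-mapping. A structural pass scans each sequence for direct
#' terminal-repeat pairs (>= 100 bp at >= 80% identity, 0.4-20 kbp
#' apart) away from qualifying loci and adds the spanned element as a
#' seed even at single-copy support. Seeds that are mostly tandem repeat
#' (SSR-like) are dropped, and near-duplicate seeds are collapsed at
#' `dedup_identity` global identity (either orientation).
#'
#' @param set a `SequenceSet`.
#' @param params a [seed_params()] list.
#' @param scoring alignment scoring.
#' @return a `data.frame` of seeds: `id`, `consensus`, `n_support`,
#'   `method` (`selfalign`/`structural`).
#' @export
discover_seeds <- function(set, params = seed_params(),
                           scoring = align_scoring()) {
  set <- as_sequence_set(set)
  seqs <- stats::setNames(as.character(set$records), names(set$records))
  chains <- seed_chains(seqs, seqs, k = params$k, max_occ = params$max_occ,
                        min_chain = params$min_chain, self = TRUE)
  seeds <- list()
  good_intervals <- NULL

  if (nrow(chains) > 0L) {
    C <- nrow(chains)
    slen <- nchar(seqs)[chains$sseq]
    s_lo <- ifelse(chains$strand == "-", slen - chains$shi, chains$slo)
    s_hi <- ifelse(chains$strand == "-", slen - chains$slo, chains$shi)
    occ <- data.frame(
      seq_id = c(chains$qseq, chains$sseq),
      start = c(chains$qlo, s_lo), end = c(chains$qhi, s_hi),
      chain = rep(seq_len(C), 2L), stringsAsFactors = FALSE
    )
    occ$cluster <- recip_cluster(occ, params$recip_overlap)
    qcl <- occ$cluster[seq_len(C)]
    scl <- occ$cluster[C + seq_len(C)]

    chain_ok <- rep(NA, C)
    verify <- function(ci) {
      if (!is.na(chain_ok[ci])) return(chain_ok[ci])
      h <- align_chain(chains[ci, ], seqs, seqs, scoring = scoring,
                       min_score = params$min_hsp_score)
      ok <- nrow(h) > 0L &&
        min(h$qend[1L] - h$qstart[1L], h$send[1L] - h$sstart[1L] + 1L) >=
          params$min_hsp_span
      chain_ok[ci] <<- ok
      ok
    }
    n_cl <- max(occ$cluster)
    support <- integer(n_cl)
    for (cl in seq_len(n_cl)) {
      cands <- unique(occ$chain[occ$cluster == cl])
      cands <- cands[order(-chains$n_kmers[cands])]
      for (ci in cands) {
        if (verify(ci)) support[cl] <- support[cl] + 1L
        if (support[cl] >= params$min_support) break
      }
    }
    good <- which(support >= params$min_support)

    if (length(good)) {
      good_intervals <- occ[occ$cluster %in% good, , drop = FALSE]
      # group qualifying loci linked by verified HSPs; one seed per group
      idx <- match(seq_len(n_cl), good)
      g <- igraph::make_empty_graph(length(good), directed = FALSE)
      ec <- which(chain_ok %in% TRUE & !is.na(idx[qcl]) & !is.na(idx[scl]))
      if (length(ec)) {
        g <- igraph::add_edges(g, rbind(idx[qcl[ec]], idx[scl[ec]]))
      }
      comp <- igraph::components(g)$membership
      for (f in unique(comp)) {
        cls <- good[comp == f]
        rows <- occ[occ$cluster %in% cls, , drop = FALSE]
        # widest locus in the group hosts the consensus
        widths <- vapply(cls, function(cl) {
          r <- occ[occ$cluster == cl, , drop = FALSE]
          max(r$end - r$start)
        }, numeric(1))
        rep_rows <- occ[occ$cluster == cls[which.max(widths)], ,
                        drop = FALSE]
        dd <- rep_rows[order(-(rep_rows$end - rep_rows$start)), ,
                       drop = FALSE]
        keep <- rep(TRUE, nrow(dd))
        for (i in seq_len(nrow(dd))) {
          if (!keep[i] || i == nrow(dd)) next
          j <- which(keep & seq_len(nrow(dd)) > i)
          ov <- pmax(0L, pmin(dd$end[j], dd$end[i]) -
                       pmax(dd$start[j], dd$start[i]))
          keep[j[ov >= 0.5 * (dd$end[j] - dd$start[j])]] <- FALSE
        }
        dd <- dd[keep, , drop = FALSE][seq_len(min(8L, sum(keep))), ,
                                       drop = FALSE]
        members <- substr(seqs[dd$seq_id], dd$start + 1L, dd$end)
        cons <- if (length(members) == 1L) members[[1L]] else
          star_consensus(members, centroid = 1L, scoring = scoring)
        seeds[[length(seeds) + 1L]] <- data.frame(
          consensus = cons,
          n_support = sum(chain_ok %in% TRUE &
                            (qcl %in% cls | scl %in% cls)),
          method = "selfalign",
          src_seq = dd$seq_id[1L], src_start = dd$start[1L],
          src_end = dd$end[1L], stringsAsFactors = FALSE
        )
      }
    }

    # structural pass: direct repeats (candidate LTR pairs) 0.4-20 kbp
    # apart within one sequence, outside already-qualified loci
    str_cand <- chains[chains$qseq == chains$sseq & chains$strand == "+" &
                         chains$qhi - chains$qlo <= 2500L &
                         chains$slo - chains$qhi > 100L &
                         chains$slo - chains$qlo >= 400L &
                         chains$slo - chains$qlo <= 20000L, , drop = FALSE]
    if (nrow(str_cand) && !is.null(good_intervals)) {
      # a repeat end lying inside an already-qualified locus is part of a
      # multi-copy repeat, not a single-copy structural element
      end_covered <- function(lo, hi, sid) {
        gi <- good_intervals[good_intervals$seq_id == sid, , drop = FALSE]
        if (nrow(gi) == 0L) return(FALSE)
        ov <- pmax(0L, pmin(gi$end, hi) - pmax(gi$start, lo))
        any(ov >= 0.5 * (hi - lo))
      }
      covered <- vapply(seq_len(nrow(str_cand)), function(i) {
        end_covered(str_cand$qlo[i], str_cand$qhi[i], str_cand$qseq[i]) ||
          end_covered(str_cand$slo[i], str_cand$shi[i], str_cand$qseq[i])
      }, logical(1))
      str_cand <- str_cand[!covered, , drop = FALSE]
    }
    if (nrow(str_cand)) {
      # dedupe candidate element spans
      o <- order(-str_cand$n_kmers)
      str_cand <- str_cand[o, , drop = FALSE]
      keep <- rep(TRUE, nrow(str_cand))
      for (i in seq_len(nrow(str_cand))) {
        if (!keep[i] || i == nrow(str_cand)) next
        j <- which(keep & seq_len(nrow(str_cand)) > i &
                     str_cand$qseq == str_cand$qseq[i])
        ov <- pmax(0L, pmin(str_cand$shi[j], str_cand$shi[i]) -
                     pmax(str_cand$qlo[j], str_cand$qlo[i]))
        keep[j[ov >= 0.5 * (str_cand$shi[j] - str_cand$qlo[j])]] <- FALSE
      }
      str_cand <- str_cand[keep, , drop = FALSE]
      for (i in seq_len(nrow(str_cand))) {
        ch <- str_cand[i, ]
        h <- align_chain(ch, seqs, seqs, scoring = scoring, min_score = 50)
        if (nrow(h) == 0L) next
        ident <- h$match_count[1L] / h$alignment_length[1L]
        span <- min(h$qend[1L] - h$qstart[1L],
                    h$send[1L] - h$sstart[1L] + 1L)
        if (ident < 0.8 || span < 100L) next
        if (h$qend[1L] >= h$sstart[1L] - 1L) next # repeats must be disjoint
        elem <- substr(seqs[[ch$qseq]], h$qstart[1L] + 1L, h$send[1L])
        if (nchar(elem) < 400L) next
        seeds[[length(seeds) + 1L]] <- data.frame(
          consensus = elem, n_support = 1L, method = "structural",
          src_seq = ch$qseq, src_start = h$qstart[1L],
          src_end = h$send[1L], stringsAsFactors = FALSE
        )
      }
    }
  }

  if (length(seeds) == 0L) return(empty_seeds())
  seeds <- do.call(rbind, seeds)
  seeds <- seeds[nchar(seeds$consensus) >= 80L, , drop = FALSE]
  if (nrow(seeds) == 0L) return(empty_seeds())

  # drop SSR-like seeds: a seed whose source locus sits mostly inside a
  # tandem array is a fragment of that array, not an interspersed repeat.
  # The neighbourhood (not just the seed) is tested because one unit of a
  # long-period satellite is not tandem by itself.
  keep <- vapply(seq_len(nrow(seeds)), function(i) {
    s <- seqs[[seeds$src_seq[i]]]
    lo <- max(0L, seeds$src_start[i] - 600L)
    hi <- min(nchar(s), seeds$src_end[i] + 600L)
    win <- substr(s, lo + 1L, hi)
    arr <- detect_tandem(stats::setNames(win, "w"))
    if (nrow(arr) == 0L) return(TRUE)
    a <- seeds$src_start[i] - lo
    b <- seeds$src_end[i] - lo
    ov <- sum(pmax(0L, pmin(arr$end, b) - pmax(arr$start, a)))
    ov / (b - a) <= params$max_tandem_frac
  }, logical(1))
  seeds <- seeds[keep, , drop = FALSE]
  if (nrow(seeds) == 0L) return(empty_seeds())

  # collapse near-duplicate seeds (k-mer prescreen, then banded identity)
  seeds <- seeds[order(-nchar(seeds$consensus)), , drop = FALSE]
  ksets_f <- lapply(seeds$consensus, kmer_set)
  ksets_r <- lapply(seeds$consensus, function(s) kmer_set(revcomp(s)))
  keep <- rep(TRUE, nrow(seeds))
  for (i in seq_len(nrow(seeds))) {
    if (!keep[i]) next
    for (jj in which(keep & seq_len(nrow(seeds)) > i)) {
      cf <- kmer_containment(ksets_f[[jj]], ksets_f[[i]])
      cr <- kmer_containment(ksets_f[[jj]], ksets_r[[i]])
      if (max(cf, cr) < 0.03) next
      target <- if (cf >= cr) seeds$consensus[i] else
        revcomp(seeds$consensus[i])
      if (global_identity(seeds$consensus[jj], target, scoring) >=
            params$dedup_identity) {
        keep[jj] <- FALSE
      }
    }
  }
  seeds <- seeds[keep, , drop = FALSE]
  seeds$id <- sprintf("seed%03d", seq_len(nrow(seeds)))
  rownames(seeds) <- NULL
  seeds[, c("id", "consensus", "n_support", "method")]
}

#' Map seeds back to the reference and extract full-length instances
#'
#' The seeds are used as the library for a non-redundant homology search
#' against the set; hits surviving the full-length [full_length_filter()]
#' (seed as the reference) become instances, with the genomic sequence
#' extracted (reverse-complemented for minus-strand hits so instances are
#' in seed orientation).
#'
#' @param seeds a seed `data.frame` from [discover_seeds()].
#' @param set the `SequenceSet`.
#' @param params [filter_params()].
#' @param scoring alignment scoring.
#' @return a `data.frame` of instances: `instance_id`, `seq_id`, `start`,
#'   `end`, `strand`, `seed_id`, `sim`, `sequence`.
#' @export
map_seeds <- function(seeds, set, params = filter_params(),
                      scoring = align_scoring()) {
  set <- as_sequence_set(set)
  empty <- data.frame(
    instance_id = character(0), seq_id = character(0), start = integer(0),
    end = integer(0), strand = character(0), seed_id = character(0),
    sim = numeric(0), sequence = character(0), stringsAsFactors = FALSE
  )
  if (nrow(seeds) == 0L) return(empty)
  lib <- repeat_library(stats::setNames(seeds$consensus, seeds$id))
  ann <- annotate_set(set, lib, params = params,
                      redundancy = "nonredundant", filtered = TRUE,
                      scoring = scoring)
  hits <- ann$hits
  if (nrow(hits) == 0L) return(empty)
  seqs <- stats::setNames(as.character(set$records), names(set$records))
  seqtxt <- substr(seqs[hits$query_id], hits$qstart + 1L, hits$qend)
  seqtxt <- ifelse(hits$strand == "-", revcomp(seqtxt), seqtxt)
  data.frame(
    instance_id = sprintf("inst%04d", seq_len(nrow(hits))),
    seq_id = hits$query_id, start = hits$qstart, end = hits$qend,
    strand = hits$strand, seed_id = hits$subject_name, sim = hits$sim,
    sequence = unname(seqtxt), stringsAsFactors = FALSE
  )
}

#' Greedy centroid clustering of instances at an identity threshold
#'
#' Instances are sorted by length descending (ties by position) and each
#' joins the first existing centroid with global identity (matches over
#' alignment columns of a Needleman-Wunsch alignment, end gaps penalized)
#' at or above the threshold, else founds a new cluster. The fixed sort
#' order makes the output deterministic; it is not order-independent.
#' A shared k-mer prescreen skips centroids that cannot reach the
#' threshold.
#'
#' @param instances instance `data.frame` from [map_seeds()].
#' @param id_threshold identity threshold.
#' @param scoring alignment scoring.
#' @return a list of `RepeatCluster` lists: `id`, `centroid`
#'   (instance_id), `members` (instance `data.frame`), `consensus`.
#' @export
cluster_instances <- function(instances, id_threshold = 0.80,
                              scoring = align_scoring()) {
  if (nrow(instances) == 0L) return(list())
  o <- order(-nchar(instances$sequence), instances$seq_id, instances$start)
  instances <- instances[o, , drop = FALSE]
  ksets <- lapply(instances$sequence, kmer_set)
  centroids <- integer(0)
  assign <- integer(nrow(instances))
  for (i in seq_len(nrow(instances))) {
    placed <- FALSE
    for (ci in seq_along(centroids)) {
      if (kmer_containment(ksets[[i]], ksets[[centroids[ci]]]) < 0.03) next
      idn <- global_identity(instances$sequence[i],
                             instances$sequence[centroids[ci]], scoring)
      if (idn >= id_threshold) {
        assign[i] <- ci
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      centroids <- c(centroids, i)
      assign[i] <- length(centroids)
    }
  }
  lapply(seq_along(centroids), function(ci) {
    members <- instances[assign == ci, , drop = FALSE]
    cl <- list(
      id = sprintf("cluster%03d", ci),
      centroid = instances$instance_id[centroids[ci]],
      members = members,
      consensus = NA_character_
    )
    cl$consensus <- cluster_consensus(cl, scoring)
    cl
  })
}

# star multiple alignment projected onto the centroid: per centroid
# column, majority over member residues and gaps; ties go to the centroid
# residue; gap-majority columns are dropped
star_consensus <- function(seqs, centroid = 1L,
                           scoring = align_scoring()) {
  cent <- seqs[[centroid]]
  L <- nchar(cent)
  cent_chars <- strsplit(cent, "", fixed = TRUE)[[1L]]
  if (length(seqs) == 1L) return(cent)
  prof <- matrix("-", nrow = length(seqs), ncol = L)
  prof[centroid, ] <- cent_chars
  for (i in seq_along(seqs)) {
    if (i == centroid) next
    res <- band_global(seqs[[i]], cent, scoring)
    mem <- strsplit(seqs[[i]], "", fixed = TRUE)[[1L]]
    row <- rep("-", L)
    sel <- res$ops == 0L
    spos <- cumsum(res$ops != 1L)  # centroid position per op
    qpos <- cumsum(res$ops != 2L)  # member position per op
    row[spos[sel]] <- mem[qpos[sel]]
    prof[i, ] <- row
  }
  cons <- majority_consensus(prof, prefer = cent_chars)
  paste(cons[cons != "-"], collapse = "")
}

#' Consensus sequence of a cluster
#'
#' Star multiple alignment: every member is globally aligned to the
#' centroid, per-column majority over A/C/G/T/gap is taken (ties resolved
#' to the centroid's residue) and gap-majority columns are dropped.
#'
#' @param cluster a `RepeatCluster` list.
#' @param scoring alignment scoring.
#' @return the consensus sequence (character).
#' @export
cluster_consensus <- function(cluster, scoring = align_scoring()) {
  members <- cluster$members
  ci <- which(members$instance_id == cluster$centroid)
  star_consensus(members$sequence, centroid = ci, scoring = scoring)
}

#' Merge clusters into repeat families by all-vs-all consensus alignment
#'
#' Cluster consensi are locally aligned all against all; two clusters are
#' connected when the best hit satisfies the 80-80-80 filter with the
#' shorter consensus as the reference. Connected components become
#' families. Family coverage is the summed length of all full-length
#' member sequences across the family's clusters, and the representative
#' cluster is the one with the most members (ties: longer consensus).
#'
#' @param clusters list of clusters from [cluster_instances()].
#' @param params [filter_params()].
#' @param scoring alignment scoring.
#' @param library optional `RepeatLibrary`: a family whose representative
#'   consensus gets a full-length nucleotide hit to a classified entry is
#'   named after that entry, mirroring the mixing of known and novel
#'   family names; others get stable generated names.
#' @return a list of `RepeatFamily` lists: `name`, `clusters`,
#'   `representative`, `copy_count`, `coverage_bp`, and (with a library)
#'   `classification`.
#' @export
build_families <- function(clusters, params = filter_params(),
                           scoring = align_scoring(), library = NULL) {
  n <- length(clusters)
  if (n == 0L) return(list())
  edges <- matrix(integer(0), ncol = 2L)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        ci <- clusters[[i]]$consensus
        cj <- clusters[[j]]$consensus
        if (nchar(ci) <= nchar(cj)) {
          q <- cj
          s <- ci
        } else {
          q <- ci
          s <- cj
        }
        hits <- local_align(q, s, scoring = scoring, min_score = 50,
                            max_hits = 3L)
        hits$subject_len <- rep(nchar(s), nrow(hits))
        hits <- full_length_filter(hits, params = params)
        if (nrow(hits) > 0L) edges <- rbind(edges, c(i, j))
      }
    }
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(edges) > 0L) g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)$membership
  fams <- lapply(unique(comp), function(f) {
    idx <- which(comp == f)
    cls <- clusters[idx]
    sizes <- vapply(cls, function(cl) nrow(cl$members), integer(1))
    conslen <- vapply(cls, function(cl) nchar(cl$consensus), integer(1))
    rep_i <- order(-sizes, -conslen)[1L]
    members_bp <- sum(vapply(cls, function(cl) {
      sum(nchar(cl$members$sequence))
    }, numeric(1)))
    list(
      name = NA_character_, clusters = cls,
      representative = cls[[rep_i]]$id,
      copy_count = sum(sizes), coverage_bp = members_bp
    )
  })
  fams <- fams[order(-vapply(fams, `[[`, numeric(1), "coverage_bp"))]
  for (i in seq_along(fams)) {
    nm <- sprintf("FAM%04d", i)
    if (!is.null(library)) {
      rep_id <- fams[[i]]$representative
      rep_cl <- fams[[i]]$clusters[[
        which(vapply(fams[[i]]$clusters, `[[`, character(1), "id") ==
                rep_id)
      ]]
      cls <- classify_repeat(rep_cl$consensus, library, params = params,
                             scoring = scoring)
      if (!is.na(cls$family)) nm <- cls$family
      fams[[i]]$classification <- cls
    }
    fams[[i]]$name <- nm
  }
  fams
}

#' Family coverage report
#'
#' One row per family with full-length copy count, summed member length
#' and percent of the sequence set, sorted by coverage, plus a totals row
#' computed by summation.
#'
#' @param families list from [build_families()], or a `data.frame` with
#'   `family`, `copies`, `length_bp` columns (e.g. an externally tabulated
#'   family table).
#' @param set the `SequenceSet`.
#' @param denominator_bp optional non-N set length for the percentage
#'   column instead of measuring `set`.
#' @return a `data.frame` with columns `family`, `copies`, `length_bp`,
#'   `pct_of_set`.
#' @export
family_report <- function(families, set = NULL, denominator_bp = NULL) {
  denom <- denominator_bp %||% summarize_set(as_sequence_set(set))$total_len
  if (is.data.frame(families)) {
    df <- families[, c("family", "copies", "length_bp")]
    df <- df[order(-df$length_bp), , drop = FALSE]
    total <- data.frame(family = "Total", copies = sum(df$copies),
                        length_bp = sum(df$length_bp),
                        stringsAsFactors = FALSE)
    out <- rbind(df, total)
    out$pct_of_set <- round(100 * out$length_bp / denom, 2L)
    rownames(out) <- NULL
    return(out)
  }
  if (length(families) == 0L) {
    return(data.frame(family = "Total", copies = 0L, length_bp = 0,
                      pct_of_set = 0, stringsAsFactors = FALSE))
  }
  df <- data.frame(
    family = vapply(families, `[[`, character(1), "name"),
    copies = vapply(families, `[[`, numeric(1), "copy_count"),
    length_bp = vapply(families, `[[`, numeric(1), "coverage_bp"),
    stringsAsFactors = FALSE
  )
  df <- df[order(-df$length_bp), , drop = FALSE]
  total <- data.frame(family = "Total", copies = sum(df$copies),
                      length_bp = sum(df$length_bp),
                      stringsAsFactors = FALSE)
  out <- rbind(df, total)
  out$pct_of_set <- round(100 * out$length_bp / denom, 2L)
  rownames(out) <- NULL
  out
}
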