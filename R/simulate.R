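# Synthetic genomes with planted repeat families and tandem arrays, plus an
# exact ground-truth table. The generator emulates the statistical structure
# the downstream analysis assumes: multi-copy interspersed families diverged
# by per-site substitutions and indels, LTR/TIR/LINE-like element anatomy
# (terminal repeats, PBS, PPT, poly-A tails), optional nesting, and tandem
# arrays spanning the micro/mini/satellite period range, all on an i.i.d.
# background with configurable GC. All randomness goes through R's RNG, so
# a fixed seed reproduces the genome byte for byte.

# fixed tRNA 3'-end 18-mer fixture used for PBS planting and detection
# (synthetic stand-in for a host tRNA database; ends in the canonical CCA)
TRNA_3PRIME_18MER <- "TGGCGCAGTCAGGTACCA"

#' The tRNA 3'-end fixture used for PBS planting and detection
#'
#' A fixed synthetic 18-mer standing in for a host tRNA database; the primer
#' binding site planted in LTR elements is its reverse complement. A custom
#' 3'-end can be supplied to the detection functions instead.
#'
#' @return an 18 bp character string.
#' @export
trna_3prime <- function() TRNA_3PRIME_18MER

#' Specification of a planted interspersed repeat family
#'
#' @param name family name (appears in the ground truth).
#' @param order element order: `"LTR"` (direct long terminal repeats, PBS
#'   and PPT), `"TIR"` (terminal inverted repeats) or `"LINE"` (poly-A
#'   tail, optional 5' truncation).
#' @param element_length full element length in bp.
#' @param ltr_length terminal repeat length (LTR/TIR only; must be less
#'   than half the element length).
#' @param copy_number number of planted copies.
#' @param sub_rate per-site substitution probability per copy.
#' @param indel_rate per-site indel-opening probability per copy
#'   (geometric lengths, mean 3).
#' @param nest_prob probability that a copy is inserted inside a
#'   previously planted copy rather than in background sequence.
#' @param truncation_prob probability that a copy is 5'-truncated.
#' @return a `FamilySpec` list.
#' @export
family_spec <- function(name, order = c("LTR", "TIR", "LINE"),
                        element_length = 3000L, ltr_length = 400L,
                        copy_number = 10L, sub_rate = 0.05,
                        indel_rate = 0.005, nest_prob = 0,
                        truncation_prob = 0) {
  order <- match.arg(order)
  rates <- c(sub_rate, indel_rate, nest_prob, truncation_prob)
  if (any(rates < 0) || any(c(sub_rate, indel_rate) > 0.5)) {
    stop("rates must be in [0, 0.5]")
  }
  if (order %in% c("LTR", "TIR") && ltr_length >= element_length / 2) {
    stop("ltr_length must be < element_length / 2")
  }
  if (copy_number < 1L) stop("copy_number must be >= 1")
  structure(list(
    name = name, order = order, element_length = as.integer(element_length),
    ltr_length = as.integer(ltr_length), copy_number = as.integer(copy_number),
    sub_rate = sub_rate, indel_rate = indel_rate, nest_prob = nest_prob,
    truncation_prob = truncation_prob
  ), class = "FamilySpec")
}

#' Specification of a planted tandem array
#'
#' @param motif repeat unit (2-500 bp, A/C/G/T).
#' @param copies copy number (>= 1.8; fractional allowed).
#' @param sub_rate per-site divergence within the array.
#' @return a `TandemSpec` list.
#' @export
tandem_spec <- function(motif, copies, sub_rate = 0.02) {
  motif <- toupper(motif)
  if (nchar(motif) < 2L || nchar(motif) > 500L) {
    stop("motif length must be in [2, 500]")
  }
  if (grepl("[^ACGT]", motif)) stop("motif must be over A/C/G/T")
  if (copies < 1.8) stop("copies must be >= 1.8")
  structure(list(motif = motif, copies = copies, sub_rate = sub_rate),
            class = "TandemSpec")
}

#' Specification of a synthetic genome
#'
#' @param n_sequences number of background sequences.
#' @param length_range either a `c(min, max)` range or a vector of exact
#'   lengths (one per sequence).
#' @param gc background GC fraction.
#' @param seed RNG seed (`NULL` to use the current RNG state).
#' @param families list of [family_spec()] objects.
#' @param tandems list of [tandem_spec()] objects.
#' @return a `GenomeSpec` list.
#' @export
genome_spec <- function(n_sequences = 3L, length_range = c(150000L, 250000L),
                        gc = 0.38, seed = NULL, families = list(),
                        tandems = list()) {
  stopifnot(n_sequences >= 1L, gc > 0, gc < 1)
  structure(list(
    n_sequences = as.integer(n_sequences), length_range = length_range,
    gc = gc, seed = seed, families = families, tandems = tandems
  ), class = "GenomeSpec")
}

#' Build the master (undiverged) sequence of a repeat family
#'
#' LTR elements get identical direct terminal repeats, an 18 bp primer
#' binding site (reverse complement of the tRNA 3'-end fixture) directly
#' interior to the 5' LTR, and a 12 bp polypurine tract directly interior
#' to the 3' LTR. TIR elements get reverse-complementary terminal repeats.
#' LINE-like elements end in a 12 bp poly-A tail.
#'
#' @param spec a [family_spec()].
#' @param gc GC fraction of the random portions.
#' @return the master sequence (character).
#' @export
build_master_element <- function(spec, gc = 0.5) {
  L <- spec$element_length
  if (spec$order == "LINE") {
    return(paste0(random_dna(L - 12L, gc), strrep("A", 12L)))
  }
  ltr <- random_dna(spec$ltr_length, gc)
  if (spec$order == "TIR") {
    internal <- random_dna(L - 2L * spec$ltr_length, gc)
    return(paste0(ltr, internal, revcomp(ltr)))
  }
  pbs <- revcomp(TRNA_3PRIME_18MER)
  ppt <- paste(sample(c("A", "G"), 12L, replace = TRUE), collapse = "")
  internal_len <- L - 2L * spec$ltr_length - nchar(pbs) - nchar(ppt)
  if (internal_len < 0L) stop("element too short for its LTRs")
  paste0(ltr, pbs, random_dna(internal_len, gc), ppt, ltr)
}

#' Mutate a copy of a master sequence
#'
#' Independent per-site substitution to a uniformly chosen different base;
#' indels open with probability `indel_rate` per site with geometric
#' lengths (mean 3), insertions and deletions equally likely. The realized
#' identity (matches over alignment columns of the generating edit script)
#' is returned with the sequence.
#'
#' @param master master sequence (character).
#' @param sub_rate per-site substitution probability.
#' @param indel_rate per-site indel-opening probability.
#' @return `list(seq =, identity =)`.
#' @export
mutate_copy <- function(master, sub_rate, indel_rate) {
  b <- strsplit(master, "", fixed = TRUE)[[1L]]
  n <- length(b)
  sub_at <- runif(n) < sub_rate
  if (any(sub_at)) {
    b[sub_at] <- vapply(b[sub_at], function(x) {
      sample(setdiff(DNA_BASES, x), 1L)
    }, character(1), USE.NAMES = FALSE)
  }
  n_ins <- 0L
  n_del <- 0L
  if (indel_rate > 0) {
    open_at <- which(runif(n) < indel_rate)
    del_mask <- rep(FALSE, n)
    ins_after <- rep("", n + 1L)
    for (i in open_at) {
      len <- rgeom(1L, 1 / 3) + 1L
      if (runif(1L) < 0.5) {
        j <- i:min(n, i + len - 1L)
        n_del <- n_del + sum(!del_mask[j])
        del_mask[j] <- TRUE
      } else {
        ins_after[i] <- paste0(ins_after[i], random_dna(len, 0.5))
        n_ins <- n_ins + len
      }
    }
    out <- character(2L * n + 1L)
    out[seq(2L, 2L * n, by = 2L)] <- ifelse(del_mask, "", b)
    out[seq(1L, 2L * n + 1L, by = 2L)] <- ins_after
    seqc <- paste(out, collapse = "")
  } else {
    del_mask <- rep(FALSE, n)
    seqc <- paste(b, collapse = "")
  }
  matches <- sum(!sub_at & !del_mask)
  identity <- matches / (n + n_ins)
  list(seq = seqc, identity = identity)
}

# build a diverged tandem array sequence of ~copies * period bp
build_tandem_array <- function(spec) {
  total <- as.integer(round(spec$copies * nchar(spec$motif)))
  full <- strrep(spec$motif, ceiling(spec$copies))
  arr <- substr(full, 1L, total)
  b <- strsplit(arr, "", fixed = TRUE)[[1L]]
  sub_at <- runif(length(b)) < spec$sub_rate
  if (any(sub_at)) {
    b[sub_at] <- vapply(b[sub_at], function(x) {
      sample(setdiff(DNA_BASES, x), 1L)
    }, character(1), USE.NAMES = FALSE)
  }
  list(seq = paste(b, collapse = ""), identity = mean(!sub_at))
}

#' Simulate a genome with planted repeats and exact ground truth
#'
#' Background sequence is i.i.d. with the target GC. Family copies and
#' tandem arrays are inserted at uniform positions that avoid the interior
#' of previously planted features, except nested insertions (with
#' per-family probability `nest_prob`), which are placed inside a
#' previously planted copy of the same family set; the host's truth row
#' then spans the insertion and is flagged `nested`. Fixing `spec$seed`
#' makes the output deterministic.
#'
#' @param spec a [genome_spec()].
#' @return a `RepeatSimulation` list with elements `set` (the
#'   [sequence_set()]), `truth` (ground-truth `data.frame` with `seq_id`,
#'   `start`, `end`, `kind`, `name`, `strand`, `full_length`, `identity`,
#'   `nested`), `masters` (named character vector) and `spec`.
#' @export
simulate_genome <- function(spec) {
  if (!is.null(spec$seed)) set.seed(spec$seed)
  lens <- if (length(spec$length_range) == 2L &&
                length(spec$length_range) != spec$n_sequences) {
    as.integer(round(runif(spec$n_sequences, spec$length_range[1L],
                           spec$length_range[2L])))
  } else {
    as.integer(rep_len(spec$length_range, spec$n_sequences))
  }
  ids <- sprintf("seq%02d", seq_len(spec$n_sequences))
  seqs <- vapply(lens, random_dna, character(1), gc = spec$gc)
  names(seqs) <- ids

  masters <- character(0)
  pieces <- list()  # feature sequences to plant
  for (fam in spec$families) {
    master <- build_master_element(fam, gc = spec$gc)
    masters[fam$name] <- master
    for (i in seq_len(fam$copy_number)) {
      mc <- mutate_copy(master, fam$sub_rate, fam$indel_rate)
      full <- TRUE
      if (runif(1L) < fam$truncation_prob) {
        keep <- runif(1L, 0.3, 0.7)
        mc$seq <- substr(mc$seq, nchar(mc$seq) - round(keep * nchar(mc$seq)),
                         nchar(mc$seq))
        full <- FALSE
      }
      pieces[[length(pieces) + 1L]] <- list(
        kind = "TE", name = fam$name, seq = mc$seq, identity = mc$identity,
        full_length = full, nest_prob = fam$nest_prob
      )
    }
  }
  for (td in spec$tandems) {
    arr <- build_tandem_array(td)
    pieces[[length(pieces) + 1L]] <- list(
      kind = "tandem", name = td$motif, seq = arr$seq,
      identity = arr$identity, full_length = TRUE, nest_prob = 0
    )
  }
  planted_bp <- sum(vapply(pieces, function(p) nchar(p$seq), numeric(1)))
  if (planted_bp > sum(lens)) {
    stop("planted content (", planted_bp,
         " bp) exceeds background capacity (", sum(lens), " bp)")
  }

  truth <- data.frame(
    seq_id = character(0), start = integer(0), end = integer(0),
    kind = character(0), name = character(0), strand = character(0),
    full_length = logical(0), identity = numeric(0), nested = logical(0),
    stringsAsFactors = FALSE
  )
  for (p in pieces) {
    strand <- if (p$kind == "TE") sample(c("+", "-"), 1L) else "+"
    ins <- if (strand == "-") revcomp(p$seq) else p$seq
    L <- nchar(ins)
    tgt_host <- NULL
    te_rows <- which(truth$kind == "TE" & !truth$nested)
    if (p$nest_prob > 0 && length(te_rows) && runif(1L) < p$nest_prob) {
      tgt_host <- sample(te_rows, 1L)
    }
    if (!is.null(tgt_host)) {
      h <- truth[tgt_host, ]
      pos <- as.integer(round(runif(1L, h$start + 20L, h$end - 20L)))
      sid <- h$seq_id
    } else {
      # uniform position avoiding feature interiors
      sid <- sample(ids, 1L, prob = nchar(seqs))
      for (try in 1:1000) {
        pos <- as.integer(floor(runif(1L, 0, nchar(seqs[[sid]]) + 1)))
        inside <- truth$seq_id == sid & truth$start < pos & pos < truth$end
        if (!any(inside)) break
        if (try == 1000L) stop("could not place feature outside features")
      }
    }
    # insert and shift existing annotations
    seqs[[sid]] <- paste0(substr(seqs[[sid]], 1L, pos), ins,
                          substr(seqs[[sid]], pos + 1L, nchar(seqs[[sid]])))
    on_seq <- truth$seq_id == sid
    shift <- on_seq & truth$start >= pos
    truth$start[shift] <- truth$start[shift] + L
    truth$end[shift] <- truth$end[shift] + L
    span <- on_seq & truth$start < pos & truth$end > pos
    truth$end[span] <- truth$end[span] + L
    if (!is.null(tgt_host)) truth$nested[tgt_host] <- TRUE
    truth <- rbind(truth, data.frame(
      seq_id = sid, start = pos, end = pos + L, kind = p$kind,
      name = p$name, strand = strand, full_length = p$full_length,
      identity = p$identity, nested = FALSE, stringsAsFactors = FALSE
    ))
  }
  truth <- truth[order(truth$seq_id, truth$start), , drop = FALSE]
  rownames(truth) <- NULL
  structure(list(
    set = sequence_set(seqs, label = "simulated"),
    truth = truth, masters = masters, spec = spec
  ), class = "RepeatSimulation")
}

#' Write a simulation to disk
#'
#' Writes the genome FASTA, the ground truth as a tab-separated table and
#' as BED, and (when the `yaml` package is available) the generating spec
#' as a YAML config.
#'
#' @param sim a `RepeatSimulation`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(sim$set, file.path(dir, "genome.fa"))
  utils::write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  ann <- annotation_table(
    seq_id = sim$truth$seq_id, start = sim$truth$start, end = sim$truth$end,
    strand = sim$truth$strand,
    category = paste(sim$truth$kind, sim$truth$name, sep = ":"),
    score = round(1000 * sim$truth$identity)
  )
  write_bed(ann, sim$set, file.path(dir, "truth.bed"))
  if (length(sim$masters)) {
    write_fasta(sim$masters, file.path(dir, "masters.fa"))
  }
  if (requireNamespace("yaml", quietly = TRUE)) {
    cfg <- sim$spec
    cfg$families <- lapply(cfg$families, unclass)
    cfg$tandems <- lapply(cfg$tandems, unclass)
    yaml::write_yaml(unclass(cfg), file.path(dir, "config.yml"))
  }
  invisible(dir)
}

#' Read a genome spec from a YAML config file
#'
#' The config uses exactly the [family_spec()] / [tandem_spec()] /
#' [genome_spec()] field names.
#'
#' @param path path to a YAML file.
#' @return a `GenomeSpec`.
#' @export
read_genome_spec <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the yaml package is required to read config files")
  }
  cfg <- yaml::read_yaml(path)
  fams <- lapply(cfg$families, function(f) do.call(family_spec, f))
  tds <- lapply(cfg$tandems, function(t) do.call(tandem_spec, t))
  genome_spec(
    n_sequences = cfg$n_sequences,
    length_range = unlist(cfg$length_range),
    gc = cfg$gc, seed = cfg$seed, families = fams, tandems = tds
  )
}
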