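# Hierarchical transposable-element classification from three evidence
# routes, applied in strict precedence: (1) nucleotide homology to a
# classified library (inherits the full classification including family),
# (2) translated ORF similarity to library ORFs (superfamily level only),
# (3) structural features (terminal repeat pairs, poly-A tails) giving
# order-level calls. Also provides the structural detectors themselves:
# LTR/TIR pairs, polypurine tracts (PPT), primer binding sites (PBS) and
# open reading frames.

#' Construct a classification record
#'
#' @param class_ `"I"` (retrotransposon), `"II"` (DNA transposon) or
#'   `"unknown"`.
#' @param order element order (LTR, LINE, SINE, DIRS, PLE, TIR, Helitron,
#'   or unknown).
#' @param superfamily e.g. Gypsy or Copia (implies order LTR).
#' @param family family name or `NA`.
#' @param evidence which route produced the call.
#' @return a `Classification` list.
#' @export
classification <- function(class_ = "unknown", order = "unknown",
                           superfamily = "unknown", family = NA_character_,
                           evidence = "none") {
  if (superfamily %in% c("Gypsy", "Copia") && order == "unknown") {
    order <- "LTR"
  }
  if (superfamily %in% c("Gypsy", "Copia") && class_ == "unknown") {
    class_ <- "I"
  }
  if (!is.na(family) && superfamily == "unknown" && order == "unknown") {
    stop("family-level classification requires higher levels")
  }
  structure(list(class_ = class_, order = order, superfamily = superfamily,
                 family = family, evidence = evidence),
            class = "Classification")
}

#' @export
format.Classification <- function(x, ...) {
  paste0(x$class_, "/", x$order, "/", x$superfamily, "/",
         if (is.na(x$family)) "unknown" else x$family,
         " (", x$evidence, ")")
}

#' @export
print.Classification <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Detect a terminal repeat pair (LTR or TIR) in an element sequence
#'
#' Locally aligns the first W against the last W bp of the sequence
#' (W = min(2500, length/3)) in both orientations. A repeat of at least
#' `min_len` bp at `min_identity` or better is reported; a direct repeat is
#' an LTR candidate, an inverted repeat a TIR candidate.
#'
#' @param seq element sequence (character), length >= 400.
#' @param min_len minimum repeat length in bp.
#' @param min_identity minimum identity (matches / alignment columns).
#' @param scoring alignment scoring.
#' @return `NULL`, or a list with `orientation` (`"direct"`/`"inverted"`),
#'   `left`/`right` (0-based half-open intervals in element coordinates),
#'   and `identity`.
#' @export
detect_ltr_pair <- function(seq, min_len = 100L, min_identity = 0.8,
                            scoring = align_scoring()) {
  seq <- toupper(as.character(seq))
  n <- nchar(seq)
  if (n < 400L) return(NULL)
  w <- min(2500L, n %/% 3L)
  head_w <- substr(seq, 1L, w)
  tail_w <- substr(seq, n - w + 1L, n)
  tail_off <- n - w
  best <- NULL
  for (orient in c("direct", "inverted")) {
    subj <- if (orient == "direct") tail_w else revcomp(tail_w)
    hits <- local_align(head_w, subj, scoring = scoring, min_score = 50,
                        both_strands = FALSE, max_hits = 3L)
    if (nrow(hits) == 0L) next
    hits$identity <- hits$match_count / hits$alignment_length
    hits <- hits[hits$identity >= min_identity &
                   pmin(hits$qend - hits$qstart,
                        hits$send - hits$sstart + 1L) >= min_len, ,
                 drop = FALSE]
    if (nrow(hits) == 0L) next
    h <- hits[1L, ]
    if (orient == "direct") {
      right <- c(tail_off + h$sstart - 1L, tail_off + h$send)
    } else {
      # coordinates were on the reverse complement of the tail window
      right <- c(tail_off + (w - h$send), tail_off + (w - h$sstart + 1L))
    }
    cand <- list(
      orientation = orient,
      left = c(h$qstart, h$qend),
      right = right,
      identity = h$identity,
      score = h$score
    )
    if (is.null(best) || cand$score > best$score) best <- cand
  }
  if (!is.null(best) && best$right[1L] < best$left[2L]) return(NULL)
  best
}

#' Detect a polypurine tract (PPT) interior to the 3' LTR
#'
#' Reports the longest window of at least `min_len` bp with at least 90%
#' purines (A/G) on the element strand, within `window` bp interior of the
#' 3' LTR.
#'
#' @param seq element sequence.
#' @param ltr_pair a [detect_ltr_pair()] result (direct orientation).
#' @param min_len minimum tract length.
#' @param window interior search window in bp.
#' @return `NULL` or a 0-based half-open interval `c(start, end)`.
#' @export
detect_ppt <- function(seq, ltr_pair, min_len = 10L, window = 30L) {
  if (is.null(ltr_pair)) stop("ltr_pair required")
  seq <- toupper(as.character(seq))
  lo <- max(0L, ltr_pair$right[1L] - window)
  hi <- ltr_pair$right[1L]
  if (hi - lo < min_len) return(NULL)
  region <- substr(seq, lo + 1L, hi)
  iv <- seq_to_int(region)
  purine <- as.integer(iv == 0L | iv == 2L)  # A or G
  best <- NULL
  n <- length(purine)
  cs <- c(0L, cumsum(purine))
  for (len in n:min_len) {
    for (s in 0:(n - len)) {
      if ((cs[s + len + 1L] - cs[s + 1L]) / len >= 0.9) {
        best <- c(lo + s, lo + s + len)
        break
      }
    }
    if (!is.null(best)) break
  }
  best
}

#' Detect a primer binding site (PBS) adjacent to an LTR
#'
#' Searches `window` bp interior of each LTR for a stretch of at least
#' `min_len` bp complementary (exactly, or with one mismatch) to the 3'
#' end of the tRNA fixture. The best (longest, then fewest mismatches)
#' site is reported.
#'
#' @param seq element sequence.
#' @param ltr_pair a [detect_ltr_pair()] result.
#' @param trna tRNA 3'-end sequence (default the package fixture).
#' @param min_len minimum complementarity length.
#' @param window interior search window in bp.
#' @return `NULL` or a list with `interval` (0-based half-open), `length`,
#'   `mismatches` and `side` (`"5prime"`/`"3prime"`).
#' @export
detect_pbs <- function(seq, ltr_pair, trna = trna_3prime(),
                       min_len = 11L, window = 30L) {
  if (is.null(ltr_pair)) stop("ltr_pair required")
  seq <- toupper(as.character(seq))
  pbs_full <- revcomp(substr(trna, max(1L, nchar(trna) - 17L), nchar(trna)))
  regions <- list(
    `5prime` = c(ltr_pair$left[2L], min(nchar(seq),
                                        ltr_pair$left[2L] + window)),
    `3prime` = c(max(0L, ltr_pair$right[1L] - window), ltr_pair$right[1L])
  )
  best <- NULL
  for (side in names(regions)) {
    r <- regions[[side]]
    if (r[2L] - r[1L] < min_len) next
    region <- substr(seq, r[1L] + 1L, r[2L])
    # PBS pairs with the tRNA 3' terminus, so candidate sites are prefixes
    # of the reverse complement of the tRNA 3' end
    for (len in nchar(pbs_full):min_len) {
      pat <- substr(pbs_full, 1L, len)
      m <- Biostrings::matchPattern(pat, Biostrings::DNAString(region),
                                    max.mismatch = 1L)
      if (length(m) == 0L) next
      mm <- Biostrings::countPattern(pat, Biostrings::DNAString(region))
      hit_mm <- if (mm > 0L) 0L else 1L
      cand <- list(
        interval = c(r[1L] + Biostrings::start(m)[1L] - 1L,
                     r[1L] + Biostrings::end(m)[1L]),
        length = len, mismatches = hit_mm, side = side
      )
      if (is.null(best) || cand$length > best$length ||
          (cand$length == best$length &&
             cand$mismatches < best$mismatches)) {
        best <- cand
      }
      break
    }
  }
  best
}

#' Detect a 3' poly-A tail
#'
#' @param seq element sequence.
#' @param min_len minimum run of A.
#' @param window terminal window inspected.
#' @return TRUE if the last `window` bp contain a run of >= `min_len` A's.
#' @export
has_polya_tail <- function(seq, min_len = 10L, window = 20L) {
  seq <- toupper(as.character(seq))
  n <- nchar(seq)
  tailseq <- substr(seq, max(1L, n - window + 1L), n)
  grepl(strrep("A", min_len), tailseq, fixed = TRUE)
}

#' Extract open reading frames from all six frames
#'
#' An ORF is a span from a start codon (or the frame start) to the next
#' stop codon, of at least `min_aa` amino acids, under the standard genetic
#' code.
#'
#' @param seq DNA sequence.
#' @param min_aa minimum ORF length in amino acids.
#' @return a `data.frame` with `frame` (1..3 forward, -1..-3 reverse),
#'   `start`, `end` (0-based half-open, on the input strand), and
#'   `protein`.
#' @export
extract_orfs <- function(seq, min_aa = 100L) {
  seq <- toupper(as.character(seq))
  n <- nchar(seq)
  out <- list()
  for (dir in c(1L, -1L)) {
    s <- if (dir == 1L) seq else revcomp(seq)
    for (off in 0:2) {
      if (n - off < 3L) next
      codable <- off + 3L * ((n - off) %/% 3L)
      aa <- suppressWarnings(as.character(Biostrings::translate(
        Biostrings::DNAString(substr(s, off + 1L, codable)),
        if.fuzzy.codon = "X"
      )))
      segs <- strsplit(aa, "*", fixed = TRUE)[[1L]]
      pos_aa <- 0L
      for (seg in segs) {
        if (nchar(seg) >= min_aa) {
          a0 <- off + 3L * pos_aa
          a1 <- a0 + 3L * nchar(seg)
          if (dir == -1L) {
            tmp <- a0
            a0 <- n - a1
            a1 <- n - tmp
          }
          out[[length(out) + 1L]] <- data.frame(
            frame = dir * (off + 1L), start = a0, end = a1,
            protein = seg, stringsAsFactors = FALSE
          )
        }
        pos_aa <- pos_aa + nchar(seg) + 1L
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(frame = integer(0), start = integer(0),
                      end = integer(0), protein = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Collect structural features of an element sequence
#'
#' @param seq element sequence.
#' @param trna tRNA 3'-end for PBS detection.
#' @param min_aa ORF length threshold.
#' @return a `StructuralFeatures` list: `ltr_pair`, `ppt`, `pbs`, `polya`,
#'   `orfs`.
#' @export
structural_features <- function(seq, trna = trna_3prime(), min_aa = 100L) {
  pair <- detect_ltr_pair(seq)
  ppt <- if (!is.null(pair) && pair$orientation == "direct") {
    detect_ppt(seq, pair)
  }
  pbs <- if (!is.null(pair) && pair$orientation == "direct") {
    detect_pbs(seq, pair, trna)
  }
  structure(list(
    ltr_pair = pair, ppt = ppt, pbs = pbs,
    polya = has_polya_tail(seq),
    orfs = extract_orfs(seq, min_aa = min_aa)
  ), class = "StructuralFeatures")
}

# protein-level similarity between two ORF sets: best local alignment
# identity over >= min_aa aligned columns
best_protein_hit <- function(orfs_q, orfs_s, min_aa = 100L) {
  if (nrow(orfs_q) == 0L || nrow(orfs_s) == 0L) return(NULL)
  data("BLOSUM62", package = "Biostrings", envir = environment())
  mat <- get("BLOSUM62", envir = environment())
  best <- NULL
  for (i in seq_len(nrow(orfs_q))) {
    for (j in seq_len(nrow(orfs_s))) {
      aln <- Biostrings::pairwiseAlignment(
        Biostrings::AAString(orfs_q$protein[i]),
        Biostrings::AAString(orfs_s$protein[j]),
        type = "local", substitutionMatrix = mat,
        gapOpening = 10, gapExtension = 1
      )
      pat <- strsplit(as.character(Biostrings::alignedPattern(aln)),
                      "")[[1L]]
      sub <- strsplit(as.character(Biostrings::alignedSubject(aln)),
                      "")[[1L]]
      cols <- length(pat)
      if (cols < min_aa) next
      ident <- sum(pat == sub & pat != "-") / cols
      if (is.null(best) || ident > best$identity) {
        best <- list(identity = ident, columns = cols,
                     score = Biostrings::score(aln))
      }
    }
  }
  best
}

#' Classify a repeat sequence against a library
#'
#' Applies the three-route precedence: (1) a nucleotide hit passing the
#' full-length 80-80-80 filter inherits the library entry's complete
#' classification including family; (2) otherwise, a local protein
#' alignment between the sequence's ORFs and the library entries' ORFs
#' with identity >= `prot_min_identity` over >= `prot_min_aa` aligned
#' residues assigns the superfamily (and implied order/class) but no
#' family; (3) otherwise structural features decide the order: a direct
#' terminal repeat pair gives (I, LTR), an inverted pair (II, TIR), and a
#' poly-A tail with no terminal repeats plus an ORF gives (I, LINE).
#'
#' @param seq the repeat sequence (consensus or instance).
#' @param library a `RepeatLibrary` (may be empty via `NULL`).
#' @param features optional precomputed [structural_features()].
#' @param params [filter_params()] for the nucleotide route.
#' @param prot_min_identity,prot_min_aa protein-route thresholds.
#' @param scoring nucleotide alignment scoring.
#' @return a [classification()].
#' @export
classify_repeat <- function(seq, library = NULL, features = NULL,
                            params = filter_params(),
                            prot_min_identity = 0.35, prot_min_aa = 100L,
                            scoring = align_scoring()) {
  seq <- toupper(as.character(seq))
  # route 1: nucleotide homology
  if (!is.null(library) && length(library$seqs) > 0L) {
    hits <- seeded_search(
      stats::setNames(seq, "query"), library$seqs, scoring = scoring,
      min_score = 50
    )
    hits <- full_length_filter(hits, library, params)
    if (nrow(hits) > 0L) {
      h <- hits[which.max(hits$score), ]
      e <- library$info[library$info$name == h$subject_name, ]
      fam <- if (e$family == "unknown") e$name else e$family
      return(classification(e$class_, e$order, e$superfamily, fam,
                            evidence = "nucleotide"))
    }
  }
  if (is.null(features)) features <- structural_features(seq)
  # route 2: translated ORF similarity -> superfamily only
  if (!is.null(library) && length(library$seqs) > 0L &&
        nrow(features$orfs) > 0L) {
    cand <- library$info[library$info$superfamily != "unknown", ,
                         drop = FALSE]
    best <- NULL
    best_e <- NULL
    for (nm in cand$name) {
      orfs_s <- extract_orfs(library$seqs[[nm]], min_aa = prot_min_aa)
      hit <- best_protein_hit(features$orfs, orfs_s, min_aa = prot_min_aa)
      if (!is.null(hit) && hit$identity >= prot_min_identity &&
            (is.null(best) || hit$identity > best$identity)) {
        best <- hit
        best_e <- cand[cand$name == nm, ]
      }
    }
    if (!is.null(best)) {
      return(classification(best_e$class_, best_e$order,
                            best_e$superfamily, NA_character_,
                            evidence = "protein"))
    }
  }
  # route 3: structural
  if (!is.null(features$ltr_pair)) {
    if (features$ltr_pair$orientation == "direct") {
      return(classification("I", "LTR", evidence = "structural"))
    }
    return(classification("II", "TIR", evidence = "structural"))
  }
  if (features$polya && nrow(features$orfs) > 0L) {
    return(classification("I", "LINE", evidence = "structural"))
  }
  classification()
}
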