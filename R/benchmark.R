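# Canonical benchmark genome: the fixed study conditions used by the
# validation suite and the acceptance script. Three ~200 kbp sequences at
# 38% GC carry K planted LTR families (independent random masters, hence
# mutually unrelated; >= 8 full-length copies each at ~95% per-copy
# identity) and twenty tandem arrays spanning the microsatellite,
# minisatellite and satellite period ranges.

#' Benchmark genome specification (fixed study conditions)
#'
#' Builds the standard validation genome: `n_sequences` background
#' sequences of ~200 kbp at 38% GC, `n_families` planted LTR
#' retrotransposon families (3 kbp elements with 400 bp LTRs, 10 copies,
#' substitution rate 0.05, indel rate 0.005 - per-copy identity around
#' 0.93-0.95; masters are independent random draws, so mutual identity is
#' far below the 0.8 clustering threshold) and twenty tandem arrays with
#' periods from 2 to 450 bp at 2% internal divergence. All randomness
#' derives from `seed`.
#'
#' @param n_families number of planted families (1-5 in the validation
#'   suite).
#' @param seed RNG seed.
#' @param n_sequences,seq_length background shape.
#' @return a [genome_spec()].
#' @export
benchmark_genome_spec <- function(n_families = 3L, seed = 1L,
                                  n_sequences = 3L, seq_length = 200000L) {
  set.seed(seed)
  fams <- lapply(seq_len(n_families), function(i) {
    family_spec(sprintf("fam%02d", i), order = "LTR",
                element_length = 3000L, ltr_length = 400L,
                copy_number = 10L, sub_rate = 0.05, indel_rate = 0.005)
  })
  tandem_plan <- list(
    c(2, 30), c(2, 25), c(3, 20), c(4, 15), c(5, 15), c(7, 12), c(10, 10),
    c(12, 9), c(15, 8), c(21, 8), c(25, 20), c(32, 6), c(45, 5), c(60, 5),
    c(80, 4), c(101, 4), c(123, 4), c(150, 3), c(201, 3), c(450, 2)
  )
  tds <- lapply(tandem_plan, function(pc) {
    motif <- random_dna(pc[1L], gc = 0.4)
    # a motif that is itself periodic (or a mononucleotide run) would
    # plant a different true period than specified
    while (is_self_periodic(motif)) motif <- random_dna(pc[1L], gc = 0.4)
    tandem_spec(motif, copies = pc[2L], sub_rate = 0.02)
  })
  # the genome itself uses a seed derived from (not equal to) the spec
  # seed, so the background stream never replays the motif/master draws
  genome_spec(
    n_sequences = n_sequences,
    length_range = c(as.integer(0.9 * seq_length),
                     as.integer(1.1 * seq_length)),
    gc = 0.38, seed = (seed + 499979L) %% .Machine$integer.max,
    families = fams, tandems = tds
  )
}

# TRUE if the motif is a whole-number repetition of a shorter unit
is_self_periodic <- function(motif) {
  n <- nchar(motif)
  for (p in seq_len(n %/% 2)) {
    if (n %% p == 0L &&
          motif == strrep(substr(motif, 1L, p), n %/% p)) {
      return(TRUE)
    }
  }
  FALSE
}
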