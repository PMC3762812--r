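# Shared fixtures, built lazily once per test run.

.fixtures <- new.env(parent = emptyenv())

# small simulated genome with one planted LTR family and two tandem
# arrays; cached along with the downstream de novo stages
small_sim <- function() {
  if (is.null(.fixtures$sim)) {
    spec <- genome_spec(
      n_sequences = 2L, length_range = c(45000L, 55000L), gc = 0.38,
      seed = 20260921L,
      families = list(family_spec("famA", order = "LTR",
                                  element_length = 3000L,
                                  ltr_length = 400L, copy_number = 10L)),
      tandems = list(tandem_spec("AT", 30), tandem_spec("TGCTT", 40))
    )
    .fixtures$sim <- simulate_genome(spec)
  }
  .fixtures$sim
}

small_seeds <- function() {
  if (is.null(.fixtures$seeds)) {
    .fixtures$seeds <- discover_seeds(small_sim()$set)
  }
  .fixtures$seeds
}

small_instances <- function() {
  if (is.null(.fixtures$instances)) {
    .fixtures$instances <- map_seeds(small_seeds(), small_sim()$set)
  }
  .fixtures$instances
}

small_clusters <- function() {
  if (is.null(.fixtures$clusters)) {
    .fixtures$clusters <- cluster_instances(small_instances())
  }
  .fixtures$clusters
}

# a tiny classified repeat library around the small_sim master plus two
# decoy entries
small_library <- function() {
  if (is.null(.fixtures$library)) {
    sim <- small_sim()
    set.seed(5)
    seqs <- c(sim$masters[["famA"]], rand_dna(1200), rand_dna(900))
    names(seqs) <- c("famA#I/LTR/Gypsy/famA@synthetic",
                     "decoy1#I/LINE/unknown/decoy1@synthetic",
                     "decoy2#II/TIR/unknown/decoy2@synthetic")
    .fixtures$library <- repeat_library(seqs)
  }
  .fixtures$library
}
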