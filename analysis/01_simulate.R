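#!/usr/bin/env Rscript

# Stage 1: build the study genome.
#
# Simulates the standard benchmark sequence set: three ~200 kbp sequences
# at 38% GC carrying three planted LTR retrotransposon families (3 kbp
# elements, 400 bp LTRs, 10 copies each at ~95% per-copy identity) and
# twenty tandem arrays with periods from 2 to 450 bp. The exact planted
# coordinates, identities and strands go to results/simulation/ as the
# ground truth that later stages are scored against.

library(repeatscape)

seed <- 42L
out_dir <- "results/simulation"

spec <- benchmark_genome_spec(n_families = 3L, seed = seed)
sim <- simulate_genome(spec)
write_simulation(sim, out_dir)

s <- summarize_set(sim$set)
cat(sprintf(
  "simulated %d sequences, %s bp (GC %.2f%%, N50 %s bp)\n",
  s$count, format(s$total_len, big.mark = ","), 100 * s$gc,
  format(s$n50, big.mark = ",")
))
cat(sprintf(
  "planted %d TE copies in %d families and %d tandem arrays (%s bp of repeat)\n",
  sum(sim$truth$kind == "TE"), length(sim$masters),
  sum(sim$truth$kind == "tandem"),
  format(sum(sim$truth$end - sim$truth$start), big.mark = ",")
))
write.table(s, file.path(out_dir, "set_summary.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("outputs in", out_dir, "\n")
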