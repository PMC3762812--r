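#!/usr/bin/env Rscript

# Stage 3: homology annotation against a classified repeat library.
#
# Builds a small classified library containing one of the planted family
# masters (playing the role of a previously characterized element; the
# other planted families stay "novel" and are left for the de novo
# stage) plus an unrelated decoy, then annotates the genome in
# non-redundant mode, both unfiltered (partial + full-length) and with
# the full-length filter (hits > 80 bp on the reference, gap-adjusted
# similarity >= 0.80, >= 80% reference coverage).

library(repeatscape)

set <- read_fasta("results/simulation/genome.fa")
masters <- read_fasta("results/simulation/masters.fa")
out_dir <- "results/homology"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

known <- names(masters$records)[1]
set.seed(7)
decoy <- paste(sample(c("A", "C", "G", "T"), 1500, TRUE), collapse = "")
lib <- repeat_library(c(
  stats::setNames(as.character(masters$records[[known]]),
                  paste0(known, "#I/LTR/Gypsy/", known, "@synthetic")),
  "decoy#I/LTR/Copia/decoy@synthetic" = decoy
))
write_repeat_library(lib, file.path(out_dir, "library.fa"))

unfiltered <- annotate_set(set, lib, redundancy = "nonredundant",
                           filtered = FALSE)
filtered <- annotate_set(set, lib, redundancy = "nonredundant",
                         filtered = TRUE)

for (mode in c("unfiltered", "filtered")) {
  ann <- get(mode)
  write.table(ann$coverage,
              file.path(out_dir, paste0("coverage_", mode, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  tot <- ann$coverage[ann$coverage$level == "total", ]
  cat(sprintf("%s: %d hits, %s bp (%.2f%% of the set)\n", mode,
              nrow(ann$hits), format(tot$bp, big.mark = ","), tot$pct))
}
write_gff3(repeatscape:::hits_to_annotations(filtered$hits, lib), set,
           file.path(out_dir, "full_length_hits.gff3"))

ratio <- gypsy_copia_ratio(filtered$coverage)
cat("Gypsy:Copia coverage ratio (full-length):",
    if (is.na(ratio)) "undefined (no Copia coverage)" else ratio, "\n")
cat(sprintf(
  "full-length %s copies found: %d\n", known,
  sum(filtered$hits$subject_name == known)
))
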