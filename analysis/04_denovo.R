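#!/usr/bin/env Rscript

# Stage 4: de novo repeat family discovery.
#
# Discovers repeat seeds by all-vs-all self-alignment (plus a structural
# direct-repeat scan), maps the deduplicated seeds back onto the genome
# as a non-redundant library search, keeps full-length instances through
# the 80-80-80 filter, clusters instances at 80% global identity, builds
# per-cluster consensi, and merges clusters into families by all-vs-all
# consensus alignment. Families are named from the homology library when
# their representative consensus matches a classified entry.

library(repeatscape)

set <- read_fasta("results/simulation/genome.fa")
lib <- read_repeat_library("results/homology/library.fa")
out_dir <- "results/denovo"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

seeds <- discover_seeds(set)
cat(sprintf("discovered %d seeds (%d self-alignment, %d structural)\n",
            nrow(seeds), sum(seeds$method == "selfalign"),
            sum(seeds$method == "structural")))
write_fasta(stats::setNames(seeds$consensus, seeds$id),
            file.path(out_dir, "seeds.fa"))

instances <- map_seeds(seeds, set)
cat(sprintf("mapped %d full-length instances (mean length %d bp)\n",
            nrow(instances),
            as.integer(mean(nchar(instances$sequence)))))
write.table(instances[, setdiff(names(instances), "sequence")],
            file.path(out_dir, "instances.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

clusters <- cluster_instances(instances)
cat(sprintf("clustered into %d clusters at 80%% identity\n",
            length(clusters)))

families <- build_families(clusters, library = lib)
report <- family_report(families, set)
write.table(report, file.path(out_dir, "family_report.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
consensi <- vapply(families, function(f) {
  rep_cl <- f$clusters[[which(vapply(f$clusters, `[[`, character(1),
                                     "id") == f$representative)]]
  rep_cl$consensus
}, character(1))
write_fasta(stats::setNames(consensi,
                            vapply(families, `[[`, character(1), "name")),
            file.path(out_dir, "family_consensi.fa"))

cat("family table:\n")
print(report, row.names = FALSE)
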