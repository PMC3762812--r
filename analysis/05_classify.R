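#!/usr/bin/env Rscript

# Stage 5: hierarchical classification of the de novo family consensi.
#
# Each family consensus runs through the three-route precedence:
# nucleotide homology to the classified library (full classification
# including family), translated ORF similarity (superfamily only), then
# structural features - a direct terminal-repeat pair gives
# (Class I, LTR), an inverted pair (Class II, TIR), a poly-A tail with an
# ORF and no terminal repeats (Class I, LINE). Structural features (LTR
# pair, PBS, PPT, ORFs) are also tabulated per consensus.

library(repeatscape)

cons <- read_fasta("results/denovo/family_consensi.fa")
lib <- read_repeat_library("results/homology/library.fa")
out_dir <- "results/classification"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

rows <- list()
for (nm in names(cons$records)) {
  seqc <- as.character(cons$records[[nm]])
  feats <- structural_features(seqc)
  cls <- classify_repeat(seqc, lib, features = feats)
  rows[[nm]] <- data.frame(
    family = nm, length = nchar(seqc),
    class = cls$class_, order = cls$order,
    superfamily = cls$superfamily,
    lib_family = ifelse(is.na(cls$family), "none", cls$family),
    evidence = cls$evidence,
    ltr_pair = !is.null(feats$ltr_pair),
    ltr_len = if (!is.null(feats$ltr_pair)) {
      feats$ltr_pair$left[2] - feats$ltr_pair$left[1]
    } else NA_integer_,
    pbs = !is.null(feats$pbs), ppt = !is.null(feats$ppt),
    n_orfs = nrow(feats$orfs), stringsAsFactors = FALSE
  )
  cat(sprintf("%s (%d bp): %s/%s/%s via %s%s\n", nm, nchar(seqc),
              cls$class_, cls$order, cls$superfamily, cls$evidence,
              if (!is.null(feats$ltr_pair)) {
                sprintf(" [LTR pair %d bp at %.0f%% identity]",
                        feats$ltr_pair$left[2] - feats$ltr_pair$left[1],
                        100 * feats$ltr_pair$identity)
              } else ""))
}
tab <- do.call(rbind, rows)
write.table(tab, file.path(out_dir, "classifications.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("%d/%d consensi classified to order level or better\n",
            sum(tab$order != "unknown"), nrow(tab)))
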