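#!/usr/bin/env Rscript

# Stage 6: combined repetitive-content accounting and truth scoring.
#
# Combines the tandem and interspersed (homology + de novo) annotations:
# interspersed intervals are unioned per mode, tandem coverage is
# reported raw and after subtracting interspersed overlap, and the total
# repetitive content is interspersed plus the non-overlapping tandem
# remainder. The planted ground truth then scores the whole analysis.

library(repeatscape)

set <- read_fasta("results/simulation/genome.fa")
truth <- read.table("results/simulation/truth.tsv", header = TRUE,
                    sep = "\t", stringsAsFactors = FALSE)
arrays <- read.table("results/tandem/tandem_arrays.tsv", header = TRUE,
                     sep = "\t", stringsAsFactors = FALSE)
instances <- read.table("results/denovo/instances.tsv", header = TRUE,
                        sep = "\t", stringsAsFactors = FALSE)
homology <- read_gff3("results/homology/full_length_hits.gff3")
out_dir <- "results/report"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

report <- content_report(set, arrays, list(
  filtered = list(homology = homology, denovo = instances)
))
write.table(report$categories, file.path(out_dir, "content_categories.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(report$totals, file.path(out_dir, "content_totals.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

tot <- report$totals
cat(sprintf(
  "interspersed %.2f%% + non-overlapping tandem %.2f%% = total repetitive %.2f%%\n",
  tot$interspersed_pct, tot$tandem_pct_nonoverlapping,
  tot$total_repetitive_pct
))
cat(sprintf("(raw tandem %.2f%%: %.2f%% of it lies inside interspersed calls)\n",
            tot$tandem_pct_raw,
            tot$tandem_pct_raw - tot$tandem_pct_nonoverlapping))

# score against the planted truth
denom <- summarize_set(set)$total_len
truth_bp <- merged_coverage(truth[, c("seq_id", "start", "end")], set)
truth_pct <- 100 * truth_bp / denom
rel_err <- abs(tot$total_repetitive_pct - truth_pct) / truth_pct
cat(sprintf("planted truth: %.2f%% repetitive; estimate off by %.1f%% relative\n",
            truth_pct, 100 * rel_err))

# planted tandem recall (period correct up to harmonics, >= 50% overlap)
planted <- truth[truth$kind == "tandem", ]
rec <- vapply(seq_len(nrow(planted)), function(i) {
  p <- planted[i, ]
  period <- nchar(p$name)
  ov <- arrays$seq_id == p$seq_id &
    pmin(arrays$end, p$end) - pmax(arrays$start, p$start) >=
      0.5 * (p$end - p$start)
  cand <- arrays[ov, , drop = FALSE]
  any(cand$period_size %% period == 0 | period %% cand$period_size == 0)
}, logical(1))
cat(sprintf("tandem recall: %d/%d planted arrays (%.0f%%)\n",
            sum(rec), nrow(planted), 100 * mean(rec)))

scores <- data.frame(
  truth_repetitive_pct = round(truth_pct, 2),
  estimated_repetitive_pct = tot$total_repetitive_pct,
  content_rel_error = round(rel_err, 4),
  tandem_recall = round(mean(rec), 3)
)
write.table(scores, file.path(out_dir, "truth_scores.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
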