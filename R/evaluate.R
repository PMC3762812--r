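# Comparison of pipeline output against a simulation's ground truth:
# family recovery, copy-count accuracy, tandem recall and total
# repetitive-content error.

#' Score a pipeline run against simulated ground truth
#'
#' A planted family counts as recovered when a reported multi-copy family
#' (>= 2 copies) has a representative consensus at >= `match_identity`
#' global identity (either orientation) to the family master. A planted
#' tandem array counts as recovered when a resolved detected array covers
#' at least half of its span with a period equal to (or an integer
#' multiple/divisor of) the planted period. The repetitive-content error
#' compares the filtered-mode total repetitive percentage against the
#' ground-truth percentage (merged truth intervals over non-N length).
#'
#' @param sim a `RepeatSimulation`.
#' @param res a [run_repeat_pipeline()] result on `sim$set`.
#' @param match_identity identity threshold for matching a family
#'   consensus to a master.
#' @return a list: `n_families_true`, `n_families_recovered`,
#'   `n_families_spurious`, `copy_count_errors` (named absolute errors per
#'   recovered master), `tandem_n_true`, `tandem_recall`,
#'   `truth_repetitive_pct`, `estimated_repetitive_pct`,
#'   `content_rel_error`.
#' @export
evaluate_recovery <- function(sim, res, match_identity = 0.8) {
  truth <- sim$truth
  masters <- sim$masters

  # family recovery
  fams <- Filter(function(f) f$copy_count >= 2L, res$denovo$families)
  assign <- rep(NA_character_, length(fams))
  for (i in seq_along(fams)) {
    f <- fams[[i]]
    rep_cl <- f$clusters[[
      which(vapply(f$clusters, `[[`, character(1), "id") ==
              f$representative)
    ]]
    cons <- rep_cl$consensus
    ids <- vapply(names(masters), function(m) {
      max(global_identity(cons, masters[[m]]),
          global_identity(cons, revcomp(masters[[m]])))
    }, numeric(1))
    if (length(ids) && max(ids) >= match_identity) {
      assign[i] <- names(masters)[which.max(ids)]
    }
  }
  recovered <- unique(assign[!is.na(assign)])
  copy_err <- vapply(recovered, function(m) {
    got <- sum(vapply(fams[assign == m & !is.na(assign)], `[[`,
                      numeric(1), "copy_count"))
    want <- sum(truth$kind == "TE" & truth$name == m & truth$full_length)
    abs(got - want)
  }, numeric(1))

  # tandem recall
  planted <- truth[truth$kind == "tandem", , drop = FALSE]
  det <- res$tandem$resolved
  rec <- vapply(seq_len(nrow(planted)), function(i) {
    p <- planted[i, ]
    period <- nchar(p$name)
    ov <- det$seq_id == p$seq_id &
      pmin(det$end, p$end) - pmax(det$start, p$start) >=
        0.5 * (p$end - p$start)
    cand <- det[ov, , drop = FALSE]
    any(cand$period_size %% period == 0 | period %% cand$period_size == 0)
  }, logical(1))

  # repetitive content
  truth_bp <- merged_coverage(truth[, c("seq_id", "start", "end")],
                              sim$set)
  denom <- summarize_set(sim$set)$total_len
  truth_pct <- 100 * truth_bp / denom
  tot <- res$content$totals
  est_pct <- tot$total_repetitive_pct[tot$mode == "filtered"]

  list(
    n_families_true = length(masters),
    n_families_recovered = length(recovered),
    n_families_spurious = sum(is.na(assign)),
    copy_count_errors = copy_err,
    tandem_n_true = nrow(planted),
    tandem_recall = if (nrow(planted)) mean(rec) else NA_real_,
    truth_repetitive_pct = truth_pct,
    estimated_repetitive_pct = est_pct,
    content_rel_error = abs(est_pct - truth_pct) / truth_pct
  )
}
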