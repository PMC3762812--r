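# End-to-end orchestration: tandem detection, optional homology
# annotation, de novo family discovery and the combined content report,
# with optional on-disk outputs mirroring the per-stage tables.

#' Run the full repeat-annotation pipeline on a sequence set
#'
#' Stages: (1) tandem repeat detection and overlap resolution; (2)
#' homology annotation against `library` (when supplied), in redundant and
#' non-redundant x filtered and unfiltered modes; (3) de novo seed
#' discovery, instance mapping, clustering, consensus and family building;
#' (4) combined content report (interspersed union plus non-overlapping
#' tandem remainder).
#'
#' @param set a `SequenceSet` (or FASTA path).
#' @param library optional `RepeatLibrary` for the homology stage and for
#'   naming/classifying de novo families.
#' @param out_dir optional directory for stage outputs (TSV/GFF3/FASTA).
#' @param filter [filter_params()].
#' @param tandem [tandem_params()].
#' @param seeds [seed_params()].
#' @param scoring [align_scoring()].
#' @return a list with elements `set_summary`, `tandem` (arrays, resolved
#'   arrays, summary), `homology` (annotate_set results per mode, or
#'   `NULL`), `denovo` (seeds, instances, clusters, families, report) and
#'   `content` (the combined [content_report()]).
#' @export
run_repeat_pipeline <- function(set, library = NULL, out_dir = NULL,
                                filter = filter_params(),
                                tandem = tandem_params(),
                                seeds = seed_params(),
                                scoring = align_scoring()) {
  if (is.character(set) && length(set) == 1L && file.exists(set)) {
    set <- read_fasta(set)
  }
  set <- as_sequence_set(set)
  set_summary <- summarize_set(set)

  arrays <- detect_tandem(set, tandem)
  resolved <- resolve_tandem_overlaps(arrays)
  tandem_summary <- classify_and_summarize(resolved, set)

  homology <- NULL
  if (!is.null(library)) {
    homology <- list(
      unfiltered = annotate_set(set, library, params = filter,
                                redundancy = "nonredundant",
                                filtered = FALSE, scoring = scoring),
      filtered = annotate_set(set, library, params = filter,
                              redundancy = "nonredundant",
                              filtered = TRUE, scoring = scoring)
    )
  }

  seed_tab <- discover_seeds(set, seeds, scoring = scoring)
  instances <- map_seeds(seed_tab, set, params = filter, scoring = scoring)
  clusters <- cluster_instances(instances, scoring = scoring)
  families <- build_families(clusters, params = filter, scoring = scoring,
                             library = library)
  fam_report <- family_report(families, set)

  modes <- list()
  denovo_spans <- spans_of(instances)
  if (!is.null(homology)) {
    modes$unfiltered <- list(
      homology = spans_of(homology$unfiltered$hits),
      denovo = denovo_spans
    )
    modes$filtered <- list(
      homology = spans_of(homology$filtered$hits),
      denovo = denovo_spans
    )
  } else {
    modes$filtered <- list(denovo = denovo_spans)
  }
  content <- content_report(set, resolved, modes)

  res <- list(
    set_summary = set_summary,
    tandem = list(arrays = arrays, resolved = resolved,
                  summary = tandem_summary),
    homology = homology,
    denovo = list(seeds = seed_tab, instances = instances,
                  clusters = clusters, families = families,
                  report = fam_report),
    content = content
  )
  if (!is.null(out_dir)) write_pipeline_outputs(res, set, out_dir)
  res
}

write_pipeline_outputs <- function(res, set, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, f) {
    utils::write.table(df, file.path(out_dir, f), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  wt(res$set_summary, "set_summary.tsv")
  wt(res$tandem$resolved, "tandem_arrays.tsv")
  wt(res$tandem$summary, "tandem_summary.tsv")
  if (nrow(res$tandem$resolved)) {
    ann <- annotation_table(
      seq_id = res$tandem$resolved$seq_id,
      start = res$tandem$resolved$start, end = res$tandem$resolved$end,
      category = paste0("tandem/period", res$tandem$resolved$period_size),
      score = res$tandem$resolved$score
    )
    write_gff3(ann, set, file.path(out_dir, "tandem.gff3"))
  }
  if (!is.null(res$homology)) {
    wt(res$homology$unfiltered$coverage, "homology_coverage_unfiltered.tsv")
    wt(res$homology$filtered$coverage, "homology_coverage_filtered.tsv")
  }
  if (nrow(res$denovo$seeds)) {
    write_fasta(stats::setNames(res$denovo$seeds$consensus,
                                res$denovo$seeds$id),
                file.path(out_dir, "seeds.fa"))
  }
  wt(res$denovo$report, "family_report.tsv")
  if (nrow(res$denovo$instances)) {
    ann <- annotation_table(
      seq_id = res$denovo$instances$seq_id,
      start = res$denovo$instances$start,
      end = res$denovo$instances$end,
      strand = res$denovo$instances$strand,
      category = paste0("denovo/", res$denovo$instances$seed_id),
      score = round(1000 * res$denovo$instances$sim)
    )
    write_gff3(ann, set, file.path(out_dir, "instances.gff3"))
  }
  wt(res$content$categories, "content_categories.tsv")
  wt(res$content$totals, "content_totals.tsv")
  invisible(out_dir)
}
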