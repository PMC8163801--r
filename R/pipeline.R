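#' Pipeline configuration
#'
#' Validated bundle of every analysis parameter consumed by
#' [run_pipeline()]. Out-of-range values are rejected before any computation.
#'
#' @param pentosidine_cutoff Group cutoff, ng/mL (default 55.2).
#' @param enrich_threshold miRNA-gene rate counting as enriched (default 0.5).
#' @param qc_threshold Sample QC score cut (default 0.15).
#' @param autosomal_count_limit Passed to [qc_filter_samples()].
#' @param max_frequency Rare-CNV locus frequency cut (default 0.01).
#' @param reciprocal_overlap Locus-clustering overlap fraction (default 0.5).
#' @param min_overlap_bases Gene-overlap minimum, bases (default 1).
#' @param fisher_direction Direction of the one-sided tests (default
#'   `"greater"`: excess in the high group).
#' @param or_correction Apply the Haldane-Anscombe zero-cell correction
#'   (default `TRUE`).
#' @param drop_shared_mirnas Drop miRNAs seen in both groups before the
#'   target/ORA stage (default `TRUE`).
#' @param ora_evidence Optional target-evidence filter (`"validated"` or
#'   `"putative"`).
#' @return List of class `mircnv_config`.
#' @export
pipeline_config <- function(pentosidine_cutoff = 55.2,
                            enrich_threshold = 0.5,
                            qc_threshold = 0.15,
                            autosomal_count_limit = "auto",
                            max_frequency = 0.01,
                            reciprocal_overlap = 0.5,
                            min_overlap_bases = 1L,
                            fisher_direction = "greater",
                            or_correction = TRUE,
                            drop_shared_mirnas = TRUE,
                            ora_evidence = NULL) {
  stopifnot(pentosidine_cutoff > 0,
            enrich_threshold > 0, enrich_threshold <= 1,
            qc_threshold > 0,
            max_frequency > 0, max_frequency <= 1,
            reciprocal_overlap > 0, reciprocal_overlap <= 1,
            min_overlap_bases >= 1,
            fisher_direction %in% c("greater", "less"),
            is.logical(or_correction), is.logical(drop_shared_mirnas))
  if (!is.null(ora_evidence)) {
    ora_evidence <- match.arg(ora_evidence, c("validated", "putative"))
  }
  structure(as.list(environment()), class = "mircnv_config")
}

#' Run the full CNV-miRNA burden pipeline
#'
#' Executes the analysis end to end: sample QC, rare-CNV frequency
#' filtering, gene/miRNA annotation, per-patient burden aggregation,
#' pentosidine group assignment, the Table-1-style group summary with exact
#' group comparisons, and (when target tables and gene sets are supplied)
#' over-representation analysis of the high-group miRNA targets.
#'
#' @param calls CNV call tibble or path readable by [read_cnv_calls()].
#' @param annotation Annotation tibble or path for [read_annotation()].
#' @param metadata Metadata tibble or path for [read_metadata()].
#' @param config A [pipeline_config()].
#' @param targets Optional miRNA target tibble or path
#'   ([read_mirna_targets()]).
#' @param gene_sets Optional gene-set collection tibble or path
#'   ([read_gmt()]).
#' @param out_dir Optional directory; when given, the burden, summary,
#'   association and ORA tables are written there as TSV.
#' @return List of class `mircnv_result`: `burden`, `summary`,
#'   `associations`, `mirna_sets`, `shared_mirnas`, `ora` (or `NULL`), and
#'   `log` (per-stage row/sample counts and the config).
#' @export
run_pipeline <- function(calls, annotation, metadata,
                         config = pipeline_config(),
                         targets = NULL, gene_sets = NULL, out_dir = NULL) {
  stopifnot(inherits(config, "mircnv_config"))
  if (is.character(calls)) calls <- read_cnv_calls(calls)
  if (is.character(annotation)) annotation <- read_annotation(annotation)
  if (is.character(metadata)) metadata <- read_metadata(metadata)
  if (is.character(targets)) targets <- read_mirna_targets(targets)
  if (is.character(gene_sets)) gene_sets <- read_gmt(gene_sets)
  log <- list(n_input_calls = nrow(calls), n_input_samples = nrow(metadata))

  # 1. sample QC
  qc <- qc_filter_samples(calls, qc_threshold = config$qc_threshold,
                          autosomal_count_limit = config$autosomal_count_limit)
  cohort_ids <- setdiff(metadata$sample_id, qc$exclusions$sample_id)
  if (length(cohort_ids) == 0) stop("no samples pass QC", call. = FALSE)
  log$n_qc_excluded <- nrow(qc$exclusions)
  log$n_cohort <- length(cohort_ids)

  # 2. rare-CNV frequency filter (denominator: full post-QC cohort)
  rare <- filter_rare_cnvs(qc$calls, n_samples = length(cohort_ids),
                           max_frequency = config$max_frequency,
                           reciprocal_overlap = config$reciprocal_overlap)
  log$n_rare_calls <- nrow(rare)

  # 3. annotation, 4. per-patient burden
  annotated <- annotate_cnvs(rare, annotation,
                             min_overlap_bases = config$min_overlap_bases)
  burden <- patient_burden(annotated, sample_ids = cohort_ids,
                           enrich_threshold = config$enrich_threshold)

  # 5. group assignment + summary table
  meta_cohort <- metadata[metadata$sample_id %in% cohort_ids, , drop = FALSE]
  groups <- tibble::tibble(
    sample_id = meta_cohort$sample_id,
    group = classify_pentosidine(meta_cohort$pentosidine,
                                 config$pentosidine_cutoff)
  )
  summary_tab <- group_summary(burden, meta_cohort,
                               cutoff = config$pentosidine_cutoff)

  # 6. headline association statistics
  grp_burden <- dplyr::inner_join(burden, groups, by = "sample_id")
  grp_burden <- grp_burden[!is.na(grp_burden$group), , drop = FALSE]
  associations <- dplyr::bind_rows(
    association_row(grp_burden, "mirna_enriched", grp_burden$enriched, config),
    association_row(grp_burden, "harbors_cnv_mirna", grp_burden$n_mirnas >= 1, config)
  )

  mirna_sets <- group_mirna_sets(annotated, groups)
  shared <- shared_mirnas(mirna_sets$high, mirna_sets$normal)

  # 7. optional ORA of high-group miRNA targets
  ora <- NULL
  if (!is.null(targets) && !is.null(gene_sets)) {
    query_mirnas <- mirna_sets$high
    if (config$drop_shared_mirnas) query_mirnas <- setdiff(query_mirnas, shared)
    query <- mirna_target_genes(targets, query_mirnas, config$ora_evidence)
    if (length(query) > 0) {
      universe <- unique(c(annotation$gene_id, targets$gene_id))
      ora <- hypergeometric_ora(query, gene_sets, universe)
    }
    log$n_ora_query_genes <- length(query)
  }

  log$config <- unclass(config)
  result <- structure(list(
    burden = dplyr::left_join(burden, groups, by = "sample_id"),
    summary = summary_tab,
    associations = associations,
    mirna_sets = mirna_sets,
    shared_mirnas = shared,
    ora = ora,
    log = log
  ), class = "mircnv_result")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    wt <- function(x, f) utils::write.table(
      x, file.path(out_dir, f), sep = "\t", quote = FALSE, row.names = FALSE, na = "")
    wt(result$burden, "patient_burden.tsv")
    wt(summary_tab, "group_summary.tsv")
    wt(associations, "associations.tsv")
    if (!is.null(ora)) wt(ora, "ora_results.tsv")
  }
  result
}

# One carrier-type comparison: 2x2 counts, one-sided Fisher p, corrected OR.
association_row <- function(grp_burden, name, flag, config) {
  hi <- flag[grp_burden$group == "high"]
  no <- flag[grp_burden$group == "normal"]
  tab <- matrix(c(sum(hi), sum(no), sum(!hi), sum(!no)), nrow = 2)
  orr <- odds_ratio(tab, zero_cell_correction = config$or_correction)
  tibble::tibble(
    comparison = name,
    high_carriers = sum(hi), high_total = length(hi),
    normal_carriers = sum(no), normal_total = length(no),
    p_value = fisher_one_sided(tab, direction = config$fisher_direction),
    or = orr$or, ci_low = orr$ci_low, ci_high = orr$ci_high,
    or_corrected = orr$corrected,
    test = paste0("fisher_one_sided_", config$fisher_direction)
  )
}

#' @export
print.mircnv_result <- function(x, ...) {
  cat("CNV-miRNA burden analysis result\n")
  cat(sprintf("  cohort: %d patients (%d high / %d normal), %d rare calls\n",
              x$log$n_cohort,
              sum(x$burden$group == "high", na.rm = TRUE),
              sum(x$burden$group == "normal", na.rm = TRUE),
              x$log$n_rare_calls))
  en <- x$associations[x$associations$comparison == "mirna_enriched", ]
  cat(sprintf("  miRNA-enriched carriers: %d/%d vs %d/%d, one-sided Fisher p = %.4g\n",
              en$high_carriers, en$high_total, en$normal_carriers,
              en$normal_total, en$p_value))
  invisible(x)
}
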