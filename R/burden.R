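#' Assign patients to pentosidine groups
#'
#' Splits patients into a high ("PEN") and a normal ("non-PEN") group by
#' plasma pentosidine concentration. The boundary is inclusive: a level
#' exactly at the cutoff is classified as high.
#'
#' @param level Plasma pentosidine in ng/mL (positive; `NA` allowed).
#' @param cutoff Group cutoff in ng/mL (default 55.2).
#' @return Character vector with values `"high"`, `"normal"`, or `NA` where
#'   the level is missing (such patients are dropped from group comparisons).
#' @export
classify_pentosidine <- function(level, cutoff = 55.2) {
  stopifnot(cutoff > 0)
  if (any(!is.na(level) & level <= 0)) {
    stop("pentosidine levels must be positive", call. = FALSE)
  }
  ifelse(is.na(level), NA_character_, ifelse(level >= cutoff, "high", "normal"))
}

#' Per-patient CNV burden and miRNA-enrichment classification
#'
#' Aggregates annotated rare CNV calls to one row per patient: total CNV
#' length, the number of distinct genes and miRNA genes hit (unions across
#' the patient's calls, so a gene hit by two CNVs counts once), the miRNA-gene
#' rate (miRNA genes / total genes within CNVs), and the enriched flag
#' (rate >= `enrich_threshold`). Patients with no CNVs, or whose CNVs hit no
#' genes, have an undefined rate and are classified not enriched, so that
#' every cohort member contributes to the group denominators.
#'
#' @param annotated Output of [annotate_cnvs()] (any number of samples).
#' @param sample_ids Optional character vector of all cohort sample ids;
#'   patients absent from `annotated` get a zero-burden row.
#' @param enrich_threshold Minimum miRNA-gene rate counting as a
#'   miRNA-enriched CNV carrier (default 0.5; the boundary is inclusive).
#' @return Tibble with columns `sample_id`, `n_cnvs`, `total_cnv_length_mb`,
#'   `n_genes`, `n_mirnas`, `mirna_rate` (`NA` when no genes), `enriched`.
#' @export
patient_burden <- function(annotated, sample_ids = NULL, enrich_threshold = 0.5) {
  stopifnot(enrich_threshold > 0, enrich_threshold <= 1)
  annotated <- tibble::as_tibble(annotated)
  per_sample <- annotated |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(
      n_cnvs = dplyr::n(),
      total_cnv_length_mb = sum(.data$end - .data$start) / 1e6,
      n_genes = length(unique(unlist(.data$gene_ids))),
      n_mirnas = length(unique(unlist(.data$mirna_ids))),
      .groups = "drop"
    )
  if (!is.null(sample_ids)) {
    missing <- setdiff(sample_ids, per_sample$sample_id)
    if (length(missing) > 0) {
      per_sample <- dplyr::bind_rows(per_sample, tibble::tibble(
        sample_id = missing, n_cnvs = 0L, total_cnv_length_mb = 0,
        n_genes = 0L, n_mirnas = 0L
      ))
    }
    per_sample <- per_sample[match(sample_ids, per_sample$sample_id), , drop = FALSE]
  }
  per_sample$mirna_rate <- ifelse(per_sample$n_genes > 0,
                                  per_sample$n_mirnas / per_sample$n_genes, NA_real_)
  per_sample$enriched <- !is.na(per_sample$mirna_rate) &
    per_sample$mirna_rate >= enrich_threshold
  per_sample
}

#' Fold change between two group statistics
#'
#' Ratio of a case-group value to the control-group value, computed from
#' unrounded inputs (summary tables round the result to one decimal for
#' display only).
#'
#' @param value_case,value_control Numeric scalars or vectors.
#' @return `value_case / value_control`; `NA` where the control value is 0.
#' @export
fold_change <- function(value_case, value_control) {
  ifelse(value_control == 0, NA_real_, value_case / value_control)
}

#' miRNAs observed in both groups
#'
#' Returns the CNV-miRNA identifiers present in both groups' CNVs. miRNAs hit
#' in both arms of a case-control split carry no information about the group
#' contrast, so downstream target and over-representation stages can drop
#' them (the study's miR-4768 rule).
#'
#' @param mirnas_high,mirnas_normal Character vectors (or lists) of miRNA ids
#'   observed within CNVs in each group.
#' @return Sorted character vector of shared ids.
#' @export
shared_mirnas <- function(mirnas_high, mirnas_normal) {
  sort(intersect(unique(unlist(mirnas_high)), unique(unlist(mirnas_normal))))
}

#' Collect the CNV-miRNA id set of each group
#'
#' @param annotated Output of [annotate_cnvs()].
#' @param groups Named character vector (or data frame with `sample_id` and
#'   `group`) mapping sample ids to `"high"`/`"normal"`.
#' @return List with elements `high` and `normal`, each a sorted character
#'   vector of miRNA ids observed within that group's CNVs.
#' @export
group_mirna_sets <- function(annotated, groups) {
  if (is.data.frame(groups)) {
    groups <- stats::setNames(groups$group, groups$sample_id)
  }
  grp <- groups[annotated$sample_id]
  list(
    high = sort(unique(unlist(annotated$mirna_ids[!is.na(grp) & grp == "high"]))),
    normal = sort(unique(unlist(annotated$mirna_ids[!is.na(grp) & grp == "normal"])))
  )
}

#' Group summary of demographics and CNV-miRNA burden
#'
#' Builds the standard case-control summary table: one row per statistic with
#' the per-group values, the group-comparison p-value and, for burden rows,
#' the high/normal fold change. Means and SDs use the sample SD (n - 1).
#' Continuous rows are compared with the pooled two-sided Student's t-test;
#' carrier-type rows (treatment resistance, harbouring a CNV-miRNA,
#' miRNA-enriched) with the one-sided Fisher exact test for excess in the
#' high group. Patients missing a clinical field are dropped pairwise from
#' that row only; fold changes use unrounded means.
#'
#' @param burden Output of [patient_burden()].
#' @param metadata Patient metadata tibble (`sample_id`, `pentosidine`, `age`,
#'   `sex`, `onset_age`, `cpz_equiv`, `treatment_resistant`).
#' @param cutoff Pentosidine cutoff in ng/mL passed to
#'   [classify_pentosidine()].
#' @return Tibble with columns `statistic`, `high`, `normal` (primary value:
#'   mean, count or percentage), `high_sd`, `normal_sd`, `p_value`,
#'   `fold_change`, `test`.
#' @export
group_summary <- function(burden, metadata, cutoff = 55.2) {
  metadata <- tibble::as_tibble(metadata)
  metadata$group <- classify_pentosidine(metadata$pentosidine, cutoff)
  d <- dplyr::inner_join(metadata, burden, by = "sample_id")
  d <- d[!is.na(d$group), , drop = FALSE]
  hi <- d[d$group == "high", , drop = FALSE]
  no <- d[d$group == "normal", , drop = FALSE]

  mean_row <- function(name, var, fc = FALSE) {
    x <- hi[[var]][!is.na(hi[[var]])]
    y <- no[[var]][!is.na(no[[var]])]
    tt <- if (length(x) >= 2 && length(y) >= 2) two_sample_t(x, y) else
      list(p = NA_real_)
    tibble::tibble(
      statistic = name,
      high = mean(x), normal = mean(y),
      high_sd = stats::sd(x), normal_sd = stats::sd(y),
      p_value = tt$p,
      fold_change = if (fc) fold_change(mean(x), mean(y)) else NA_real_,
      test = "t_pooled_two_sided"
    )
  }
  carrier_row <- function(name, flag_hi, flag_no, as_pct = FALSE) {
    flag_hi <- flag_hi[!is.na(flag_hi)]
    flag_no <- flag_no[!is.na(flag_no)]
    tab <- matrix(c(sum(flag_hi), sum(flag_no),
                    sum(!flag_hi), sum(!flag_no)), nrow = 2)
    p <- fisher_one_sided(tab, direction = "greater")
    scale <- function(k, n) if (as_pct) 100 * k / n else k
    tibble::tibble(
      statistic = name,
      high = scale(sum(flag_hi), length(flag_hi)),
      normal = scale(sum(flag_no), length(flag_no)),
      high_sd = NA_real_, normal_sd = NA_real_,
      p_value = p, fold_change = NA_real_,
      test = "fisher_one_sided_greater"
    )
  }
  count_row <- function(name, vhi, vno, fc = FALSE) {
    tibble::tibble(
      statistic = name, high = vhi, normal = vno,
      high_sd = NA_real_, normal_sd = NA_real_, p_value = NA_real_,
      fold_change = if (fc) fold_change(vhi, vno) else NA_real_,
      test = NA_character_
    )
  }

  dplyr::bind_rows(
    count_row("n_patients", nrow(hi), nrow(no)),
    count_row("n_male", sum(hi$sex == "M", na.rm = TRUE), sum(no$sex == "M", na.rm = TRUE)),
    count_row("n_female", sum(hi$sex == "F", na.rm = TRUE), sum(no$sex == "F", na.rm = TRUE)),
    mean_row("age_years", "age"),
    mean_row("onset_age_years", "onset_age"),
    mean_row("pentosidine_ng_ml", "pentosidine"),
    mean_row("cpz_equiv_mg_day", "cpz_equiv"),
    carrier_row("treatment_resistant_pct", hi$treatment_resistant,
                no$treatment_resistant, as_pct = TRUE),
    mean_row("total_cnv_length_mb", "total_cnv_length_mb", fc = TRUE),
    mean_row("genes_within_cnvs", "n_genes", fc = TRUE),
    count_row("total_mirnas_within_cnvs", sum(hi$n_mirnas), sum(no$n_mirnas),
              fc = TRUE),
    carrier_row("patients_harboring_cnv_mirnas", hi$n_mirnas >= 1, no$n_mirnas >= 1),
    carrier_row("patients_harboring_cnv_mirnas_pct", hi$n_mirnas >= 1,
                no$n_mirnas >= 1, as_pct = TRUE),
    mean_row("mirnas_per_patient", "n_mirnas", fc = TRUE),
    carrier_row("patients_mirna_rate_ge_threshold", hi$enriched, no$enriched),
    count_row("patients_mirna_rate_lt_threshold", sum(!hi$enriched), sum(!no$enriched))
  )
}
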