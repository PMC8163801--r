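#' Sample-level quality control of CNV calls
#'
#' Excludes samples whose array QC score exceeds `qc_threshold` (strict
#' inequality: a score exactly at the threshold is retained) or that carry an
#' excessive number of autosomal CNV calls. The per-sample QC score is taken
#' as the maximum `qc_score` over the sample's calls; samples with no recorded
#' score pass the QC-score check.
#'
#' @param calls CNV call table: `sample_id`, `chrom`, `start`, `end`, `state`,
#'   optionally `qc_score`.
#' @param qc_threshold Samples with QC score strictly above this are removed
#'   (default 0.15, the array-variance cut used for NimbleGen CGH QC).
#' @param autosomal_count_limit Either a positive number, or `"auto"` to use
#'   cohort mean + 3 SD of per-sample autosomal call counts. Samples with
#'   strictly more autosomal calls than the limit are removed.
#' @param sex_chroms Chromosome names treated as non-autosomal when counting.
#' @return A list with `retained` (character vector of sample ids), `calls`
#'   (the input restricted to retained samples), and `exclusions` (tibble of
#'   `sample_id`, `reason`, `value`).
#' @export
qc_filter_samples <- function(calls, qc_threshold = 0.15,
                              autosomal_count_limit = "auto",
                              sex_chroms = c("chrX", "chrY", "X", "Y")) {
  stopifnot(qc_threshold > 0)
  calls <- tibble::as_tibble(calls)
  if (!"qc_score" %in% names(calls)) calls$qc_score <- NA_real_

  per_sample <- calls |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(
      qc = if (all(is.na(.data$qc_score))) NA_real_ else max(.data$qc_score, na.rm = TRUE),
      n_autosomal = sum(!.data$chrom %in% sex_chroms),
      .groups = "drop"
    )

  if (identical(autosomal_count_limit, "auto")) {
    cnt <- per_sample$n_autosomal
    autosomal_count_limit <- mean(cnt) + 3 * stats::sd(cnt)
    if (is.na(autosomal_count_limit)) autosomal_count_limit <- Inf
  }

  qc_fail <- !is.na(per_sample$qc) & per_sample$qc > qc_threshold
  count_fail <- per_sample$n_autosomal > autosomal_count_limit

  exclusions <- dplyr::bind_rows(
    tibble::tibble(
      sample_id = per_sample$sample_id[qc_fail],
      reason = "qc_score",
      value = per_sample$qc[qc_fail]
    ),
    tibble::tibble(
      sample_id = per_sample$sample_id[count_fail & !qc_fail],
      reason = "excessive_autosomal_cnvs",
      value = as.numeric(per_sample$n_autosomal[count_fail & !qc_fail])
    )
  )

  retained <- setdiff(per_sample$sample_id, exclusions$sample_id)
  list(
    retained = retained,
    calls = calls[calls$sample_id %in% retained, , drop = FALSE],
    exclusions = exclusions
  )
}

#' Retain rare CNV calls by locus frequency
#'
#' Groups calls into loci by single-linkage clustering: two calls belong to
#' the same locus when they overlap by at least `reciprocal_overlap` of each
#' call's own length (deletions and duplications are pooled). A call is
#' retained when the number of distinct samples carrying its locus, divided by
#' the cohort size, is strictly below `max_frequency`.
#'
#' @param calls CNV call table (`sample_id`, `chrom`, `start`, `end`, ...).
#' @param n_samples Cohort size used as the frequency denominator; defaults to
#'   the number of distinct samples present in `calls`, but should be the full
#'   post-QC cohort size (including CNV-free samples) when known.
#' @param max_frequency Frequency cut: loci at or above this population
#'   frequency are removed (default 0.01, i.e. keep rare < 1% CNVs).
#' @param reciprocal_overlap Minimum mutual overlap fraction linking two calls
#'   into one locus (default 0.5).
#' @return The retained calls with `locus_id`, `locus_n_samples` and
#'   `locus_freq` columns appended.
#' @export
filter_rare_cnvs <- function(calls, n_samples = NULL, max_frequency = 0.01,
                             reciprocal_overlap = 0.5) {
  stopifnot(max_frequency > 0, max_frequency <= 1,
            reciprocal_overlap > 0, reciprocal_overlap <= 1)
  calls <- tibble::as_tibble(calls)
  if (nrow(calls) == 0) {
    return(dplyr::mutate(calls, locus_id = integer(), locus_n_samples = integer(),
                         locus_freq = numeric()))
  }
  validate_interval_table(calls, "filter_rare_cnvs")
  if (is.null(n_samples)) n_samples <- dplyr::n_distinct(calls$sample_id)

  calls$locus_id <- cluster_cnv_loci(calls, reciprocal_overlap)
  locus_stats <- calls |>
    dplyr::group_by(.data$locus_id) |>
    dplyr::summarise(locus_n_samples = dplyr::n_distinct(.data$sample_id),
                     .groups = "drop")
  calls <- dplyr::left_join(calls, locus_stats, by = "locus_id")
  calls$locus_freq <- calls$locus_n_samples / n_samples
  calls[calls$locus_freq < max_frequency, , drop = FALSE]
}

# Single-linkage locus clustering: connected components of the graph whose
# edges join call pairs with >= f reciprocal overlap.
cluster_cnv_loci <- function(calls, reciprocal_overlap) {
  gr <- as_granges0(calls)
  hits <- GenomicRanges::findOverlaps(gr, drop.self = TRUE, drop.redundant = TRUE)
  q <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)
  if (length(q) > 0) {
    ov <- GenomicRanges::width(IRanges::pintersect(
      GenomicRanges::ranges(gr)[q], GenomicRanges::ranges(gr)[s]
    ))
    keep <- ov >= reciprocal_overlap * GenomicRanges::width(gr)[q] &
      ov >= reciprocal_overlap * GenomicRanges::width(gr)[s]
    q <- q[keep]
    s <- s[keep]
  }
  g <- igraph::make_empty_graph(n = nrow(calls), directed = FALSE)
  if (length(q) > 0) g <- igraph::add_edges(g, rbind(q, s))
  as.integer(igraph::components(g)$membership)
}

#' Annotate CNV calls with overlapping genes and miRNA genes
#'
#' For each call, records the identifiers of annotation features overlapping
#' it by at least `min_overlap_bases`, and the subset of those flagged as
#' miRNA genes. Any overlap of one base counts a gene as affected by default.
#'
#' @param calls CNV call table.
#' @param annotation Gene table: `gene_id`, `chrom`, `start`, `end`,
#'   `is_mirna` (logical).
#' @param min_overlap_bases Minimum shared bases for a gene to count
#'   (default 1).
#' @return `calls` with list-columns `gene_ids` and `mirna_ids` plus integer
#'   columns `n_genes` and `n_mirnas`.
#' @export
annotate_cnvs <- function(calls, annotation, min_overlap_bases = 1L) {
  stopifnot(min_overlap_bases >= 1)
  calls <- tibble::as_tibble(calls)
  annotation <- tibble::as_tibble(annotation)
  if (anyDuplicated(annotation$gene_id) > 0) {
    stop("annotation gene_id values must be unique", call. = FALSE)
  }
  if (nrow(calls) == 0) {
    return(dplyr::mutate(calls, gene_ids = list(), mirna_ids = list(),
                         n_genes = integer(), n_mirnas = integer()))
  }
  validate_interval_table(calls, "annotate_cnvs(calls)")
  validate_interval_table(annotation, "annotate_cnvs(annotation)")
  no_shared <- !any(unique(calls$chrom) %in% unique(annotation$chrom))
  if (no_shared) {
    warning("CNV calls and annotation share no chromosome names; ",
            "check naming scheme (e.g. 'chr1' vs '1')", call. = FALSE)
  }

  find_hits <- function() GenomicRanges::findOverlaps(
    as_granges0(calls), as_granges0(annotation),
    minoverlap = as.integer(min_overlap_bases)
  )
  # GenomicRanges emits its own seqlevel warning in this case; ours is clearer
  hits <- if (no_shared) suppressWarnings(find_hits()) else find_hits()
  gene_by_call <- split(
    annotation$gene_id[S4Vectors::subjectHits(hits)],
    factor(S4Vectors::queryHits(hits), levels = seq_len(nrow(calls)))
  )
  is_mir <- annotation$is_mirna[match(unlist(gene_by_call, use.names = FALSE),
                                      annotation$gene_id)]
  mirna_by_call <- split(
    unlist(gene_by_call, use.names = FALSE)[is_mir],
    rep(seq_len(nrow(calls)), lengths(gene_by_call))[is_mir]
  )
  calls$gene_ids <- lapply(unname(gene_by_call), sort)
  calls$mirna_ids <- lapply(seq_len(nrow(calls)), function(i) {
    m <- mirna_by_call[[as.character(i)]]
    if (is.null(m)) character(0) else sort(m)
  })
  calls$n_genes <- lengths(calls$gene_ids)
  calls$n_mirnas <- lengths(calls$mirna_ids)
  calls
}
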