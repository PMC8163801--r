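#' Hypergeometric over-representation analysis
#'
#' Tests each gene set in a collection for over-representation of a query
#' gene list within a gene universe, using the upper hypergeometric tail
#' P(X >= overlap). Query genes and set members outside the universe are
#' dropped (with a message reporting how many). Benjamini-Hochberg q-values
#' are computed across the collection and results are sorted by p-value with
#' set id as the deterministic tie-break.
#'
#' @param query Character vector of query gene ids.
#' @param collection Gene-set collection: either the tibble returned by
#'   [read_gmt()] or a named list of character vectors.
#' @param universe Character vector of all assayable gene ids.
#' @param min_overlap Sets overlapping the query in fewer genes are reported
#'   with `p_value = NA` rather than tested (default 0, i.e. test every set;
#'   a zero overlap then simply gives p = 1).
#' @return Tibble with `set_id`, `description`, `overlap`, `query_size`,
#'   `set_size`, `universe_size`, `frac_of_set`, `frac_of_query`, `p_value`,
#'   `bh_q`, sorted by p-value then set id.
#' @export
hypergeometric_ora <- function(query, collection, universe, min_overlap = 0L) {
  if (length(universe) == 0) stop("empty universe", call. = FALSE)
  if (length(query) == 0) stop("empty query", call. = FALSE)
  universe <- unique(universe)
  query0 <- unique(query)
  query <- intersect(query0, universe)
  if (length(query) < length(query0)) {
    message(length(query0) - length(query), " query gene(s) outside the universe dropped")
  }
  if (length(query) == 0) stop("no query genes in the universe", call. = FALSE)

  if (is.data.frame(collection)) {
    sets <- stats::setNames(collection$genes, collection$set_id)
    descr <- stats::setNames(collection$description, collection$set_id)
  } else {
    sets <- collection
    descr <- stats::setNames(rep(NA_character_, length(sets)), names(sets))
  }
  N <- length(universe)
  q <- length(query)

  res <- lapply(names(sets), function(id) {
    members <- intersect(unique(sets[[id]]), universe)
    m <- length(members)
    k <- length(intersect(query, members))
    p <- if (m == 0 || k < min_overlap) NA_real_ else
      stats::phyper(k - 1, m, N - m, q, lower.tail = FALSE)
    tibble::tibble(
      set_id = id, description = descr[[id]], overlap = k,
      query_size = q, set_size = m, universe_size = N,
      frac_of_set = if (m > 0) k / m else NA_real_,
      frac_of_query = k / q, p_value = p
    )
  })
  res <- dplyr::bind_rows(res)
  res$bh_q <- stats::p.adjust(res$p_value, method = "BH")
  res[order(res$p_value, res$set_id), , drop = FALSE]
}

#' Read a GMT gene-set collection
#'
#' Tab-delimited gene-set format: one set per line, fields set id,
#' description, then member genes. Duplicate members within a set are
#' dropped.
#'
#' @param path Path to a `.gmt` file.
#' @return Tibble with `set_id`, `description` and list-column `genes`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 3)
  if (length(short) > 0) {
    stop(sprintf("%s: line %d has fewer than 3 tab-separated fields",
                 path, short[1]), call. = FALSE)
  }
  ids <- vapply(parts, `[[`, "", 1)
  if (anyDuplicated(ids) > 0) {
    stop(sprintf("%s: duplicate set id '%s'", path, ids[duplicated(ids)][1]),
         call. = FALSE)
  }
  tibble::tibble(
    set_id = ids,
    description = vapply(parts, `[[`, "", 2),
    genes = lapply(parts, function(x) unique(x[-(1:2)]))
  )
}

#' Read a miRNA -> target-gene table
#'
#' Tab-separated file with header columns `mirna_id`, `gene_id` and
#' `evidence` (each row labelled `validated` or `putative`). Duplicate rows
#' are removed; unknown evidence labels are rejected with the offending line
#' number.
#'
#' @param path Path to the TSV file.
#' @param evidence Optional filter: keep only `"validated"` or `"putative"`
#'   rows.
#' @return Tibble with `mirna_id`, `gene_id`, `evidence`.
#' @export
read_mirna_targets <- function(path, evidence = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("mirna_id", "gene_id", "evidence")
  if (!all(need %in% names(df))) {
    stop(sprintf("%s: expected header columns %s", path,
                 paste(need, collapse = ", ")), call. = FALSE)
  }
  bad <- which(!df$evidence %in% c("validated", "putative"))
  if (length(bad) > 0) {
    stop(sprintf("%s: line %d: unknown evidence label '%s'", path,
                 bad[1] + 1L, df$evidence[bad[1]]), call. = FALSE)
  }
  df <- tibble::as_tibble(df[, need])
  dplyr::distinct(df)
}

#' Target genes of a miRNA list
#'
#' Looks up the unique target genes of the given miRNAs in a target table,
#' optionally restricted by evidence class, for use as an ORA query.
#'
#' @param targets Tibble from [read_mirna_targets()].
#' @param mirnas Character vector of miRNA ids.
#' @param evidence Optional `"validated"` or `"putative"` filter.
#' @return Sorted character vector of target gene ids.
#' @export
mirna_target_genes <- function(targets, mirnas, evidence = NULL) {
  keep <- targets$mirna_id %in% mirnas
  if (!is.null(evidence)) {
    evidence <- match.arg(evidence, c("validated", "putative"))
    keep <- keep & targets$evidence == evidence
  }
  sort(unique(targets$gene_id[keep]))
}
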