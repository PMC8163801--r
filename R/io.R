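# Readers and writers for the package's plain-text interchange formats.
# Coordinates are converted to the internal 0-based half-open convention
# exactly once, at the read boundary (GFF3 is 1-based inclusive; BED and the
# CNV TSV are already 0-based half-open).

cnv_header <- c("sample_id", "chrom", "start", "end", "state", "qc_score")

#' Read a CNV call table
#'
#' Accepts either the package's headered TSV
#' (`sample_id chrom start end state qc_score`, 0-based half-open
#' coordinates) or a headerless BED file with 4+ columns where the name field
#' carries the sample id (and an optional 5th column the del/dup state).
#' Negative coordinates or `end <= start` are rejected with the offending
#' line number.
#'
#' @param path Path to the file.
#' @return Tibble with the six CNV call columns.
#' @export
read_cnv_calls <- function(path) {
  first <- readLines(path, n = 1)
  headered <- identical(strsplit(first, "\t")[[1]][1:2], cnv_header[1:2])
  if (headered) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE,
                            colClasses = c(sample_id = "character", chrom = "character"))
    missing_cols <- setdiff(cnv_header[1:5], names(df))
    if (length(missing_cols) > 0) {
      stop(sprintf("%s: missing column(s): %s", path,
                   paste(missing_cols, collapse = ", ")), call. = FALSE)
    }
    if (!"qc_score" %in% names(df)) df$qc_score <- NA_real_
    line <- seq_len(nrow(df)) + 1L
  } else {
    df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                            colClasses = "character")
    if (ncol(df) < 4) {
      stop(sprintf("%s: BED input needs >= 4 columns (chrom start end name)", path),
           call. = FALSE)
    }
    df <- tibble::tibble(
      sample_id = df[[4]], chrom = df[[1]],
      start = as.numeric(df[[2]]), end = as.numeric(df[[3]]),
      state = if (ncol(df) >= 5) normalize_state(df[[5]]) else NA_character_,
      qc_score = NA_real_
    )
    line <- seq_len(nrow(df))
  }
  df$state <- normalize_state(df$state)
  bad_state <- which(!is.na(df$state) & !df$state %in% c("deletion", "duplication"))
  if (length(bad_state) > 0) {
    stop(sprintf("%s: line %d: state must be deletion/del or duplication/dup",
                 path, line[bad_state[1]]), call. = FALSE)
  }
  validate_interval_table(df, path, line)
  tibble::as_tibble(df[, cnv_header])
}

normalize_state <- function(x) {
  x <- tolower(as.character(x))
  x[x == "del"] <- "deletion"
  x[x == "dup"] <- "duplication"
  x
}

#' @rdname read_cnv_calls
#' @param calls CNV call tibble.
#' @export
write_cnv_calls <- function(calls, path) {
  utils::write.table(calls[, cnv_header], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a gene annotation with miRNA flags
#'
#' GFF3 input (`.gff`/`.gff3`): features of type `gene` are kept; the
#' `biotype` attribute value `miRNA` marks miRNA genes; 1-based inclusive
#' coordinates are converted to 0-based half-open. BED-style input
#' (`.bed`/`.tsv`): tab-separated columns
#' `chrom start end gene_id score strand biotype`, already 0-based.
#'
#' @param path Path to the annotation file.
#' @return Annotation tibble: `gene_id`, `chrom`, `start`, `end`, `is_mirna`.
#' @export
read_annotation <- function(path) {
  if (grepl("\\.gff3?$", path, ignore.case = TRUE)) {
    gr <- rtracklayer::import(path)
    gr <- gr[gr$type == "gene"]
    biotype <- if ("biotype" %in% names(S4Vectors::mcols(gr))) gr$biotype
      else rep(NA_character_, length(gr))
    ids <- if (!is.null(gr$ID)) gr$ID else gr$Name
    df <- tibble::tibble(
      gene_id = as.character(ids),
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1,  # 1-based inclusive -> 0-based half-open
      end = as.numeric(GenomicRanges::end(gr)),
      is_mirna = !is.na(biotype) & biotype == "miRNA"
    )
  } else {
    raw <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                             colClasses = "character")
    if (ncol(raw) < 7) {
      stop(sprintf("%s: BED annotation needs 7 columns (chrom start end gene_id score strand biotype)",
                   path), call. = FALSE)
    }
    df <- tibble::tibble(
      gene_id = raw[[4]], chrom = raw[[1]],
      start = as.numeric(raw[[2]]), end = as.numeric(raw[[3]]),
      is_mirna = raw[[7]] == "miRNA"
    )
  }
  if (anyDuplicated(df$gene_id) > 0) {
    stop(sprintf("%s: duplicate gene_id '%s'", path,
                 df$gene_id[duplicated(df$gene_id)][1]), call. = FALSE)
  }
  validate_interval_table(df, path)
  df
}

#' Write an annotation as GFF3
#'
#' Emits `gene` features with `ID` and `biotype` attributes, converting the
#' internal 0-based half-open coordinates back to GFF3's 1-based inclusive.
#'
#' @param annotation Annotation tibble.
#' @param path Output path (`.gff3`).
#' @export
write_annotation_gff3 <- function(annotation, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = annotation$chrom,
    ranges = IRanges::IRanges(start = annotation$start + 1, end = annotation$end),
    type = "gene",
    ID = annotation$gene_id,
    biotype = ifelse(annotation$is_mirna, "miRNA", "protein_coding")
  )
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

meta_header <- c("sample_id", "pentosidine", "age", "sex", "onset_age",
                 "cpz_equiv", "treatment_resistant")

#' Read and write patient metadata
#'
#' Tab-separated with header `sample_id pentosidine age sex onset_age
#' cpz_equiv treatment_resistant`; empty cells mark missing values,
#' `treatment_resistant` is TRUE/FALSE.
#'
#' @param path Path to the TSV file.
#' @return Tibble with the seven metadata columns.
#' @export
read_metadata <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = c("", "NA"),
                          colClasses = c(sample_id = "character", sex = "character"))
  missing_cols <- setdiff(meta_header, names(df))
  if (length(missing_cols) > 0) {
    stop(sprintf("%s: missing column(s): %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  if (anyDuplicated(df$sample_id) > 0) {
    stop(sprintf("%s: duplicate sample_id", path), call. = FALSE)
  }
  bad <- which(!is.na(df$pentosidine) & df$pentosidine <= 0)
  if (length(bad) > 0) {
    stop(sprintf("%s: line %d: pentosidine must be positive", path, bad[1] + 1L),
         call. = FALSE)
  }
  df$treatment_resistant <- as.logical(df$treatment_resistant)
  tibble::as_tibble(df[, meta_header])
}

#' @rdname read_metadata
#' @param metadata Metadata tibble.
#' @export
write_metadata <- function(metadata, path) {
  utils::write.table(metadata[, meta_header], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Write a simulated cohort to an output directory
#'
#' Writes `metadata.tsv`, `cnv_calls.tsv`, `annotation.gff3` and `truth.tsv`
#' so a simulated cohort can be consumed through the same file interfaces as
#' real data.
#'
#' @param cohort A `mircnv_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "mircnv_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_metadata(cohort$metadata, file.path(dir, "metadata.tsv"))
  write_cnv_calls(cohort$calls, file.path(dir, "cnv_calls.tsv"))
  write_annotation_gff3(cohort$annotation, file.path(dir, "annotation.gff3"))
  utils::write.table(cohort$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Plot pentosidine levels by group
#'
#' Strip plot of plasma pentosidine per patient, split at the cutoff and
#' coloured by miRNA-enriched CNV carrier status when a burden table is
#' supplied.
#'
#' @param metadata Metadata tibble.
#' @param burden Optional output of [patient_burden()].
#' @param cutoff Pentosidine cutoff (ng/mL).
#' @return A ggplot object.
#' @export
plot_pentosidine <- function(metadata, burden = NULL, cutoff = 55.2) {
  d <- metadata[!is.na(metadata$pentosidine), , drop = FALSE]
  d$group <- classify_pentosidine(d$pentosidine, cutoff)
  if (!is.null(burden)) {
    d <- dplyr::left_join(d, burden[, c("sample_id", "enriched")], by = "sample_id")
  } else {
    d$enriched <- FALSE
  }
  ggplot2::ggplot(d, ggplot2::aes(x = .data$group, y = .data$pentosidine,
                                  colour = .data$enriched)) +
    ggplot2::geom_jitter(width = 0.2, height = 0, alpha = 0.7) +
    ggplot2::geom_hline(yintercept = cutoff, linetype = "dashed") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "pentosidine group", y = "plasma pentosidine (ng/mL)",
                  colour = "miRNA-enriched CNV") +
    ggplot2::theme_minimal()
}
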