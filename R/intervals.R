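# Genomic intervals are represented throughout as 0-based, half-open
# [start, end) coordinates (BED convention); GFF3 input is converted on read.

#' Overlap length of two genomic intervals
#'
#' Computes the number of bases shared by two half-open intervals
#' `[start1, end1)` and `[start2, end2)`. Intervals on different chromosomes
#' share zero bases. All arguments are vectorised and recycled.
#'
#' @param chrom1,start1,end1 First interval (chromosome, 0-based start,
#'   exclusive end).
#' @param chrom2,start2,end2 Second interval.
#' @return Integer-valued vector of shared base counts (>= 0).
#' @examples
#' overlap_length("chr1", 0, 10, "chr1", 5, 15)  # 5
#' overlap_length("chr1", 0, 10, "chr1", 10, 20) # 0 (half-open adjacency)
#' @export
overlap_length <- function(chrom1, start1, end1, chrom2, start2, end2) {
  check_interval(start1, end1)
  check_interval(start2, end2)
  ov <- pmin(end1, end2) - pmax(start1, start2)
  ifelse(as.character(chrom1) == as.character(chrom2), pmax(ov, 0), 0)
}

# Reject invalid coordinates early; all interval arithmetic assumes validity.
check_interval <- function(start, end) {
  if (any(start < 0)) {
    stop("interval start must be >= 0", call. = FALSE)
  }
  if (any(end <= start)) {
    stop("interval end must be > start (half-open [start, end))", call. = FALSE)
  }
  invisible(TRUE)
}

# Validate a data frame carrying chrom/start/end columns. `where` names the
# source (file path or argument) for the error message; `line` optionally maps
# rows to input line numbers.
validate_interval_table <- function(df, where = "input", line = NULL) {
  bad <- which(df$start < 0 | df$end <= df$start | is.na(df$start) | is.na(df$end))
  if (length(bad) > 0) {
    loc <- if (is.null(line)) paste("row", bad[1]) else paste("line", line[bad[1]])
    stop(sprintf(
      "%s: invalid interval at %s (start=%s, end=%s); need 0 <= start < end",
      where, loc, df$start[bad[1]], df$end[bad[1]]
    ), call. = FALSE)
  }
  invisible(df)
}

# Internal: build an unstranded GRanges from a 0-based half-open table.
# Strand is deliberately dropped: copy-number events are strand-agnostic.
as_granges0 <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
}
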