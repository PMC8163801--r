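# Brute-force oracles kept deliberately independent of the package's
# implementation paths, plus small fixture builders.

# Overlap length by counting shared integer base positions one by one.
bf_overlap_length <- function(chrom1, s1, e1, chrom2, s2, e2) {
  if (chrom1 != chrom2) return(0)
  length(intersect(seq(s1, e1 - 1), seq(s2, e2 - 1)))
}

# O(n^2) single-linkage clustering of calls at >= f reciprocal overlap,
# via repeated label propagation (no graph library).
bf_cluster_loci <- function(calls, f) {
  n <- nrow(calls)
  lab <- seq_len(n)
  link <- function(i, j) {
    if (calls$chrom[i] != calls$chrom[j]) return(FALSE)
    ov <- min(calls$end[i], calls$end[j]) - max(calls$start[i], calls$start[j])
    if (ov <= 0) return(FALSE)
    ov >= f * (calls$end[i] - calls$start[i]) &&
      ov >= f * (calls$end[j] - calls$start[j])
  }
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i != j && link(i, j) && lab[j] != lab[i]) {
        lab[c(i, j)] <- min(lab[i], lab[j])
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(lab, unique(lab))
}

# Linear per-gene scan annotation oracle.
bf_annotate_one <- function(cnv, annotation, min_bases) {
  hit <- vapply(seq_len(nrow(annotation)), function(i) {
    bf_overlap_length(cnv$chrom, cnv$start, cnv$end,
                      annotation$chrom[i], annotation$start[i],
                      annotation$end[i]) >= min_bases
  }, TRUE)
  sort(annotation$gene_id[hit])
}

# One-sided Fisher p by explicit enumeration of every table with the
# observed margins, probabilities from exact binomial coefficients.
bf_fisher_greater <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; k <- a + c; n <- r1 + r2
  xs <- max(0, k - r2):min(r1, k)
  probs <- choose(r1, xs) * choose(r2, k - xs) / choose(n, k)
  sum(probs[xs >= a])
}

# Hypergeometric upper tail by enumerating every possible draw of size q
# from the universe (feasible for |universe| <= 25).
bf_ora_p <- function(universe, set_members, q, k_obs) {
  draws <- utils::combn(universe, q)
  overlaps <- apply(draws, 2, function(d) sum(d %in% set_members))
  mean(overlaps >= k_obs)
}

# Toy fixtures ---------------------------------------------------------------

toy_annotation <- function() {
  tibble::tibble(
    gene_id = c("GENE1", "MIR4300", "GENE2", "MIR100", "GENE3"),
    chrom = c("chr1", "chr1", "chr1", "chr2", "chr2"),
    start = c(100, 1000, 5000, 200, 900),
    end = c(600, 1085, 9000, 280, 4000),
    is_mirna = c(FALSE, TRUE, FALSE, TRUE, FALSE)
  )
}

toy_calls <- function() {
  tibble::tibble(
    sample_id = c("P1", "P1", "P2", "P3"),
    chrom = c("chr1", "chr2", "chr1", "chr2"),
    start = c(950, 100, 4500, 850),
    end = c(1100, 300, 9500, 5000),
    state = c("deletion", "duplication", "deletion", "duplication"),
    qc_score = c(0.05, 0.05, 0.08, 0.02)
  )
}

random_calls <- function(n, n_samples = 10, chroms = c("chr1", "chr2"),
                         max_pos = 2000) {
  start <- sample(max_pos, n, replace = TRUE)
  tibble::tibble(
    sample_id = paste0("S", sample(n_samples, n, replace = TRUE)),
    chrom = sample(chroms, n, replace = TRUE),
    start = start,
    end = start + sample(300, n, replace = TRUE),
    state = sample(c("deletion", "duplication"), n, replace = TRUE),
    qc_score = stats::runif(n, 0, 0.1)
  )
}
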