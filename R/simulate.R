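# Seeded generator of a toy genome annotation and a two-group case-control
# cohort with the statistical structure the burden analysis assumes: a
# pentosidine-defined group split, a background rate of rare CNV carriers,
# and a planted per-group rate of patients whose single CNV covers only a
# miRNA gene (the "miRNA-enriched" signal).

#' Simulation configuration
#'
#' Collects and validates every tunable of the synthetic genome and cohort.
#' Defaults mirror the published study conditions: 94 high-pentosidine and
#' 91 normal-pentosidine patients split at 55.2 ng/mL, a normal group at
#' 39.8 +/- 9.3 ng/mL, a heavy-tailed high group (log-normal moment-matched
#' to mean 128.1, SD 126.0), a ~14% CNV carrier rate, and planted
#' miRNA-only-CNV patient rates of 5/94 versus 0/91.
#'
#' @param seed Integer seed; the genome and cohort are deterministic given it.
#' @param n_high,n_normal Patients per group.
#' @param pentosidine_cutoff Group cutoff in ng/mL.
#' @param pentosidine_normal_mean,pentosidine_normal_sd Normal-group level
#'   (ng/mL), drawn from a normal truncated to (0, cutoff).
#' @param pentosidine_high_mean,pentosidine_high_sd Moments (ng/mL) of the
#'   high-group log-normal before truncation to `>= cutoff`.
#' @param carrier_rate Fraction of patients carrying a rare CNV.
#' @param mirna_only_rate_high,mirna_only_rate_normal Per-group fractions of
#'   patients planted with a CNV covering only a miRNA gene; each must not
#'   exceed `carrier_rate`.
#' @param exact_counts If `TRUE`, plant exactly `round(rate * n)` miRNA-only
#'   patients per group (random identities); if `FALSE` (default) draw
#'   per-patient Bernoulli indicators.
#' @param n_chromosomes,n_genes Toy genome size.
#' @param mirna_fraction Fraction of genes flagged as miRNA genes (Bernoulli
#'   per gene).
#' @param coding_gene_length_range Uniform range (bp) for non-miRNA genes.
#' @param mirna_gene_length_range Uniform range (bp) for miRNA genes (real
#'   miRNA genes are ~100 bp).
#' @param intergenic_mean Mean (bp) of exponential intergenic gaps.
#' @param cnv_length_meanlog,cnv_length_sdlog Log-normal parameters of
#'   background CNV lengths.
#' @param cnv_length_range Truncation range (bp) for background CNV lengths;
#'   the lower bound keeps background CNVs spanning many genes so that a
#'   miRNA-majority CNV essentially only arises when planted.
#' @return Validated list of class `mircnv_sim_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_high = 94L, n_normal = 91L,
                              pentosidine_cutoff = 55.2,
                              pentosidine_normal_mean = 39.8,
                              pentosidine_normal_sd = 9.3,
                              pentosidine_high_mean = 128.1,
                              pentosidine_high_sd = 126.0,
                              carrier_rate = 0.14,
                              mirna_only_rate_high = 5 / 94,
                              mirna_only_rate_normal = 0,
                              exact_counts = FALSE,
                              n_chromosomes = 5L,
                              n_genes = 2000L,
                              mirna_fraction = 0.08,
                              coding_gene_length_range = c(5e3, 5e4),
                              mirna_gene_length_range = c(60, 150),
                              intergenic_mean = 3e4,
                              cnv_length_meanlog = log(6e5),
                              cnv_length_sdlog = 0.5,
                              cnv_length_range = c(3e5, 3e6)) {
  cfg <- as.list(environment())
  fracs <- c(carrier_rate, mirna_only_rate_high, mirna_only_rate_normal,
             mirna_fraction)
  if (any(fracs < 0 | fracs > 1)) {
    stop("rates and fractions must lie in [0, 1]", call. = FALSE)
  }
  if (mirna_only_rate_high > carrier_rate || mirna_only_rate_normal > carrier_rate) {
    stop("miRNA-only CNV rate cannot exceed the carrier rate", call. = FALSE)
  }
  stopifnot(n_high > 0, n_normal > 0, n_chromosomes > 0, n_genes > 0,
            pentosidine_cutoff > 0, intergenic_mean > 0,
            cnv_length_range[1] > 0, cnv_length_range[2] > cnv_length_range[1])
  structure(cfg, class = "mircnv_sim_config")
}

#' Simulate a toy genome annotation
#'
#' Lays non-overlapping genes along `n_chromosomes` chromosomes (round-robin)
#' separated by exponential intergenic gaps. A configured fraction of genes
#' is flagged as miRNA genes, which are short (~100 bp) as in real genomes;
#' the rest are protein-coding-sized. Deterministic given `seed`.
#'
#' @param config A [simulation_config()].
#' @param seed Seed; defaults to `config$seed`.
#' @return Annotation tibble: `gene_id`, `chrom`, `start`, `end`, `is_mirna`
#'   (0-based half-open coordinates).
#' @export
simulate_genome <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "mircnv_sim_config"))
  withr::with_seed(seed, {
    n <- config$n_genes
    is_mirna <- stats::runif(n) < config$mirna_fraction
    len <- ifelse(
      is_mirna,
      round(stats::runif(n, config$mirna_gene_length_range[1],
                         config$mirna_gene_length_range[2])),
      round(stats::runif(n, config$coding_gene_length_range[1],
                         config$coding_gene_length_range[2]))
    )
    gap <- round(stats::rexp(n, 1 / config$intergenic_mean)) + 1000
    chrom_idx <- rep(seq_len(config$n_chromosomes), length.out = n)
    start <- numeric(n)
    for (ch in seq_len(config$n_chromosomes)) {
      i <- which(chrom_idx == ch)
      start[i] <- cumsum(gap[i] + len[i]) - len[i]
    }
    mir_n <- cumsum(is_mirna)
    cod_n <- cumsum(!is_mirna)
    tibble::tibble(
      gene_id = ifelse(is_mirna, sprintf("MIR%04d", mir_n),
                       sprintf("GENE%04d", cod_n)),
      chrom = paste0("chr", chrom_idx),
      start = start,
      end = start + len,
      is_mirna = is_mirna
    )
  })
}

#' Simulate a two-group case-control cohort
#'
#' Draws patient metadata and rare CNV calls with a planted group difference
#' in miRNA-only CNVs. High-group pentosidine is log-normal (truncated at the
#' cutoff), normal-group pentosidine truncated normal below the cutoff, so
#' the pipeline's cutoff classification recovers the generating groups
#' exactly. Carrier patients receive one CNV: planted patients a CNV covering
#' exactly one miRNA gene and nothing else (each planted patient a distinct
#' miRNA gene, so planted loci stay rare), other carriers a CNV of
#' log-normal length placed uniformly.
#'
#' @param config A [simulation_config()].
#' @param annotation Output of [simulate_genome()] (or any annotation tibble).
#' @param seed Seed; defaults to `config$seed`.
#' @return List of class `mircnv_cohort` with `metadata` (patient table),
#'   `calls` (CNV call table), `annotation`, and `truth` (per-patient ground
#'   truth: `group`, `carrier`, `planted_mirna_only`).
#' @export
simulate_cohort <- function(config, annotation, seed = config$seed) {
  stopifnot(inherits(config, "mircnv_sim_config"))
  withr::with_seed(seed, {
    n <- config$n_high + config$n_normal
    group <- rep(c("high", "normal"), c(config$n_high, config$n_normal))
    sample_id <- sprintf("S%03d", seq_len(n))

    metadata <- tibble::tibble(
      sample_id = sample_id,
      pentosidine = ifelse(
        group == "high",
        rlnorm_trunc(n, config$pentosidine_high_mean, config$pentosidine_high_sd,
                     lower = config$pentosidine_cutoff),
        rnorm_trunc(n, config$pentosidine_normal_mean,
                    config$pentosidine_normal_sd,
                    lower = 1e-6, upper = config$pentosidine_cutoff - 1e-6)
      ),
      age = round(pmax(stats::rnorm(n, ifelse(group == "high", 52.0, 47.0),
                                    ifelse(group == "high", 11.2, 14.1)), 18)),
      sex = ifelse(stats::runif(n) < 0.52, "M", "F"),
      onset_age = NA_real_,
      cpz_equiv = round(pmax(stats::rnorm(n, ifelse(group == "high", 1147.6, 716.4),
                                          ifelse(group == "high", 864.0, 607.7)), 25)),
      treatment_resistant = ifelse(
        stats::runif(n) < 0.53,
        stats::runif(n) < ifelse(group == "high", 0.393, 0.119),
        NA
      )
    )
    metadata$onset_age <- round(pmin(
      pmax(stats::rnorm(n, 25.5, 9), 12), metadata$age))

    planted <- plant_indicator(config, group)
    u <- stats::runif(n)
    carrier <- planted | (u < (config$carrier_rate - mean_rate(config, group)) /
                            pmax(1 - mean_rate(config, group), 1e-12))

    mir_genes <- annotation[annotation$is_mirna, , drop = FALSE]
    if (sum(planted) > nrow(mir_genes)) {
      stop("not enough miRNA genes to plant distinct miRNA-only CNVs",
           call. = FALSE)
    }
    planted_gene_rows <- sample(nrow(mir_genes), sum(planted))

    chrom_len <- tapply(annotation$end, annotation$chrom, max) + 5e4
    calls <- list()
    k <- 0
    for (i in seq_len(n)) {
      if (!carrier[i]) next
      k <- k + 1
      if (planted[i]) {
        row <- mir_genes[planted_gene_rows[match(i, which(planted))], ]
        iv <- mirna_only_interval(row, annotation)
      } else {
        len <- rlnorm_range(1, config$cnv_length_meanlog, config$cnv_length_sdlog,
                            config$cnv_length_range)
        chrom <- sample(names(chrom_len), 1)
        start <- floor(stats::runif(1, 0, max(chrom_len[[chrom]] - len, 1)))
        iv <- list(chrom = chrom, start = start, end = start + len)
      }
      calls[[k]] <- tibble::tibble(
        sample_id = sample_id[i], chrom = iv$chrom, start = iv$start,
        end = iv$end, state = sample(c("deletion", "duplication"), 1),
        qc_score = round(stats::runif(1, 0.01, 0.10), 3)
      )
    }
    calls <- if (k > 0) dplyr::bind_rows(calls) else tibble::tibble(
      sample_id = character(), chrom = character(), start = numeric(),
      end = numeric(), state = character(), qc_score = numeric()
    )

    structure(list(
      metadata = metadata,
      calls = calls,
      annotation = annotation,
      truth = tibble::tibble(sample_id = sample_id, group = group,
                             carrier = carrier, planted_mirna_only = planted)
    ), class = "mircnv_cohort")
  })
}

# Per-patient planted miRNA-only indicator, exact or Bernoulli per group.
plant_indicator <- function(config, group) {
  rate <- ifelse(group == "high", config$mirna_only_rate_high,
                 config$mirna_only_rate_normal)
  if (config$exact_counts) {
    planted <- rep(FALSE, length(group))
    for (g in c("high", "normal")) {
      idx <- which(group == g)
      k <- round(unique(rate[group == g])[1] * length(idx))
      if (k > 0) planted[sample(idx, k)] <- TRUE
    }
    planted
  } else {
    stats::runif(length(group)) < rate
  }
}

mean_rate <- function(config, group) {
  ifelse(group == "high", config$mirna_only_rate_high,
         config$mirna_only_rate_normal)
}

# CNV spanning one miRNA gene but none of its neighbours: pad into the
# flanking intergenic gaps, stopping short of the adjacent genes.
mirna_only_interval <- function(gene_row, annotation) {
  same_chrom <- annotation[annotation$chrom == gene_row$chrom, , drop = FALSE]
  prev_end <- suppressWarnings(max(same_chrom$end[same_chrom$end <= gene_row$start]))
  next_start <- suppressWarnings(min(same_chrom$start[same_chrom$start >= gene_row$end]))
  lo <- if (is.finite(prev_end)) prev_end else max(gene_row$start - 5e3, 0)
  hi <- if (is.finite(next_start)) next_start else gene_row$end + 5e3
  start <- floor(stats::runif(1, lo, gene_row$start))
  end <- ceiling(stats::runif(1, gene_row$end, hi))
  list(chrom = gene_row$chrom, start = start, end = end)
}

# Truncated draws by rejection; moments are of the untruncated distribution.
rnorm_trunc <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < lower | out > upper)
  while (length(bad) > 0) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < lower | out[bad] > upper]
  }
  out
}

rlnorm_trunc <- function(n, mean, sd, lower = 0) {
  # moment-match a log-normal to the given mean/SD, then truncate below
  cv2 <- (sd / mean)^2
  sdlog <- sqrt(log(1 + cv2))
  meanlog <- log(mean) - log(1 + cv2) / 2
  out <- stats::rlnorm(n, meanlog, sdlog)
  bad <- which(out < lower)
  while (length(bad) > 0) {
    out[bad] <- stats::rlnorm(length(bad), meanlog, sdlog)
    bad <- bad[out[bad] < lower]
  }
  out
}

rlnorm_range <- function(n, meanlog, sdlog, range) {
  out <- stats::rlnorm(n, meanlog, sdlog)
  pmin(pmax(round(out), range[1]), range[2])
}
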