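test_that("pentosidine classification is cutoff-inclusive for the high group", {
  expect_equal(classify_pentosidine(505.433), "high")
  expect_equal(classify_pentosidine(39.8), "normal")
  expect_equal(classify_pentosidine(55.2), "high")   # boundary
  expect_equal(classify_pentosidine(NA), NA_character_)
  expect_error(classify_pentosidine(-3), "positive")
})

test_that("a patient whose single CNV hits only a miRNA gene is enriched", {
  ann <- toy_annotation()
  cnv <- tibble::tibble(sample_id = "P1", chrom = "chr1", start = 950,
                        end = 1100, state = "deletion", qc_score = NA_real_)
  b <- patient_burden(annotate_cnvs(cnv, ann))
  expect_equal(b$n_genes, 1L)
  expect_equal(b$n_mirnas, 1L)
  expect_equal(b$mirna_rate, 1)
  expect_true(b$enriched)
  expect_equal(b$total_cnv_length_mb, 150 / 1e6)
})

test_that("patients without CNVs or without genes get rate NA and enriched FALSE", {
  ann <- toy_annotation()
  cnv <- tibble::tibble(sample_id = "P1", chrom = "chr1", start = 20000,
                        end = 21000, state = "deletion", qc_score = NA_real_)
  b <- patient_burden(annotate_cnvs(cnv, ann), sample_ids = c("P1", "P2"))
  expect_equal(b$sample_id, c("P1", "P2"))
  expect_equal(b$n_cnvs, c(1L, 0L))
  expect_true(all(is.na(b$mirna_rate)))
  expect_false(any(b$enriched))
})

test_that("gene counts are unions across a patient's CNVs (no double count)", {
  ann <- toy_annotation()
  cnvs <- tibble::tibble(
    sample_id = "P1", chrom = "chr1",
    start = c(4500, 8000), end = c(6000, 9500),  # both overlap GENE2
    state = "deletion", qc_score = NA_real_
  )
  antd <- annotate_cnvs(cnvs, ann)
  b <- patient_burden(antd)
  # brute-force set union over per-CNV gene lists
  expect_equal(b$n_genes, length(unique(unlist(antd$gene_ids))))
  expect_equal(b$n_genes, 1L)
  expect_equal(b$total_cnv_length_mb, 3000 / 1e6)
})

test_that("raising the enrichment threshold only ever shrinks the enriched set", {
  withr::with_seed(3, {
    ann <- toy_annotation()
    calls <- random_calls(30, n_samples = 12, max_pos = 9000)
    antd <- annotate_cnvs(calls, ann)
    b1 <- patient_burden(antd, enrich_threshold = 0.5)
    b2 <- patient_burden(antd, enrich_threshold = 0.51)
    expect_true(all(b1$enriched | !b2$enriched))
    expect_lte(sum(b2$enriched), sum(b1$enriched))
  })
})

test_that("fold change reproduces the published ratios from unrounded inputs", {
  expect_equal(round(fold_change(205, 21), 1), 9.8)
  expect_equal(round(fold_change(92.2, 4.5), 1), 20.5)
  expect_true(is.na(fold_change(3, 0)))
})

test_that("shared miRNAs are the intersection of the two group sets", {
  expect_equal(shared_mirnas(c("miR-4300", "miR-4768"), "miR-4768"), "miR-4768")
  expect_length(shared_mirnas(c("a", "b"), c("c", "d")), 0)
  withr::with_seed(11, {
    for (i in 1:20) {
      x <- sample(letters, sample(1:10, 1))
      y <- sample(letters, sample(1:10, 1))
      want <- sort(unique(letters[letters %in% x & letters %in% y]))
      expect_equal(shared_mirnas(x, y), want)
    }
  })
})

test_that("group summary matches hand-computed values on a 3+2 patient toy", {
  burden <- tibble::tibble(
    sample_id = paste0("S", 1:5),
    n_cnvs = c(1L, 1L, 0L, 1L, 0L),
    total_cnv_length_mb = c(0.5, 1.0, 0, 0.3, 0),
    n_genes = c(2L, 1L, 0L, 4L, 0L),
    n_mirnas = c(1L, 1L, 0L, 1L, 0L),
    mirna_rate = c(0.5, 1, NA, 0.25, NA),
    enriched = c(TRUE, TRUE, FALSE, FALSE, FALSE)
  )
  metadata <- tibble::tibble(
    sample_id = paste0("S", 1:5),
    pentosidine = c(100, 60, 70, 40, 30),  # S1-S3 high, S4-S5 normal
    age = c(50, 60, 40, 30, 50),
    sex = c("M", "F", "M", "M", "F"),
    onset_age = c(20, 25, 30, 22, 28),
    cpz_equiv = c(1000, 500, 750, 600, 400),
    treatment_resistant = c(TRUE, NA, FALSE, FALSE, FALSE)
  )
  s <- group_summary(burden, metadata)
  row <- function(st) s[s$statistic == st, ]
  expect_equal(row("n_patients")$high, 3)
  expect_equal(row("n_patients")$normal, 2)
  expect_equal(row("age_years")$high, 50)
  expect_equal(row("age_years")$high_sd, 10)        # sd of (50,60,40), n-1
  expect_equal(row("age_years")$normal, 40)
  expect_equal(row("age_years")$normal_sd, sd(c(30, 50)))
  expect_equal(row("total_mirnas_within_cnvs")$high, 2)  # S1 + S2
  expect_equal(row("total_mirnas_within_cnvs")$normal, 1)
  expect_equal(row("total_mirnas_within_cnvs")$fold_change, 2)
  expect_equal(row("patients_harboring_cnv_mirnas")$high, 2)
  expect_equal(row("patients_harboring_cnv_mirnas_pct")$high, 200 / 3)
  expect_equal(row("patients_mirna_rate_ge_threshold")$high, 2)
  expect_equal(row("patients_mirna_rate_lt_threshold")$high, 1)
  # enriched + not-enriched partition each group
  expect_equal(row("patients_mirna_rate_ge_threshold")$high +
                 row("patients_mirna_rate_lt_threshold")$high,
               row("n_patients")$high)
  # treatment resistance: NA dropped pairwise (1/2 high, 0/2 normal)
  expect_equal(row("treatment_resistant_pct")$high, 50)
  expect_equal(row("treatment_resistant_pct")$normal, 0)
  # age p-value equals the pooled t-test computed directly
  tt <- stats::t.test(c(50, 60, 40), c(30, 50), var.equal = TRUE)
  expect_equal(row("age_years")$p_value, tt$p.value)
  # conservation: total miRNAs equals the per-patient sum
  expect_equal(row("total_mirnas_within_cnvs")$high + row("total_mirnas_within_cnvs")$normal,
               sum(burden$n_mirnas))
})

test_that("the harbouring-count example reproduces the published row", {
  # 13 of 94 patients harbouring a CNV-miRNA -> 13 (13.8%)
  n_mirnas <- c(rep(1L, 13), rep(0L, 81))
  expect_equal(sum(n_mirnas >= 1), 13)
  expect_equal(round(100 * mean(n_mirnas >= 1), 1), 13.8)
})
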