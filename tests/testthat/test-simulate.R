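small_cfg <- function(...) {
  simulation_config(seed = 17, n_genes = 600, n_chromosomes = 3, ...)
}

test_that("configuration validation rejects inconsistent rates", {
  expect_error(simulation_config(carrier_rate = 0.05, mirna_only_rate_high = 0.1),
               "carrier rate")
  expect_error(simulation_config(carrier_rate = 1.2), "0, 1")
  expect_silent(simulation_config())
})

test_that("genome simulation is deterministic and respects the miRNA fraction", {
  cfg <- small_cfg()
  g1 <- simulate_genome(cfg)
  g2 <- simulate_genome(cfg)
  expect_identical(g1, g2)
  expect_false(identical(g1, simulate_genome(cfg, seed = 18)))
  # genes valid and non-overlapping per chromosome
  expect_true(all(g1$end > g1$start))
  by_chr <- split(g1, g1$chrom)
  for (d in by_chr) {
    d <- d[order(d$start), ]
    expect_true(all(d$start[-1] >= d$end[-nrow(d)]))
  }
  # zero fraction: no miRNA genes
  g0 <- simulate_genome(small_cfg(mirna_fraction = 0))
  expect_equal(sum(g0$is_mirna), 0)
  # fraction 0.1 with 1000 genes: count within the exact binomial 99% interval
  gf <- simulate_genome(simulation_config(seed = 4, n_genes = 1000,
                                          mirna_fraction = 0.1))
  lims <- stats::qbinom(c(0.005, 0.995), 1000, 0.1)
  expect_gte(sum(gf$is_mirna), lims[1])
  expect_lte(sum(gf$is_mirna), lims[2])
})

test_that("cohort simulation is deterministic and internally consistent", {
  cfg <- small_cfg()
  ann <- simulate_genome(cfg)
  c1 <- simulate_cohort(cfg, ann)
  c2 <- simulate_cohort(cfg, ann)
  expect_identical(c1$metadata, c2$metadata)
  expect_identical(c1$calls, c2$calls)
  # every CNV belongs to a known sample; truth covers the whole cohort
  expect_true(all(c1$calls$sample_id %in% c1$metadata$sample_id))
  expect_equal(nrow(c1$truth), cfg$n_high + cfg$n_normal)
  # groups recoverable from pentosidine by construction
  got <- classify_pentosidine(c1$metadata$pentosidine, cfg$pentosidine_cutoff)
  expect_equal(got, c1$truth$group)
  # carriers and only carriers have calls
  expect_setequal(unique(c1$calls$sample_id),
                  c1$truth$sample_id[c1$truth$carrier])
})

test_that("zero carrier rate gives a CNV-free cohort", {
  cfg <- small_cfg(carrier_rate = 0, mirna_only_rate_high = 0)
  co <- simulate_cohort(cfg, simulate_genome(cfg))
  expect_equal(nrow(co$calls), 0)
})

test_that("every planted patient's CNV covers exactly one miRNA gene", {
  cfg <- small_cfg(exact_counts = TRUE)
  ann <- simulate_genome(cfg)
  co <- simulate_cohort(cfg, ann)
  planted <- co$truth$sample_id[co$truth$planted_mirna_only]
  expect_equal(length(planted), round(5 / 94 * 94))
  antd <- annotate_cnvs(co$calls, ann)
  b <- patient_burden(antd, sample_ids = co$metadata$sample_id)
  expect_true(all(b$mirna_rate[b$sample_id %in% planted] == 1))
  expect_true(all(b$enriched[b$sample_id %in% planted]))
})

test_that("exact-count planting hits the requested per-group counts", {
  cfg <- small_cfg(exact_counts = TRUE, mirna_only_rate_high = 5 / 94,
                   mirna_only_rate_normal = 2 / 91)
  co <- simulate_cohort(cfg, simulate_genome(cfg))
  tr <- co$truth
  expect_equal(sum(tr$planted_mirna_only & tr$group == "high"), 5)
  expect_equal(sum(tr$planted_mirna_only & tr$group == "normal"), 2)
})

test_that("pipeline-recovered enriched counts track the planted rates", {
  cfg <- small_cfg(mirna_only_rate_high = 0.15, mirna_only_rate_normal = 0.05,
                   carrier_rate = 0.2)
  ann <- simulate_genome(cfg)
  tot_hi <- 0; tot_no <- 0; n_seeds <- 25
  for (i in seq_len(n_seeds)) {
    co <- simulate_cohort(cfg, ann, seed = 5000 + i)
    b <- patient_burden(annotate_cnvs(co$calls, ann),
                        sample_ids = co$metadata$sample_id)
    tot_hi <- tot_hi + sum(b$enriched[co$truth$group == "high"])
    tot_no <- tot_no + sum(b$enriched[co$truth$group == "normal"])
  }
  # binomial 99.9% bounds around the planted rates
  n1 <- n_seeds * cfg$n_high; n2 <- n_seeds * cfg$n_normal
  expect_gte(tot_hi, qbinom(5e-4, n1, 0.15))
  expect_lte(tot_hi, qbinom(1 - 5e-4, n1, 0.15) + 3)  # spurious hits possible
  expect_gte(tot_no, qbinom(5e-4, n2, 0.05))
  expect_lte(tot_no, qbinom(1 - 5e-4, n2, 0.05) + 3)
})

test_that("pentosidine levels respect the cutoff split and group spread", {
  cfg <- small_cfg()
  co <- simulate_cohort(cfg, simulate_genome(cfg))
  hi <- co$metadata$pentosidine[co$truth$group == "high"]
  no <- co$metadata$pentosidine[co$truth$group == "normal"]
  expect_true(all(hi >= cfg$pentosidine_cutoff))
  expect_true(all(no > 0 & no < cfg$pentosidine_cutoff))
  expect_gt(mean(hi), mean(no))
})
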