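tab <- function(a, b, c, d) matrix(c(a, c, b, d), nrow = 2)

test_that("one-sided Fisher reproduces the headline enrichment p-value", {
  expect_equal(round(fisher_one_sided(tab(5, 89, 0, 91)), 3), 0.032)
  expect_equal(fisher_one_sided(tab(0, 94, 0, 91)), 1)
})

test_that("Fisher p agrees with stats::fisher.test and the enumeration oracle", {
  withr::with_seed(21, {
    for (i in 1:60) {
      t <- tab(sample(0:8, 1), sample(0:8, 1), sample(0:8, 1), sample(0:8, 1))
      if (sum(t) == 0) next
      got <- fisher_one_sided(t, "greater")
      expect_equal(got, stats::fisher.test(t, alternative = "greater")$p.value,
                   tolerance = 1e-9)
      expect_equal(got, bf_fisher_greater(t[1, 1], t[1, 2], t[2, 1], t[2, 2]),
                   tolerance = 1e-12)
      expect_equal(fisher_one_sided(t, "less"),
                   stats::fisher.test(t, alternative = "less")$p.value,
                   tolerance = 1e-9)
    }
  })
})

test_that("Fisher tail and symmetry invariants hold", {
  withr::with_seed(33, {
    for (i in 1:25) {
      t <- tab(sample(0:10, 1), sample(0:10, 1), sample(0:10, 1), sample(0:10, 1))
      if (sum(t) == 0) next
      # the two opposite tails share the observed table's probability
      expect_gte(fisher_one_sided(t, "greater") +
                   fisher_one_sided(t[2:1, ], "greater"), 1 - 1e-12)
      # invariant to swapping both rows and both columns simultaneously
      expect_equal(fisher_one_sided(t, "greater"),
                   fisher_one_sided(t[2:1, 2:1], "greater"), tolerance = 1e-12)
    }
  })
})

test_that("Fisher is numerically stable at large counts", {
  t <- tab(520, 499480, 380, 499620)
  expect_equal(fisher_one_sided(t, "greater"),
               stats::fisher.test(t, alternative = "greater")$p.value,
               tolerance = 1e-6)
})

test_that("zero-cell correction reproduces the published odds ratios", {
  r1 <- odds_ratio(tab(1, 93, 0, 91))
  expect_equal(round(r1$or, 2), 2.94)
  expect_true(r1$corrected)
  r2 <- odds_ratio(tab(2, 92, 0, 91))
  expect_equal(round(r2$or, 2), 4.95)
  # no zero cell: correction does not fire
  r3 <- odds_ratio(tab(1, 1, 1, 1))
  expect_equal(r3$or, 1)
  expect_false(r3$corrected)
  expect_error(odds_ratio(tab(1, 93, 0, 91), zero_cell_correction = FALSE),
               "zero cell")
})

test_that("odds ratio transposition and CI invariants hold", {
  withr::with_seed(55, {
    for (i in 1:25) {
      t <- tab(sample(0:9, 1), sample(0:9, 1), sample(0:9, 1), sample(0:9, 1))
      r <- odds_ratio(t)
      expect_equal(odds_ratio(t(t))$or, r$or, tolerance = 1e-12)
      expect_equal(odds_ratio(t[2:1, ])$or, 1 / r$or, tolerance = 1e-12)
      expect_lte(r$ci_low, r$or)
      expect_gte(r$ci_high, r$or)
      wider <- odds_ratio(t, conf_level = 0.99)
      expect_lte(wider$ci_low, r$ci_low)
      expect_gte(wider$ci_high, r$ci_high)
    }
  })
})

test_that("two-sample t handles identical groups and matches t.test", {
  expect_equal(two_sample_t(c(1, 2, 3), c(1, 2, 3))$p, 1)
  same <- list(mean = 5, sd = 2, n = 10)
  expect_equal(two_sample_t(same, same)$t, 0)
  expect_equal(two_sample_t(same, same)$p, 1)
  withr::with_seed(77, {
    for (i in 1:20) {
      x <- rnorm(sample(3:12, 1)); y <- rnorm(sample(3:12, 1), mean = 0.5)
      got <- two_sample_t(x, y)
      want <- stats::t.test(x, y, var.equal = TRUE)
      expect_equal(got$t, unname(want$statistic), tolerance = 1e-12)
      expect_equal(got$df, unname(want$parameter))
      expect_equal(got$p, want$p.value, tolerance = 1e-12)
      gotw <- two_sample_t(x, y, variant = "welch")
      wantw <- stats::t.test(x, y)
      expect_equal(gotw$p, wantw$p.value, tolerance = 1e-12)
      # summary mode reproduces raw mode exactly
      gs <- two_sample_t(list(mean = mean(x), sd = sd(x), n = length(x)),
                         list(mean = mean(y), sd = sd(y), n = length(y)))
      expect_equal(gs$p, got$p, tolerance = 1e-12)
    }
  })
})

test_that("published summary-mode comparisons give sensible p-values", {
  # pentosidine 128.1 +/- 126.0 (n=94) vs 39.8 +/- 9.3 (n=91): p ~ 5e-10
  p <- two_sample_t(list(mean = 128.1, sd = 126.0, n = 94),
                    list(mean = 39.8, sd = 9.3, n = 91))$p
  expect_lt(p, 1e-8)
  # CNV length 3.6 +/- 21.9 vs 0.4 +/- 0.5: not significant
  p2 <- two_sample_t(list(mean = 3.6, sd = 21.9, n = 94),
                     list(mean = 0.4, sd = 0.5, n = 91))$p
  expect_gt(p2, 0.05)
})
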