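# mircnv

Case-control burden analysis of microRNA genes inside rare copy number
variants (CNVs).

## The problem

Rare CNVs can delete or duplicate miRNA genes, and because a single miRNA
post-transcriptionally regulates many targets, a CNV affecting *only* a
miRNA gene can matter far beyond its size. A recurring clinical-genetics
design asks whether one patient group carries more **miRNA-enriched CNVs**
than another — here, schizophrenia patients with high versus normal plasma
pentosidine (an advanced glycation end product; cohort split at 55.2
ng/mL). `mircnv` is for analysts running that design: it takes per-sample
CNV calls, a gene annotation with miRNA flags, and patient metadata, and
produces the per-patient burden table, the group summary, and the exact
group-comparison statistics.

A patient is a miRNA-enriched CNV carrier when, over the union of their
rare CNVs,

```
miRNA-gene rate = (# distinct miRNA genes in CNVs) / (# distinct genes in CNVs) >= 0.5
```

and the groups are compared with the one-sided Fisher exact test
`P(X >= a)` under fixed margins. Sparse carrier tables get the
Haldane–Anscombe correction (0.5 added to all four cells when any is zero)
before the odds ratio and its Wald interval
`exp(ln OR ± z·sqrt(Σ 1/n_ij))`. A dominant-model power calculator
(penetrances solved from prevalence K, allele frequency p and genotype
relative risk γ under Hardy–Weinberg, carrier-collapsed two-proportion
test) and a hypergeometric over-representation module for miRNA target
genes round out the workflow. A seeded simulator generates cohorts with
the same structure so the whole pipeline is testable without patient data.

## Worked example

```r
library(mircnv)

cfg    <- simulation_config(seed = 1, exact_counts = TRUE)  # 94 vs 91 patients,
ann    <- simulate_genome(cfg)                              # 5/94 vs 0/91 planted
cohort <- simulate_cohort(cfg, ann)
res    <- run_pipeline(cohort$calls, ann, cohort$metadata)
res
#> CNV-miRNA burden analysis result
#>   cohort: 185 patients (94 high / 91 normal), 27 rare calls
#>   miRNA-enriched carriers: 5/94 vs 0/91, one-sided Fisher p = 0.0321
```

The pipeline recovered exactly the planted 5/94 vs 0/91 miRNA-only-CNV
patients; p = 0.0321 says that under fixed margins, tables at least this
extreme arise ~3.2% of the time by chance. The statistics are also usable
directly on published counts:

```r
fisher_one_sided(matrix(c(5, 0, 89, 91), nrow = 2))
#> [1] 0.03209903

odds_ratio(matrix(c(1, 0, 93, 91), nrow = 2))   # single carrier vs none
#> $or 2.935829   $ci_low 0.1180592   $ci_high 73.00649   $corrected TRUE

association_power(0.007, 0.05, grr_from_or(5), "dominant",
                  n_cases = 94, n_controls = 91)
#> [1] 0.9897525
```

(The corrected OR of 2.94 with its wide CI is what a 1-vs-0 carrier table
can support; the power call shows the calculator's interface — published
power figures require the CNV's population allele frequency, so supply
your own `risk_allele_freq`.) `run_pipeline()` also accepts file paths
(CNV TSV/BED, GFF3/BED annotation, metadata TSV, GMT gene sets, miRNA
target TSV) and writes all result tables to `out_dir`;
`inst/scripts/run_pipeline.R` wraps it for shell use.

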