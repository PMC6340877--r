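# ithshape

Multidimensional intratumor-heterogeneity analysis from the **shape of the
variant-allele-frequency (VAF) distribution**.

A tumor sample is a mixture of subclones; each somatic point mutation sits
in some fraction of the tumor cells and is observed through its VAF. In a
diploid, copy-neutral site the expected VAF is `purity × CCF / 2`, so the
sample-wide VAF distribution encodes the subclonal architecture.
One-number heterogeneity scores (MATH, clone counts) flatten that
information; `ithshape` summarises each sample's purity-adjusted VAF
distribution with three shape parameters and analyses cohorts in that
three-dimensional space:

* `m_peak` — the VAF maximising a Gaussian kernel density estimate of the
  sample's VAFs (dominant-clone location),
* `m_count` — log2 of the number of contributing "more functional" (MF)
  mutations (PolyPhen-2 probably/possibly damaging),
* `m_math` — the MATH dispersion score, `1.4826 · MAD(v) / median(v)`.

The pipeline: strict mutation filtering (depth ≥ 20, MF class, copy-neutral
segments with |log2 ratio| ≤ 0.2 and ≥ 10 probes, purity adjustment with
capping) → shape parameters per sample (≥ 2 MF mutations required) → PCA →
k-medoids (squared Euclidean, k = 5) into five archetypes → cluster-level
genetics (per-gene MF frequency, six-class substitution spectrum, CNV
abundance), clinical comparisons (χ²/Fisher, ANOVA + Tukey,
Benjamini–Hochberg) and survival (Kaplan–Meier, Cox proportional hazards
with a size gate of 10 and an automatic reference-cluster rule) → a CART
tree (pruned at CP = 0.1, 10-fold cross-validated) that classifies new
samples from the three parameters alone.

It is aimed at cancer-genomics analysts working from MAF-like somatic
mutation tables, SEG copy-number segments and per-sample clinical tables
(e.g. GDC exports). A calibrated subclonal-architecture simulator
(`simulate_cohort()`) generates complete synthetic cohorts, so the whole
pipeline is testable and demonstrable without protected patient data.

## Worked example

Shape parameters of a single VAF vector:

```r
library(ithshape)
vafs <- c(0.12, 0.18, 0.22, 0.25, 0.26, 0.28, 0.31, 0.45, 0.48, 0.52)
compute_m_peak(vafs)   # 0.247  -- dominant clone near VAF 0.25
compute_m_count(vafs)  # 3.322  -- log2(10) mutations
compute_m_math(vafs)   # 0.384  -- dispersion relative to the median
```

A full synthetic-cohort run:

```r
cohort <- simulate_cohort(default_cohort_spec(n_samples = 200, seed = 7))
cfg <- pipeline_config(mutations = cohort$mutations,
                       segments  = cohort$segments,
                       clinical  = cohort$clinical, seed = 7)
res <- run_pipeline(cfg, out_dir = "ithshape-run")

table(res$labels)
#>  1  2  3  4  5
#> 39 33 32 49 47
round(100 * res$model$pca$explained[1:2], 1)   # 64.1 30.1  (% variance, PC1/PC2)
res$survival$reference$reference               # "3"
res$survival$adjusted$table[, c("cluster", "n", "hr", "ci_low", "ci_high", "p")]
#>   cluster  n   hr ci_low ci_high       p
#> 1       1 39 1.97  1.089    3.57 0.02495
#> 2       2 33 1.11  0.592    2.07 0.75070
#> 3       4 49 2.33  1.302    4.16 0.00437
#> 4       5 47 2.55  1.414    4.59 0.00184
round(100 * res$tree$cv$mean, 1)               # 90.5  (% CV accuracy)
```

Here cluster 3 (mutation-poor, tight clonal peak) is selected as the
reference because every other cluster shows a hazard ratio above 1
against it; clusters 1, 4 and 5 are significantly worse after adjusting
for age, gender and stage. `run_pipeline()` also writes every report as a
TSV (filter report, shape parameters, cluster labels, hazard ratios, KM
curves, spectrum, CNV abundance, top genes, decision tree, CV accuracy)
plus a manifest with checksums; reruns with the same seed are
byte-identical. The same cohort recovered its generating archetypes with
an adjusted Rand index of 0.76 at n = 200 (0.86 at the default n = 500).

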