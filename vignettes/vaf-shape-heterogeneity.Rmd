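---
title: "Quantifying intratumor heterogeneity from the shape of the VAF distribution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying intratumor heterogeneity from the shape of the VAF distribution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ithshape)
```

## The problem and the model

A tumor specimen is a mixture of normal cells and tumor subclones. Each
somatic point mutation is carried by some fraction of the tumor cells (its
cancer-cell fraction, CCF), and sequencing observes it through its variant
allele frequency (VAF): the fraction of reads at the site that carry the
variant. In a diploid, copy-neutral region the expected VAF is
`purity * CCF / 2`, so the *distribution* of VAFs across a sample's
mutations is a noisy image of its subclonal architecture: a tight peak near
`purity / 2` indicates clonal mutations; mass at lower VAFs indicates
subclones.

One-dimensional heterogeneity scores (such as MATH) compress this
distribution to a single number. `ithshape` instead summarises each
sample's purity-adjusted VAF distribution with three shape parameters:

* **m_peak** — the VAF at which a Gaussian kernel density estimate of the
  VAFs is maximal (location of the dominant clone);
* **m_count** — `log2` of the number of contributing mutations (mutational
  burden on a doubling scale);
* **m_math** — the MATH dispersion score, `1.4826 * MAD / median` of the
  VAFs (spread relative to location).

Samples are embedded by principal components of the standardized
parameters, partitioned into `k = 5` archetypes with k-medoids under
squared Euclidean distance, and the archetypes are then compared:
per-gene mutation frequencies, the six-class substitution spectrum,
copy-number alteration abundance, clinical covariates
(chi-square/Fisher and ANOVA + Tukey, Benjamini-Hochberg corrected),
and survival (Kaplan-Meier and Cox proportional hazards). A pruned CART
tree finally maps the three parameters directly to archetype labels so
new samples can be classified without re-clustering.

## Which mutations enter the VAF vector

Only mutations passing a fixed filter chain contribute:

1. **Point mutations** with single-base reference and alternate alleles;
   anything else is dropped at parse time with a skip report.
2. **Depth**: `ref_count + alt_count >= 20` (inclusive). Total depth is
   computed from the two count columns, not from a separate depth field.
3. **Functional class**: PolyPhen-2 `probably_damaging` or
   `possibly_damaging` ("more functional", MF). Unannotated (`unknown`)
   records are treated as non-MF: the class is defined strictly by the two
   damaging labels.
4. **Copy-neutral**: the mutation must lie inside at least one same-sample
   segment with `segment_mean` in `[-0.2, 0.2]` and `>= 10` probes.
   Mutations covered by no segment are *excluded* — unknown copy-number
   status is not assumed neutral. When overlapping segments disagree, one
   passing segment suffices (overlaps are rare and flagged in data checks).
5. **Purity adjustment**: `adjusted = min(raw / purity, 1)`. The cap
   handles sites whose raw VAF exceeds what the purity estimate allows;
   the number of capped values is reported, and the cap can be disabled.
   Samples lacking a purity estimate are dropped by default
   (`missing_purity = "assume_pure"` uses purity 1 instead).

Samples with fewer than 2 surviving mutations cannot yield shape
parameters and are listed in the exclusion report.

## Numerical choices

* **Density estimation** (m_peak): Gaussian kernel, Silverman's
  rule-of-thumb bandwidth (`bw = "nrd0"`), evaluated on a 512-point even
  grid spanning `[0, 1]` rather than the data range, so peak locations are
  comparable across samples. Ties resolve to the smallest VAF; a
  zero-variance input returns the common value directly. Kernel, bandwidth
  rule and grid are configurable.
* **MATH scaling**: the dispersion score is reported as a bare ratio with
  the normal-consistency constant 1.4826; `percent = TRUE` restores the
  original percentage convention.
* **PCA**: features are centered and scaled to unit variance by default —
  m_count lives on roughly 1–10 while the other two parameters live in
  `[0, 1]`, so unstandardized PCA would be dominated by m_count.
  Clustering uses the first two components by default (three available via
  `n_components`).
* **k-medoids**: PAM (BUILD + SWAP) on the squared Euclidean
  dissimilarity. Because SWAP exchanges one medoid at a time, it can stall
  in strict local optima — with squared distances this happens even on
  7-point instances — so `fit_kmedoids()` restarts the SWAP phase from 20
  seeded random medoid sets and keeps the lowest-cost solution, the
  k-medoids analogue of `kmeans`'s `nstart`. The procedure is
  deterministic given the seed and input order. After fitting, cluster ids
  are relabelled by descending median m_count, ties by descending median
  m_peak, which fixes archetype semantics (1–2 mutation-rich, 3–5
  mutation-poor with decreasing peak and increasing dispersion).
  `choose_k_diagnostics()` reports cost and mean silhouette over a k
  range; the default `k = 5` is an analyst's choice, not automated.
* **Survival**: Cox partial likelihood with Efron tie handling; Wald 95%
  intervals; clusters with fewer than 10 samples are excluded before
  fitting; a scaled-Schoenfeld test of proportional hazards is reported.
  Stage enters binarized (I/II vs III/IV) by default. Covariate-missing
  rows are dropped per model (complete-case) with counts reported. The
  reference cluster is the one yielding hazard ratios above 1 against
  every other cluster; when no (or no unique) cluster qualifies, the
  fallback minimizes the worst-case reciprocal hazard ratio and the result
  carries a flag. Because all pairwise ratios derive from a single fit,
  the fallback can only trigger on externally supplied ratio tables.
* **Categorical tests**: Fisher's exact test whenever any expected cell
  frequency is at most 5, otherwise chi-square *without* continuity
  correction (so an exactly independent table reports p = 1). Fisher on
  tables too large to enumerate falls back to a seeded Monte-Carlo
  p-value.
* **CART**: trees are grown to `min_leaf = 5` at `cp = 0` and pruned at
  `cp = 0.1` under the rpart convention (a split must cut resubstitution
  risk by at least `cp` times the root risk). Splits route values below
  the threshold left and values at or above it right. Cross-validation is
  stratified by class (unstratified, with a warning, when a class is
  smaller than the fold count).
* **Seeds**: one pipeline seed fans out through `derive_seed()` to each
  stage, so running a stage in isolation reproduces its part of a full
  run; no stage draws entropy from the clock.

## The synthetic cohort generator

The generator exists so that every stage is testable without protected
patient data; its defaults are the study conditions of the package's
tests. Each of five archetype specifications is a mixture of subclone
CCFs. Per sample: purity is Beta-distributed (mean 0.62, sd 0.06); one
synthetic chromosome of 1e8 bp is tiled into 40 equal segments of which a
fraction (default 0.15) are copy-altered (`|segment mean| >= 0.3`);
mutation count is log2-normal; each mutation draws a CCF from the
mixture, a depth `20 + Poisson(130)`, variant reads
`Binomial(depth, purity * CCF / 2)`, a uniform position, a substitution
class from a six-class spectrum (archetype 1 is C>T-enriched), and with
probability 0.3 a non-MF decoy class. Survival is exponential with
archetype-specific hazard multipliers (archetype 2 lowest, so it becomes
the expected reference cluster) under independent uniform censoring.

The five CCF mixtures were calibrated once so that the *post-filter*
archetype medians of (m_peak, m_count, m_math) land near the published
archetype medians — e.g. archetype 1 near (0.376, 6.794, 0.186) — with the
mutation-count location inflated by `log2(1 / (0.7 * 0.85))` to compensate
for decoy and copy-number thinning. Calibration targets are recovered by
`scripts/acceptance.R`, not restated here.

What the generator does *not* emulate: trinucleotide mutational-signature
context, realistic chromosome structure and segment length distributions,
correlated clinical covariates, subclonal phylogenies beyond independent
CCF mixtures, and inter-cancer-type composition differences. Tests passing
on this cohort therefore validate the pipeline's statistical machinery,
not its behaviour on any real cohort.

## Problem sizes

The test-suite and acceptance computations use a 500-sample cohort (about
100 samples per archetype, a median of 16–110 MF mutations per sample), a
two-group survival simulation with 500 samples per arm, 200 replicate
cohorts of 200 for interval coverage, and 100 random instances of up to 8
points for the exhaustive k-medoids cross-check. These sizes give stable
medians and coverage estimates while keeping a full run in minutes on one
core.

## Known limitations

* m_peak on samples with very few mutations (near the 2-mutation floor) is
  dominated by the kernel bandwidth; archetype medians remain stable but
  individual values are noisy.
* The purity cap concentrates mass at exactly 1 for high-VAF clonal
  mutations in impure samples, which can sharpen m_peak at the boundary.
* The reference-cluster rule assumes a common proportional-hazards model
  across clusters; with non-proportional hazards the Schoenfeld diagnostic
  should be consulted before interpreting ratios.
* Copy-number-bearing mutations are excluded rather than modelled, so
  tumors whose heterogeneity is driven by aneuploidy are summarised only
  through the separate CNV-abundance statistic.

## A minimal run

```{r example, eval = FALSE}
cohort <- simulate_cohort(default_cohort_spec(n_samples = 200, seed = 7))
cfg <- pipeline_config(mutations = cohort$mutations,
                       segments = cohort$segments,
                       clinical = cohort$clinical, seed = 7)
res <- run_pipeline(cfg, out_dir = tempfile("ithshape-run-"))
table(res$labels)
res$tree$cv$mean
```
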