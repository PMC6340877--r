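# Row builder for canonical mutation tables
mut_row <- function(sample_id = "T1", chrom = "chr1", pos = 100,
                    ref = "A", alt = "C", ref_count = 20, alt_count = 10,
                    polyphen = "probably_damaging", gene = "GENE1") {
  data.frame(sample_id = sample_id, chrom = chrom, pos = as.integer(pos),
             ref_allele = ref, alt_allele = alt,
             ref_count = as.integer(ref_count),
             alt_count = as.integer(alt_count),
             polyphen_class = polyphen, gene = gene, stringsAsFactors = FALSE)
}

seg_row <- function(sample_id = "T1", chrom = "chr1", start = 1, end = 1000,
                    num_probes = 50, segment_mean = 0) {
  data.frame(sample_id = sample_id, chrom = chrom, start = as.integer(start),
             end = as.integer(end), num_probes = as.integer(num_probes),
             segment_mean = segment_mean, stringsAsFactors = FALSE)
}

clin_row <- function(sample_id = "T1", cancer_type = "SYNTH", purity = 0.5,
                     survival_days = 100, event = 1, age = 60,
                     gender = "female", stage = "II") {
  data.frame(sample_id = sample_id, cancer_type = cancer_type,
             purity = purity, survival_days = survival_days, event = event,
             age = age, gender = gender, stage = stage,
             stringsAsFactors = FALSE)
}

# Hand-traced 8-mutation fixture for sample T1 (purity 0.5):
# rows 1-2 fail the depth filter, rows 3-4 fail the MF class filter,
# row 5 lands in a copy-altered segment, rows 6-8 survive with
# purity-adjusted VAFs 0.5, 0.8, 1.0.
fixture_chain <- function() {
  muts <- rbind(
    mut_row(pos = 100, ref_count = 5, alt_count = 5),                    # depth 10
    mut_row(pos = 110, ref_count = 9, alt_count = 10),                   # depth 19
    mut_row(pos = 120, ref_count = 12, alt_count = 8, polyphen = "benign"),
    mut_row(pos = 130, ref_count = 20, alt_count = 10, polyphen = "unknown"),
    mut_row(pos = 2500, ref_count = 20, alt_count = 10),                 # altered CN
    mut_row(pos = 140, ref_count = 15, alt_count = 5),                   # vaf 0.25 -> 0.5
    mut_row(pos = 150, ref_count = 18, alt_count = 12,
            polyphen = "possibly_damaging"),                             # 0.4 -> 0.8
    mut_row(pos = 160, ref_count = 25, alt_count = 25)                   # 0.5 -> 1.0
  )
  segs <- rbind(
    seg_row(start = 1, end = 1000, segment_mean = 0.0, num_probes = 50),
    seg_row(start = 2000, end = 3000, segment_mean = 0.5, num_probes = 50),
    seg_row(start = 4000, end = 5000, segment_mean = 0.1, num_probes = 5)
  )
  list(mutations = muts, segments = segs, clinical = clin_row(purity = 0.5))
}

# The default 500-sample cohort, run once per test session and shared by the
# clustering, tree and acceptance tests.
.cohort_cache <- new.env(parent = emptyenv())
default_cohort_fixture <- function() {
  if (is.null(.cohort_cache$c500)) {
    sc <- simulate_cohort(default_cohort_spec(n_samples = 500, seed = 1))
    fc <- run_filter_chain(sc$mutations, sc$segments, sc$clinical)
    pr <- profile_cohort(fc$vaf_sets)
    model <- fit_cohort_clusters(pr$params, k = 5)
    truth <- stats::setNames(sc$truth$archetype, sc$truth$sample_id)
    .cohort_cache$c500 <- list(
      cohort = sc, filtered = fc, params = pr$params,
      correlations = pr$correlations, model = model,
      truth = truth[pr$params$sample_id]
    )
  }
  .cohort_cache$c500
}

# Published archetype medians used as generator calibration targets
archetype_targets <- function() {
  cbind(m_peak = c(0.376, 0.229, 0.424, 0.271, 0.140),
        m_count = c(6.794, 6.119, 4.000, 3.807, 3.807),
        m_math = c(0.186, 0.320, 0.133, 0.251, 0.473))
}

# Exhaustive k-medoids oracle: minimal total squared Euclidean cost over all
# medoid subsets of size k.
brute_force_kmedoids_cost <- function(points, k) {
  d2 <- as.matrix(stats::dist(points))^2
  combos <- utils::combn(nrow(points), k)
  min(apply(combos, 2, function(m) sum(apply(d2[, m, drop = FALSE], 1, min))))
}
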