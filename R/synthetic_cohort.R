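#' Archetype specification for the cohort simulator
#'
#' Describes one VAF-distribution archetype as a mixture of subclones: each
#' simulated mutation draws a cancer-cell fraction (CCF) from the mixture,
#' and its variant reads are binomially sampled at the drawn depth with
#' success probability `purity * CCF / 2` (diploid, copy-neutral model).
#'
#' @param label Archetype id (1-5).
#' @param n_log2_mean,n_log2_sd Mutation count per sample is
#'   `max(2, round(2^N))` with `N ~ Normal(n_log2_mean, n_log2_sd)`.
#' @param ccf Vector of subclone cancer-cell fractions in (0, 1].
#' @param weights Mixture weights, summing to 1.
#' @param purity_mean,purity_sd Tumor purity drawn from the Beta
#'   distribution with these moments.
#' @param depth_mean Mean sequencing depth; per-mutation depth is
#'   `20 + Poisson(depth_mean - 20)` (so every site passes the depth
#'   filter).
#' @param benign_fraction Probability a mutation is emitted with a non-MF
#'   PolyPhen class (a decoy removed by the MF filter).
#' @param cnv_altered_fraction Fraction of the simulated genome covered by
#'   non-neutral copy-number segments; mutations landing there are removed
#'   by the copy-neutral filter downstream.
#' @param spectrum_weights Probabilities over the six substitution classes
#'   C>A, C>G, C>T, T>A, T>C, T>G.
#' @return An `archetype_spec` list.
#' @export
archetype_spec <- function(label, n_log2_mean, n_log2_sd, ccf, weights,
                           purity_mean = 0.62, purity_sd = 0.06,
                           depth_mean = 150, benign_fraction = 0.3,
                           cnv_altered_fraction = 0.15,
                           spectrum_weights = c(0.1, 0.1, 0.35, 0.1, 0.2, 0.15)) {
  stopifnot(length(ccf) == length(weights), abs(sum(weights) - 1) < 1e-8,
            all(ccf > 0 & ccf <= 1), benign_fraction >= 0, benign_fraction < 1,
            cnv_altered_fraction >= 0, cnv_altered_fraction < 1,
            length(spectrum_weights) == 6)
  structure(
    list(label = label, n_log2_mean = n_log2_mean, n_log2_sd = n_log2_sd,
         ccf = ccf, weights = weights, purity_mean = purity_mean,
         purity_sd = purity_sd, depth_mean = depth_mean,
         benign_fraction = benign_fraction,
         cnv_altered_fraction = cnv_altered_fraction,
         spectrum_weights = spectrum_weights / sum(spectrum_weights)),
    class = "archetype_spec"
  )
}

#' Default five-archetype specifications
#'
#' Calibrated so that the full pipeline (filters, purity adjustment, shape
#' parameters) recovers per-archetype medians of (m_peak, m_count, m_math)
#' close to the five published archetype medians: mutation-rich clonal
#' (1), mutation-rich subclone-shifted (2), mutation-poor tight clonal
#' (3), mutation-poor with a mid-CCF subclone (4), and mutation-poor
#' dispersed low-CCF (5). The mutation-count location compensates for the
#' benign-decoy and copy-number thinning so the *post-filter* MF count hits
#' the target. Archetype 1 carries a C>T-enriched substitution spectrum
#' (clonal, melanoma-like trunk); the others share a flatter default.
#'
#' @return List of five `archetype_spec` objects.
#' @export
default_archetype_specs <- function() {
  # thinning: benign decoys (30%) and CNV-altered placement (15%)
  thin <- log2(1 / (0.7 * 0.85))
  list(
    archetype_spec(1, n_log2_mean = 6.794 + thin, n_log2_sd = 0.30,
                   ccf = c(0.77, 0.35), weights = c(0.86, 0.14),
                   spectrum_weights = c(0.06, 0.06, 0.60, 0.06, 0.12, 0.10)),
    archetype_spec(2, n_log2_mean = 6.119 + thin, n_log2_sd = 0.30,
                   ccf = c(0.48, 0.22), weights = c(0.72, 0.28)),
    archetype_spec(3, n_log2_mean = 4.000 + thin, n_log2_sd = 0.30,
                   ccf = c(0.86), weights = c(1)),
    archetype_spec(4, n_log2_mean = 3.807 + thin, n_log2_sd = 0.30,
                   ccf = c(0.55, 0.30), weights = c(0.75, 0.25)),
    archetype_spec(5, n_log2_mean = 3.807 + thin, n_log2_sd = 0.30,
                   ccf = c(0.34, 0.14), weights = c(0.62, 0.38))
  )
}

#' Default cohort specification
#'
#' Equal archetype proportions, exponential survival with archetype-specific
#' hazard multipliers (archetype 2 lowest, so it is the expected reference
#' cluster), independent uniform censoring, and simple clinical covariates.
#'
#' @param n_samples Number of samples; default 500.
#' @param seed Seed controlling all randomness; default 1.
#' @return A `cohort_spec` list.
#' @export
default_cohort_spec <- function(n_samples = 500, seed = 1) {
  structure(
    list(
      archetypes = default_archetype_specs(),
      proportions = rep(0.2, 5),
      n_samples = n_samples,
      seed = seed,
      baseline_hazard = 1 / 1500,    # events per day
      hazard_multipliers = c(1.4, 1.0, 1.9, 2.3, 1.2),
      censor_max = 4000,             # days; uniform censoring window
      age_mean = 62, age_sd = 11,
      cancer_type = "SYNTH"
    ),
    class = "cohort_spec"
  )
}

rbeta_moments <- function(n, mean, sd) {
  v <- sd^2
  a <- mean * (mean * (1 - mean) / v - 1)
  b <- (1 - mean) * (mean * (1 - mean) / v - 1)
  stats::rbeta(n, a, b)
}

BASES_BY_CLASS <- list(
  "C>A" = c("C", "A"), "C>G" = c("C", "G"), "C>T" = c("C", "T"),
  "T>A" = c("T", "A"), "T>C" = c("T", "C"), "T>G" = c("T", "G")
)

#' Simulate one tumor sample
#'
#' Draws purity, tiles a single synthetic chromosome into equal segments
#' (of which `cnv_altered_fraction` are copy-altered with
#' `|segment mean| >= 0.3`, the rest copy-neutral within (-0.15, 0.15)),
#' then emits mutations: per mutation a CCF from the subclone mixture, a
#' depth, variant reads `Binomial(depth, purity * CCF / 2)`, a uniform
#' genomic position, a substitution class from the spectrum (reported on
#' either strand with equal probability), and a PolyPhen class (non-MF
#' decoy with probability `benign_fraction`).
#'
#' @param spec An `archetype_spec`.
#' @param sample_id Sample identifier for the emitted records.
#' @param seed Optional seed; if `NULL`, uses the current RNG stream.
#' @param genome_length Length of the synthetic chromosome; default 1e8.
#' @param n_segments Number of equal tiling segments; default 40.
#' @return List with `mutations` (data frame in the canonical mutation
#'   layout), `segments` (SEG layout), `purity`.
#' @export
simulate_sample <- function(spec, sample_id = "S1", seed = NULL,
                            genome_length = 1e8, n_segments = 40) {
  if (!is.null(seed)) set.seed(seed)
  purity <- min(1, max(0.1, rbeta_moments(1, spec$purity_mean, spec$purity_sd)))

  bounds <- round(seq(0, genome_length, length.out = n_segments + 1))
  n_alt <- round(spec$cnv_altered_fraction * n_segments)
  altered <- sample.int(n_segments, n_alt)
  seg_mean <- stats::runif(n_segments, -0.15, 0.15)
  seg_mean[altered] <- sample(c(-1, 1), n_alt, replace = TRUE) *
    stats::runif(n_alt, 0.3, 1.0)
  segments <- data.frame(
    sample_id = sample_id, chrom = "chr1",
    start = as.integer(bounds[-length(bounds)] + 1),
    end = as.integer(bounds[-1]),
    num_probes = sample(20:200, n_segments, replace = TRUE),
    segment_mean = round(seg_mean, 4),
    stringsAsFactors = FALSE
  )

  n <- max(2, round(2^stats::rnorm(1, spec$n_log2_mean, spec$n_log2_sd)))
  ccf <- sample(spec$ccf, n, replace = TRUE, prob = spec$weights)
  depth <- 20L + stats::rpois(n, spec$depth_mean - 20)
  p_var <- pmin(1, purity * ccf / 2)
  alt_count <- stats::rbinom(n, depth, p_var)
  benign <- stats::runif(n) < spec$benign_fraction
  polyphen <- ifelse(
    benign,
    sample(c("benign", "unknown"), n, replace = TRUE, prob = c(0.7, 0.3)),
    sample(c("probably_damaging", "possibly_damaging"), n, replace = TRUE)
  )
  cls <- sample(names(BASES_BY_CLASS), n, replace = TRUE,
                prob = spec$spectrum_weights)
  ref <- vapply(BASES_BY_CLASS[cls], `[`, "", 1)
  alt <- vapply(BASES_BY_CLASS[cls], `[`, "", 2)
  flip <- stats::runif(n) < 0.5
  ref[flip] <- COMPLEMENT[ref[flip]]
  alt[flip] <- COMPLEMENT[alt[flip]]

  mutations <- data.frame(
    sample_id = sample_id, chrom = "chr1",
    pos = sample.int(genome_length, n, replace = TRUE),
    ref_allele = unname(ref), alt_allele = unname(alt),
    ref_count = as.integer(depth - alt_count), alt_count = as.integer(alt_count),
    polyphen_class = polyphen,
    gene = sprintf("GENE%03d", sample.int(100, n, replace = TRUE)),
    stringsAsFactors = FALSE
  )
  list(mutations = mutations, segments = segments, purity = purity)
}

#' Simulate a full cohort
#'
#' Draws an archetype per sample, simulates its mutations, segments and
#' purity with [simulate_sample()], then survival: time-to-event is
#' exponential with hazard `baseline_hazard * hazard_multipliers[archetype]`
#' and censoring is uniform on `(0, censor_max)`. Ages, genders and stages
#' are drawn independently of archetype. With `dir` set, writes the three
#' input TSVs (mutation table in GDC MAF dialect, SEG table, clinical
#' table) plus the truth-label TSV. Identical spec and seed produce
#' byte-identical files.
#'
#' @param spec A `cohort_spec`; see [default_cohort_spec()].
#' @param dir Optional output directory for the TSV bundle.
#' @return List with `mutations`, `segments`, `clinical`, `truth` (data
#'   frames; `truth` maps `sample_id` to the generating `archetype`), and
#'   `paths` (named file paths when `dir` is given).
#' @export
simulate_cohort <- function(spec = default_cohort_spec(), dir = NULL) {
  set.seed(spec$seed)
  n <- spec$n_samples
  if (n == 0) {
    empty <- list(
      mutations = simulate_sample(spec$archetypes[[1]], "S0")$mutations[0, ],
      segments = simulate_sample(spec$archetypes[[1]], "S0")$segments[0, ],
      clinical = data.frame(), truth = data.frame(), paths = NULL
    )
    set.seed(spec$seed)  # the probe draws above must not leak
    return(empty)
  }
  arch <- sample.int(5, n, replace = TRUE, prob = spec$proportions)
  ids <- sprintf("S%04d", seq_len(n))

  muts <- vector("list", n); segs <- vector("list", n)
  clin <- vector("list", n)
  for (i in seq_len(n)) {
    sim <- simulate_sample(spec$archetypes[[arch[i]]], ids[i])
    muts[[i]] <- sim$mutations
    segs[[i]] <- sim$segments
    rate <- spec$baseline_hazard * spec$hazard_multipliers[arch[i]]
    t_event <- stats::rexp(1, rate)
    t_cens <- stats::runif(1, 0, spec$censor_max)
    clin[[i]] <- data.frame(
      sample_id = ids[i], cancer_type = spec$cancer_type,
      purity = round(sim$purity, 4),
      survival_days = round(min(t_event, t_cens), 1),
      event = as.integer(t_event <= t_cens),
      age = round(min(95, max(25, stats::rnorm(1, spec$age_mean, spec$age_sd)))),
      gender = sample(c("male", "female"), 1),
      stage = sample(c("I", "II", "III", "IV"), 1,
                     prob = c(0.3, 0.3, 0.25, 0.15)),
      stringsAsFactors = FALSE
    )
  }
  out <- list(
    mutations = do.call(rbind, muts),
    segments = do.call(rbind, segs),
    clinical = do.call(rbind, clin),
    truth = data.frame(sample_id = ids, archetype = arch,
                       stringsAsFactors = FALSE),
    paths = NULL
  )
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- c(
      mutations = file.path(dir, "mutations.tsv"),
      segments = file.path(dir, "segments.tsv"),
      clinical = file.path(dir, "clinical.tsv"),
      truth = file.path(dir, "truth.tsv")
    )
    write_mutations(out$mutations, paths["mutations"])
    write_segments(out$segments, paths["segments"])
    write_clinical(out$clinical, paths["clinical"])
    write_tsv(out$truth, paths["truth"])
    out$paths <- paths
  }
  out
}
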