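SPECTRUM_CLASSES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

# Purine-reference substitutions collapsed onto the pyrimidine strand:
# G>A ~ C>T, G>T ~ C>A, G>C ~ C>G, A>G ~ T>C, A>C ~ T>G, A>T ~ T>A.
COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Six-class substitution spectrum
#'
#' Counts point mutations in the six pyrimidine-strand substitution classes.
#' Records with a purine reference (A or G) are complemented onto the
#' pyrimidine strand before counting, so the twelve substitution types
#' partition exactly into the six classes.
#'
#' @param mutations Mutation data frame with `ref_allele`, `alt_allele`.
#' @return List with `counts` (named integer vector over the six classes)
#'   and `fractions` (summing to 1 when the total is positive, `NA`
#'   otherwise).
#' @export
mutation_spectrum <- function(mutations) {
  ref <- mutations$ref_allele
  alt <- mutations$alt_allele
  flip <- ref %in% c("A", "G")
  ref[flip] <- COMPLEMENT[mutations$ref_allele[flip]]
  alt[flip] <- COMPLEMENT[mutations$alt_allele[flip]]
  cls <- paste0(ref, ">", alt)
  counts <- stats::setNames(integer(6), SPECTRUM_CLASSES)
  tab <- table(factor(cls, levels = SPECTRUM_CLASSES))
  counts[names(tab)] <- as.integer(tab)
  total <- sum(counts)
  fractions <- if (total > 0) counts / total else stats::setNames(rep(NA_real_, 6), SPECTRUM_CLASSES)
  list(counts = counts, fractions = fractions)
}

#' Copy-number alteration abundance of a sample
#'
#' Fraction of the segment-covered genome carrying a copy-number alteration:
#' total length of segments with `|segment_mean| > threshold` (strict)
#' divided by the total length of all segments. A proxy for genomic
#' instability.
#'
#' @param segments Segment data frame for one sample.
#' @param threshold Absolute log2-ratio above which a segment counts as
#'   altered; default 0.2, mirroring the copy-neutral filter window.
#' @return Fraction in [0, 1], or `NA` if the total segment length is zero.
#' @export
cnv_abundance <- function(segments, threshold = 0.2) {
  len <- segments$end - segments$start + 1
  total <- sum(len)
  if (length(len) == 0 || total == 0) {
    return(NA_real_)
  }
  sum(len[abs(segments$segment_mean) > threshold]) / total
}

#' Per-gene MF mutation frequency by cluster
#'
#' For each gene and cluster, the fraction of the cluster's samples carrying
#' at least one MF mutation in the gene (a sample-level indicator: several
#' mutations in one gene count once).
#'
#' @param mutations MF-filtered mutation data frame with a `gene` column.
#' @param labels Named vector mapping `sample_id` to cluster id; samples
#'   without a label are ignored, and cluster denominators are the label
#'   counts (samples with zero MF mutations still count in the denominator).
#' @param top_n Number of top genes to report per cluster; default 10.
#' @return List with `frequencies` (data frame gene x cluster, long format:
#'   `gene`, `cluster`, `n_mutated`, `n_samples`, `frequency`) and `top`
#'   (the `top_n` highest-frequency genes per cluster).
#' @export
per_gene_mf_frequency <- function(mutations, labels, top_n = 10) {
  stopifnot(!is.null(names(labels)))
  muts <- mutations[mutations$sample_id %in% names(labels) &
                      !is.na(mutations$gene), , drop = FALSE]
  muts$cluster <- labels[muts$sample_id]
  cluster_sizes <- table(labels)
  pairs <- unique(muts[, c("sample_id", "gene", "cluster")])
  counts <- as.data.frame(table(gene = pairs$gene, cluster = pairs$cluster),
                          stringsAsFactors = FALSE)
  names(counts)[3] <- "n_mutated"
  counts <- counts[counts$n_mutated > 0, , drop = FALSE]
  counts$n_samples <- as.integer(cluster_sizes[counts$cluster])
  counts$frequency <- counts$n_mutated / counts$n_samples
  counts <- counts[order(counts$cluster, -counts$frequency, counts$gene), ]
  rownames(counts) <- NULL
  top <- do.call(rbind, lapply(split(counts, counts$cluster), utils::head, top_n))
  rownames(top) <- NULL
  list(frequencies = counts, top = top)
}

expected_frequencies <- function(tab) {
  outer(rowSums(tab), colSums(tab)) / sum(tab)
}

#' Categorical group comparison (chi-square / Fisher switch)
#'
#' Compares an r x c contingency table of counts. If any cell's expected
#' frequency under independence is <= 5, Fisher's exact test is used;
#' otherwise a chi-square test without continuity correction. For tables
#' beyond 2 x 2 where exhaustive enumeration of the exact test fails, a
#' Monte-Carlo Fisher p-value is computed with a fixed seed.
#'
#' @param tab Matrix of non-negative integer counts (no zero margins).
#' @param seed Seed for the Monte-Carlo fallback; default 1.
#' @param B Monte-Carlo replicates for the fallback; default 1e5.
#' @return A `group_test` list: `test_used` (`"chi_square"` or
#'   `"fisher_exact"`), `p`, `statistic` (chi-square only), `expected`.
#' @export
compare_categorical <- function(tab, seed = 1, B = 1e5) {
  tab <- as.matrix(tab)
  stopifnot(all(tab >= 0), all(tab == round(tab)))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("degenerate table: zero row or column margin", call. = FALSE)
  }
  exp_freq <- expected_frequencies(tab)
  if (any(exp_freq <= 5)) {
    ft <- tryCatch(
      stats::fisher.test(tab),
      error = function(e) {
        withr_seed <- function(expr) { set.seed(seed); expr }
        withr_seed(stats::fisher.test(tab, simulate.p.value = TRUE, B = B))
      }
    )
    res <- list(test_used = "fisher_exact", p = ft$p.value,
                statistic = NA_real_, expected = exp_freq)
  } else {
    ct <- stats::chisq.test(tab, correct = FALSE)
    res <- list(test_used = "chi_square", p = ct$p.value,
                statistic = unname(ct$statistic), expected = exp_freq)
  }
  structure(res, class = "group_test")
}

#' Continuous group comparison (ANOVA + Tukey HSD)
#'
#' One-way analysis of variance across groups followed by Tukey's honest
#' significant difference test for all pairwise contrasts.
#'
#' @param values Numeric response vector.
#' @param groups Group labels, at least 2 groups with at least 2 values each.
#' @return A `group_test` list: `test_used = "anova_tukey"`, `p` (ANOVA F
#'   test), `statistic` (F), `tukey` (data frame: `comparison`, `diff`,
#'   `ci_low`, `ci_high`, `p_adj`).
#' @export
compare_continuous <- function(values, groups) {
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]
  groups <- factor(groups[keep])
  sizes <- table(groups)
  if (length(sizes) < 2 || any(sizes < 2)) {
    stop("need >= 2 groups with >= 2 values each", call. = FALSE)
  }
  if (stats::sd(values) == 0) {
    stop("degenerate input: all values identical across groups", call. = FALSE)
  }
  fit <- stats::aov(values ~ groups)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$groups
  tukey <- data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                      ci_low = tk[, "lwr"], ci_high = tk[, "upr"],
                      p_adj = tk[, "p adj"], stringsAsFactors = FALSE)
  rownames(tukey) <- NULL
  structure(
    list(test_used = "anova_tukey", p = an[["Pr(>F)"]][1],
         statistic = an[["F value"]][1], tukey = tukey),
    class = "group_test"
  )
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate correction with monotonicity enforcement,
#' capped at 1; output order matches input order.
#'
#' @param p_values Numeric vector of p-values in [0, 1].
#' @return Adjusted p-values, same length and order.
#' @export
adjust_bh <- function(p_values) {
  stopifnot(all(p_values >= 0 & p_values <= 1, na.rm = TRUE))
  stats::p.adjust(p_values, method = "BH")
}
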