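test_that("substitution spectrum collapses purine references to the pyrimidine strand", {
  expect_equal(unname(mutation_spectrum(mut_row(ref = "G", alt = "A"))$counts["C>T"]), 1L)
  expect_equal(unname(mutation_spectrum(mut_row(ref = "A", alt = "C"))$counts["T>G"]), 1L)
  # the 12 substitution types partition exactly into the 6 classes
  bases <- c("A", "C", "G", "T")
  all12 <- do.call(rbind, lapply(bases, function(r)
    do.call(rbind, lapply(setdiff(bases, r), function(a) mut_row(ref = r, alt = a)))))
  sp <- mutation_spectrum(all12)
  expect_equal(sum(sp$counts), 12L)
  expect_equal(unname(sp$counts), rep(2L, 6))
  expect_equal(sum(sp$fractions), 1)

  # 12-record fixture with known composition: 6 C>T, 3 G>T (=C>A), 3 T>A
  fx <- rbind(do.call(rbind, replicate(6, mut_row(ref = "C", alt = "T"),
                                       simplify = FALSE)),
              do.call(rbind, replicate(3, mut_row(ref = "G", alt = "T"),
                                       simplify = FALSE)),
              do.call(rbind, replicate(3, mut_row(ref = "T", alt = "A"),
                                       simplify = FALSE)))
  frac <- mutation_spectrum(fx)$fractions
  expect_equal(unname(frac[c("C>T", "C>A", "T>A")]), c(0.5, 0.25, 0.25))
})

test_that("CNV abundance is the altered fraction of covered genome", {
  neutral <- rbind(seg_row(start = 1, end = 1000, segment_mean = 0),
                   seg_row(start = 1001, end = 2000, segment_mean = 0.05))
  expect_equal(cnv_abundance(neutral), 0)
  half <- rbind(seg_row(start = 1, end = 1000, segment_mean = 0),
                seg_row(start = 1001, end = 2000, segment_mean = 1.0))
  expect_equal(cnv_abundance(half), 0.5)
  # |mean| must strictly exceed the threshold
  boundary <- seg_row(start = 1, end = 1000, segment_mean = 0.2)
  expect_equal(cnv_abundance(boundary), 0)
  expect_true(is.na(cnv_abundance(neutral[0, ])))
})

test_that("per-gene MF frequency counts each sample once", {
  labels <- stats::setNames(c(1, 1, 1, 1), paste0("S", 1:4))
  muts <- rbind(mut_row(sample_id = "S1", gene = "PIK3CA"),
                mut_row(sample_id = "S1", gene = "PIK3CA", pos = 200),
                mut_row(sample_id = "S1", gene = "PIK3CA", pos = 300))
  fr <- per_gene_mf_frequency(muts, labels)$frequencies
  expect_equal(fr$frequency, 0.25)   # 3 mutations, 1 of 4 samples

  # 71 mutated of 200 samples -> 0.355
  labels200 <- stats::setNames(rep(2, 200), sprintf("Q%03d", 1:200))
  muts71 <- do.call(rbind, lapply(sprintf("Q%03d", 1:71), function(s)
    mut_row(sample_id = s, gene = "TP53")))
  fr2 <- per_gene_mf_frequency(muts71, labels200)$frequencies
  expect_equal(fr2$frequency, 0.355)
})

test_that("categorical comparison switches between chi-square and Fisher", {
  even <- matrix(c(20, 20, 20, 20), 2)
  res <- compare_categorical(even)
  expect_equal(res$test_used, "chi_square")
  expect_equal(res$p, 1.0)

  small <- matrix(c(2, 4, 3, 1), 2)    # min expected frequency 2.5
  expect_equal(compare_categorical(small)$test_used, "fisher_exact")

  # exact p for the fully separated 2x2 table vs hypergeometric brute force
  sep <- matrix(c(10, 0, 0, 10), 2)
  res_sep <- compare_categorical(sep)
  brute <- sum(sapply(0:10, function(a) {
    p <- dhyper(a, 10, 10, 10)
    if (p <= dhyper(10, 10, 10, 10) + 1e-12) p else 0
  }))
  expect_equal(res_sep$p, brute, tolerance = 1e-12)
  expect_equal(res_sep$p, 2 / choose(20, 10), tolerance = 1e-12)

  expect_error(compare_categorical(matrix(c(0, 0, 5, 5), 2, byrow = TRUE)),
               "margin")
})

test_that("Fisher and chi-square agree on large balanced tables", {
  tab <- matrix(c(300, 200, 250, 250), 2)
  p_chi <- stats::chisq.test(tab, correct = FALSE)$p.value
  p_fis <- stats::fisher.test(tab)$p.value
  expect_lt(abs(p_chi - p_fis), 0.02)
  expect_equal(compare_categorical(tab)$test_used, "chi_square")
})

test_that("continuous comparison runs ANOVA with Tukey HSD", {
  set.seed(171)
  g1 <- rnorm(30, 0, 1); g2 <- rnorm(30, 5, 1)   # 5 SD apart
  res <- compare_continuous(c(g1, g2), rep(c("a", "b"), each = 30))
  expect_lt(res$p, 1e-6)
  expect_lt(res$tukey$p_adj[1], 1e-6)

  # identical groups: no between-group variance
  same <- compare_continuous(c(1, 2, 3, 1, 2, 3),
                             rep(c("a", "b"), each = 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  expect_error(compare_continuous(rep(1, 6), rep(c("a", "b"), each = 3)),
               "degenerate")
})

test_that("null ANOVA keeps its size", {
  set.seed(181)
  hits <- vapply(1:100, function(i) {
    v <- rnorm(60)
    compare_continuous(v, rep(1:3, each = 20))$p > 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("BH adjustment matches the hand computation and is idempotent", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(adjust_bh(0.5), 0.5)
  p <- c(0.04, 0.001, 0.9, 0.02)
  adj <- adjust_bh(p)
  expect_equal(order(adj), order(p))            # order preserved
  expect_true(all(adj >= p & adj <= 1))
  flat <- adjust_bh(c(0.01, 0.02, 0.03))
  expect_equal(adjust_bh(flat), flat)           # flat adjusted vectors are fixed points
})
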