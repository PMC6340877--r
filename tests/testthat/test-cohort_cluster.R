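make_params <- function(m) {
  data.frame(sample_id = paste0("S", seq_len(nrow(m))),
             m_peak = m[, 1], m_count = m[, 2], m_math = m[, 3])
}

test_that("PCA explained fractions behave on independent and collinear data", {
  set.seed(51)
  iso <- make_params(matrix(rnorm(3 * 10000), ncol = 3))
  pca <- fit_pca(iso)
  expect_true(all(abs(pca$explained - 1 / 3) < 0.03))
  expect_equal(sum(pca$explained), 1, tolerance = 1e-9)
  expect_true(all(diff(pca$explained) <= 1e-12))
  # loadings orthonormal
  expect_equal(crossprod(pca$loadings), diag(3), tolerance = 1e-8,
               ignore_attr = TRUE)

  t_line <- seq(0, 1, length.out = 50)
  line <- make_params(cbind(t_line, 2 * t_line, -t_line))
  pca_line <- fit_pca(line, standardize = FALSE)
  expect_equal(pca_line$explained[1], 1, tolerance = 1e-9)

  degen <- make_params(cbind(rnorm(10), 5, rnorm(10)))
  expect_error(fit_pca(degen), "m_count")
})

test_that("PAM on the line instance finds medoids 1 and 11 with cost 4", {
  pts <- matrix(c(0, 1, 2, 10, 11, 12), ncol = 1)
  km <- fit_kmedoids(pts, k = 2)
  expect_setequal(pts[km$medoid_idx, 1], c(1, 11))
  expect_equal(km$cost, 4.0)
  expect_equal(km$cost, brute_force_kmedoids_cost(pts, 2))
})

test_that("PAM edge cases: k = n and duplicate points", {
  pts <- matrix(rnorm(8), ncol = 2)
  km <- fit_kmedoids(pts, k = 4)
  expect_equal(km$cost, 0)
  expect_equal(sort(km$medoid_idx), 1:4)

  dup <- matrix(c(0.3, 0.3, 0.3, 0.3), ncol = 2, byrow = TRUE)
  km1 <- fit_kmedoids(dup, k = 1)
  expect_equal(km1$cost, 0)
  expect_equal(unname(km1$medoid_idx), 1L)   # tie broken by input order
  expect_error(fit_kmedoids(dup, k = 3), "exceed")
})

test_that("PAM matches the exhaustive optimum on small random instances", {
  set.seed(61)
  for (i in 1:100) {
    n <- sample(4:8, 1)
    k <- sample(2:3, 1)
    pts <- matrix(runif(2 * n), ncol = 2)
    km <- fit_kmedoids(pts, k)
    expect_equal(km$cost, brute_force_kmedoids_cost(pts, k),
                 tolerance = 1e-10)
    # every point assigned to its nearest medoid
    d2 <- as.matrix(dist(pts))^2
    nearest <- apply(d2[, km$medoid_idx, drop = FALSE], 1, min)
    assigned <- d2[cbind(seq_len(n), km$medoid_idx[km$labels])]
    expect_equal(assigned, nearest, ignore_attr = TRUE)
  }
})

test_that("cluster labels are stable under sample-order permutation", {
  set.seed(71)
  pts <- rbind(matrix(rnorm(40, 0), ncol = 2),
               matrix(rnorm(40, 4), ncol = 2),
               matrix(rnorm(40, 8), ncol = 2))
  rownames(pts) <- paste0("S", 1:60)
  km <- fit_kmedoids(pts, 3)
  perm <- sample(60)
  km_p <- fit_kmedoids(pts[perm, ], 3)
  expect_equal(adjusted_rand_index(km$labels[rownames(pts)[perm]],
                                   km_p$labels), 1)
})

test_that("k diagnostics report cost and silhouette over the range", {
  set.seed(81)
  blobs <- rbind(matrix(rnorm(60, 0, 0.1), ncol = 2),
                 matrix(rnorm(60, 3, 0.1), ncol = 2),
                 matrix(rnorm(60, c(0, 6), 0.1), ncol = 2, byrow = TRUE))
  diag3 <- choose_k_diagnostics(blobs, 2:6)
  expect_equal(nrow(diag3), 5L)
  expect_equal(diag3$k[which.max(diag3$mean_silhouette)], 3L)

  blob1 <- matrix(rnorm(100), ncol = 2)
  diag1 <- choose_k_diagnostics(blob1, 2:6)
  expect_true(all(diff(diag1$cost) < 0))
})

test_that("fitted cluster ids are ordered by median m_count then m_peak", {
  fx <- default_cohort_fixture()
  med <- aggregate(fx$params[, c("m_count", "m_peak")],
                   list(cluster = as.integer(fx$model$labels)), median)
  ord <- order(-med$m_count, -med$m_peak)
  expect_equal(med$cluster[ord], 1:5)
})

test_that("new samples are assigned to the nearest medoid's cluster", {
  fx <- default_cohort_fixture()
  model <- fx$model
  for (cl in 1:5) {
    mid <- model$medoid_sample_ids[cl]
    p <- fx$params[fx$params$sample_id == mid, ]
    expect_equal(unname(assign_new_sample(model, p)), cl)
  }
  # persistence round-trip preserves assignment
  path <- withr::local_tempfile(fileext = ".json")
  save_cohort_model(model, path)
  loaded <- load_cohort_model(path)
  sub <- fx$params[seq(1, 500, by = 25), ]
  expect_equal(assign_new_sample(loaded, sub), assign_new_sample(model, sub))
})

test_that("fresh archetype-1 samples are mostly assigned to cluster 1", {
  fx <- default_cohort_fixture()
  spec <- default_archetype_specs()[[1]]
  set.seed(91)
  hits <- vapply(1:100, function(i) {
    sim <- simulate_sample(spec, "NEW")
    fc <- run_filter_chain(sim$mutations, sim$segments,
                           clin_row(sample_id = "NEW", purity = sim$purity))
    vs <- fc$vaf_sets[["NEW"]]
    p <- data.frame(sample_id = "NEW", m_peak = compute_m_peak(vs),
                    m_count = compute_m_count(vs),
                    m_math = compute_m_math(vs))
    assign_new_sample(fx$model, p) == 1
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
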