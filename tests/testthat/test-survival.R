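# Independent Cox oracle for a two-group covariate: root of the partial
# likelihood score equation, found with a 1-D bracketing solver. Valid when
# event times are untied (Efron = Breslow = exact there).
cox_score_root <- function(time, event, x) {
  score <- function(b) {
    s <- 0
    for (i in which(event == 1)) {
      risk <- time >= time[i]
      w <- exp(b * x[risk])
      s <- s + x[i] - sum(x[risk] * w) / sum(w)
    }
    s
  }
  stats::uniroot(score, c(-5, 5), tol = 1e-10)$root
}

test_that("Kaplan-Meier matches the hand product-limit computation", {
  km <- km_estimate(c(1, 2, 3), c(1, 1, 1), rep("g", 3))
  expect_equal(km$survival, c(2 / 3, 1 / 3, 0))
  # all censored: flat at 1
  flat <- km_estimate(c(5, 6, 7), c(0, 0, 0), rep("g", 3))
  expect_true(all(flat$survival == 1))
  # tied event times drop simultaneously
  tied <- km_estimate(c(1, 1, 2), c(1, 1, 1), rep("g", 3))
  expect_equal(tied$survival[tied$time == 1], 1 / 3)
})

test_that("Cox fit matches an independent score-equation solver", {
  set.seed(111)
  n <- 60
  x <- rep(0:1, each = n / 2)
  time <- rexp(n, 0.01 * exp(0.7 * x))
  event <- rep(1L, n)
  stopifnot(!any(duplicated(time)))
  res <- fit_cox(time, event, labels = x, reference = 0,
                 min_cluster_size = 5)
  expect_equal(log(res$table$hr), cox_score_root(time, event, x),
               tolerance = 1e-6)
})

test_that("Cox recovers a known hazard ratio and covers the null", {
  set.seed(121)
  n <- 500
  lab <- rep(c(1, 2), each = n)
  time <- c(rexp(n, 0.001), rexp(n, 0.002))          # true HR 2 for group 2
  cens <- runif(2 * n, 0, 2000)
  obs <- pmin(time, cens); ev <- as.integer(time <= cens)
  res <- fit_cox(obs, ev, lab, reference = 1)
  expect_gt(res$table$hr, 1.6); expect_lt(res$table$hr, 2.5)
  expect_true(res$table$ci_low <= 2 && 2 <= res$table$ci_high)

  set.seed(122)
  t0 <- rexp(2 * n, 0.001)
  obs0 <- pmin(t0, cens); ev0 <- as.integer(t0 <= cens)
  null_res <- fit_cox(obs0, ev0, lab, reference = 1)
  expect_true(null_res$table$ci_low <= 1 && 1 <= null_res$table$ci_high)
})

test_that("clusters under the size gate are excluded without moving the fit", {
  set.seed(131)
  n <- 200
  lab <- rep(c(1, 2), each = n)
  time <- c(rexp(n, 0.001), rexp(n, 0.0025))
  ev <- rep(1L, 2 * n)
  base <- fit_cox(time, ev, lab, reference = 1)
  lab9 <- c(lab, rep(3, 9))
  time9 <- c(time, rexp(9, 0.01)); ev9 <- c(ev, rep(1L, 9))
  gated <- fit_cox(time9, ev9, lab9, reference = 1)
  expect_equal(gated$excluded_clusters, 3)
  expect_equal(gated$table$hr, base$table$hr)
  expect_error(fit_cox(time9, ev9, lab9, reference = 3), "size gate")
})

test_that("covariate-adjusted fit uses and reports the covariates", {
  set.seed(141)
  n <- 300
  lab <- sample(1:2, n, replace = TRUE)
  age <- rnorm(n, 60, 10)
  time <- rexp(n, 0.001 * exp(0.03 * (age - 60)))
  ev <- rep(1L, n)
  covs <- data.frame(age = age,
                     gender = sample(c("m", "f"), n, TRUE),
                     stage = sample(c("I", "II", "III", "IV"), n, TRUE))
  res <- fit_cox(time, ev, lab, reference = 1, covariates = covs)
  expect_setequal(res$covariates_used, c("age", "gender", "stage"))
  expect_true(all(res$table$ci_low <= res$table$hr &
                    res$table$hr <= res$table$ci_high))
  # stage is binarized: the fit has one stage coefficient
  expect_equal(sum(grepl("^stage", names(coef(res$fit)))), 1L)
})

test_that("reference selection returns the uniformly lowest-hazard cluster", {
  set.seed(151)
  n <- 150
  lab <- rep(c("A", "B", "C"), each = n)
  time <- c(rexp(n, 0.001), rexp(n, 0.002), rexp(n, 0.003))
  ev <- rep(1L, 3 * n)
  hr <- cox_hr_matrix(time, ev, lab)
  sel <- select_reference_cluster(hr)
  expect_equal(sel$reference, "A")
  expect_true(sel$qualified)
  expect_true(all(hr["A", c("B", "C")] > 1))

  # two clusters with HR(B vs A) = 1.5
  tab2 <- matrix(c(NA, 1.5, 1 / 1.5, NA), 2, 2, byrow = TRUE,
                 dimnames = list(c("A", "B"), c("A", "B")))
  expect_equal(select_reference_cluster(tab2)$reference, "A")

  # constructed cyclic table: no row has all HR > 1 -> flagged fallback
  cyc <- matrix(c(NA, 2, 0.5, 0.5, NA, 2, 2, 0.5, NA), 3, 3, byrow = TRUE,
                dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  sel_c <- select_reference_cluster(cyc)
  expect_false(sel_c$qualified)
  expect_equal(sel_c$reference, "A")   # tie broken by order
})

test_that("univariate model delegates and rejects single-cluster input", {
  set.seed(161)
  n <- 100
  lab <- rep(1:2, each = n)
  time <- rexp(2 * n, 0.001); ev <- rep(1L, 2 * n)
  uni <- univariate_cluster_cox(time, ev, lab, reference = 1)
  full <- fit_cox(time, ev, lab, reference = 1)
  expect_equal(uni$table$hr, full$table$hr)
  expect_equal(uni$covariates_used, character(0))
  expect_error(
    univariate_cluster_cox(time, ev, c(rep(1, 195), rep(2, 5)), reference = 1),
    "fewer than 2"
  )
})
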