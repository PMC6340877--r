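#' Adjusted Rand index between two label vectors
#'
#' Chance-corrected agreement between two partitions of the same samples;
#' 1 for identical partitions (up to label renaming), about 0 for
#' independent ones.
#'
#' @param a,b Label vectors of equal length.
#' @return Numeric scalar.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) {
    return(1)
  }
  (sum_ij - expected) / (max_index - expected)
}

#' Derive a per-stage seed from the pipeline seed
#'
#' One configuration seed fans out to per-stage seeds so that stages run in
#' isolation reproduce the corresponding stage of a full pipeline run.
#' Linear-congruential-style derivation, kept below 2^31 - 1.
#'
#' @param seed Integer pipeline seed.
#' @param stage One of `"simulate"`, `"profile"`, `"cluster"`, `"survive"`,
#'   `"stats"`, `"classify"`.
#' @return Integer seed.
#' @export
derive_seed <- function(seed, stage) {
  offsets <- c(simulate = 1L, profile = 2L, cluster = 3L, survive = 4L,
               stats = 5L, classify = 6L)
  stopifnot(stage %in% names(offsets))
  as.integer((as.numeric(seed) * 7919 + offsets[[stage]]) %% 2147483647)
}
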