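#' log2 mutation count (m_Count)
#'
#' Size parameter of a sample's VAF distribution: the base-2 logarithm of the
#' number of MF mutations. Defined only for samples with at least 2
#' mutations.
#'
#' @param vafs Numeric vector of VAFs, or a `vaf_set` (see
#'   [compute_adjusted_vafs()]).
#' @return `log2(length(vafs))`.
#' @export
compute_m_count <- function(vafs) {
  v <- as_vaf_vector(vafs)
  if (length(v) < 2) {
    stop("m_Count requires at least 2 mutations", call. = FALSE)
  }
  log2(length(v))
}

#' MATH dispersion score (m_MATH)
#'
#' Mutant-allele tumor heterogeneity: the median absolute deviation of the
#' VAFs (scaled by the normal-consistency constant) divided by their median.
#' Zero iff all VAFs are equal. The original MATH publication reports the
#' score as a percentage; the default here is the bare ratio, with the
#' percentage available via `percent = TRUE`.
#'
#' @param vafs Numeric vector of VAFs, or a `vaf_set`.
#' @param scale_constant MAD consistency constant; default 1.4826.
#' @param percent Multiply by 100; default `FALSE`.
#' @return Non-negative dispersion score.
#' @export
compute_m_math <- function(vafs, scale_constant = 1.4826, percent = FALSE) {
  v <- as_vaf_vector(vafs)
  if (length(v) < 2) {
    stop("m_MATH requires at least 2 mutations", call. = FALSE)
  }
  med <- stats::median(v)
  if (med == 0) {
    stop("m_MATH undefined: median VAF is 0", call. = FALSE)
  }
  out <- scale_constant * stats::median(abs(v - med)) / med
  if (percent) out <- 100 * out
  out
}

#' Density-peak VAF (m_Peak)
#'
#' Location parameter of a sample's VAF distribution: the VAF at which a
#' Gaussian kernel density estimate of the VAFs (Silverman's rule-of-thumb
#' bandwidth) is maximal. The density is evaluated on an even grid spanning
#' [0, 1] — not the data range — so peaks are comparable across samples.
#' Ties are broken toward the smallest VAF; a zero-variance input returns
#' the common value directly.
#'
#' @param vafs Numeric vector of VAFs, or a `vaf_set`.
#' @param grid_points Number of evaluation points on [0, 1]; default 512.
#' @param bw Bandwidth selector passed to [stats::density()]; default
#'   `"nrd0"` (Silverman).
#' @return Peak VAF in [0, 1].
#' @export
compute_m_peak <- function(vafs, grid_points = 512, bw = "nrd0") {
  v <- as_vaf_vector(vafs)
  if (length(v) < 2) {
    stop("m_Peak requires at least 2 mutations", call. = FALSE)
  }
  if (stats::sd(v) == 0) {
    return(v[1])
  }
  d <- stats::density(v, bw = bw, n = grid_points, from = 0, to = 1)
  # which.max returns the first maximum; the grid ascends, so ties resolve
  # to the smallest VAF
  d$x[which.max(d$y)]
}

as_vaf_vector <- function(vafs) {
  if (inherits(vafs, "vaf_set")) vafs$vafs else as.numeric(vafs)
}

#' Shape parameters for a whole cohort
#'
#' Computes (m_Peak, m_Count, m_MATH) for every sample and the pairwise
#' Pearson correlation matrix of the three parameters across the cohort.
#' Correlations are undefined (NA) with fewer than 2 samples or when a
#' parameter has zero variance.
#'
#' @param vaf_sets Named list of `vaf_set` objects (see
#'   [run_filter_chain()]), each with at least 2 VAFs.
#' @param grid_points,bw Passed to [compute_m_peak()].
#' @param scale_constant,percent Passed to [compute_m_math()].
#' @return List with `params` (data frame: `sample_id`, `m_peak`, `m_count`,
#'   `m_math`, `n_mf`) and `correlations` (3x3 matrix).
#' @export
profile_cohort <- function(vaf_sets, grid_points = 512, bw = "nrd0",
                           scale_constant = 1.4826, percent = FALSE) {
  params <- do.call(rbind, lapply(vaf_sets, function(vs) {
    data.frame(
      sample_id = vs$sample_id,
      m_peak = compute_m_peak(vs, grid_points = grid_points, bw = bw),
      m_count = compute_m_count(vs),
      m_math = compute_m_math(vs, scale_constant = scale_constant,
                              percent = percent),
      n_mf = length(vs$vafs),
      stringsAsFactors = FALSE
    )
  }))
  rownames(params) <- NULL
  feats <- c("m_peak", "m_count", "m_math")
  cors <- matrix(NA_real_, 3, 3, dimnames = list(feats, feats))
  if (nrow(params) >= 2) {
    for (a in feats) {
      for (b in feats) {
        if (stats::sd(params[[a]]) > 0 && stats::sd(params[[b]]) > 0) {
          cors[a, b] <- stats::cor(params[[a]], params[[b]])
        }
      }
    }
  }
  list(params = params, correlations = cors)
}
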