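#' Filter mutations by sequencing depth
#'
#' Keeps point mutations whose total coverage (`ref_count + alt_count`) is at
#' least `min_depth`. The boundary is inclusive: a site with exactly
#' `min_depth` reads passes.
#'
#' @param mutations Mutation data frame (see [read_mutations()]).
#' @param min_depth Minimum total read depth; default 20.
#' @return Filtered mutation data frame.
#' @export
filter_depth <- function(mutations, min_depth = 20) {
  stopifnot(min_depth >= 1)
  keep <- (mutations$ref_count + mutations$alt_count) >= min_depth
  mutations[keep, , drop = FALSE]
}

#' Filter mutations to the "more functional" (MF) classes
#'
#' Keeps mutations whose PolyPhen-2 class is `probably_damaging` or
#' `possibly_damaging`. `benign` and `unknown` (unannotated or non-missense)
#' records are treated as non-MF and dropped.
#'
#' @param mutations Mutation data frame.
#' @return Filtered mutation data frame.
#' @export
filter_mf <- function(mutations) {
  keep <- mutations$polyphen_class %in%
    c("probably_damaging", "possibly_damaging")
  mutations[keep, , drop = FALSE]
}

#' Filter mutations to copy-neutral regions
#'
#' A mutation is kept iff it lies within (1-based inclusive) at least one
#' segment of the same sample whose log2 segment mean is inside
#' `[mean_lo, mean_hi]` and whose probe count is at least `min_probes`.
#' Mutations covered by no such segment — including mutations outside every
#' segment, whose copy-number status is unknown — are dropped.
#'
#' @param mutations Mutation data frame.
#' @param segments Segment data frame (see [read_segments()]); may contain
#'   segments of many samples, only same-sample segments are consulted.
#' @param mean_lo,mean_hi Copy-neutral window on the log2 segment mean;
#'   defaults -0.2 and 0.2 (inclusive).
#' @param min_probes Minimum probe count for a segment to be trusted;
#'   default 10.
#' @return Filtered mutation data frame.
#' @export
filter_copy_neutral <- function(mutations, segments,
                                mean_lo = -0.2, mean_hi = 0.2,
                                min_probes = 10) {
  if (nrow(mutations) == 0) {
    return(mutations)
  }
  ok_seg <- segments[segments$segment_mean >= mean_lo &
                       segments$segment_mean <= mean_hi &
                       segments$num_probes >= min_probes, , drop = FALSE]
  keep <- logical(nrow(mutations))
  seg_split <- split(ok_seg, ok_seg$sample_id)
  mut_idx <- split(seq_len(nrow(mutations)), mutations$sample_id)
  for (sid in names(mut_idx)) {
    segs <- seg_split[[sid]]
    if (is.null(segs) || nrow(segs) == 0) next
    idx <- mut_idx[[sid]]
    for (i in idx) {
      keep[i] <- any(segs$chrom == mutations$chrom[i] &
                       segs$start <= mutations$pos[i] &
                       segs$end >= mutations$pos[i])
    }
  }
  mutations[keep, , drop = FALSE]
}

#' Compute purity-adjusted VAFs for one sample
#'
#' Raw VAF is the proportion of variant reads at the site,
#' `alt_count / (alt_count + ref_count)`. The purity-adjusted VAF divides by
#' tumor purity and, by default, caps at 1 (an observed VAF above what a pure
#' tumor could show); the number of capped values is reported. Records with
#' zero total reads cannot yield a VAF and are rejected with a count.
#'
#' @param mutations Mutation data frame, already filtered.
#' @param purity Tumor purity in (0, 1].
#' @param cap Logical; cap adjusted VAFs at 1 (default `TRUE`).
#' @return A `vaf_set` list: `sample_id`, `vafs` (in input order), counts
#'   `n_capped` and `n_zero_depth`.
#' @export
compute_adjusted_vafs <- function(mutations, purity, cap = TRUE) {
  stopifnot(length(purity) == 1, purity > 0, purity <= 1)
  total <- mutations$ref_count + mutations$alt_count
  zero <- total == 0
  raw <- mutations$alt_count[!zero] / total[!zero]
  adj <- raw / purity
  n_capped <- sum(adj > 1)
  if (cap) adj <- pmin(adj, 1)
  structure(
    list(
      sample_id = if (nrow(mutations) > 0) mutations$sample_id[1] else NA_character_,
      vafs = adj,
      n_capped = n_capped,
      n_zero_depth = sum(zero)
    ),
    class = "vaf_set"
  )
}

#' Run the full MF filter chain over a cohort
#'
#' Applies, per sample: depth filter, MF (PolyPhen class) filter, copy-neutral
#' segment filter, then purity adjustment. Samples with fewer than `min_mf`
#' surviving mutations are excluded from downstream shape computation and
#' listed in the report with a reason, as are samples missing from the
#' clinical table or lacking a purity estimate (when `missing_purity =
#' "drop"`, the default; `"assume_pure"` uses purity 1 instead).
#'
#' @param mutations Cohort mutation data frame.
#' @param segments Cohort segment data frame.
#' @param clinical Clinical data frame with `sample_id` and `purity`.
#' @param min_depth,mean_lo,mean_hi,min_probes Filter thresholds; see
#'   [filter_depth()] and [filter_copy_neutral()].
#' @param min_mf Minimum surviving MF mutations for a sample to be profiled;
#'   default 2.
#' @param cap Cap purity-adjusted VAFs at 1; default `TRUE`.
#' @param missing_clinical `"drop"` (default, with a warning) or `"error"`
#'   for samples present in the mutation table but absent from the clinical
#'   table.
#' @param missing_purity `"drop"` (default) or `"assume_pure"` for samples
#'   whose purity is `NA`.
#' @return A list with `vaf_sets` (named list of `vaf_set` objects for
#'   retained samples) and `report` (one row per sample: counts after each
#'   stage, capped-VAF count, exclusion flag and reason).
#' @export
run_filter_chain <- function(mutations, segments, clinical,
                             min_depth = 20, mean_lo = -0.2, mean_hi = 0.2,
                             min_probes = 10, min_mf = 2, cap = TRUE,
                             missing_clinical = c("drop", "error"),
                             missing_purity = c("drop", "assume_pure")) {
  missing_clinical <- match.arg(missing_clinical)
  missing_purity <- match.arg(missing_purity)

  sample_ids <- unique(mutations$sample_id)
  unknown <- setdiff(sample_ids, clinical$sample_id)
  if (length(unknown) > 0) {
    if (missing_clinical == "error") {
      stop("samples missing from clinical table: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    warning("dropping ", length(unknown),
            " sample(s) missing from clinical table", call. = FALSE)
  }

  vaf_sets <- list()
  rows <- vector("list", length(sample_ids))
  for (j in seq_along(sample_ids)) {
    sid <- sample_ids[j]
    m0 <- mutations[mutations$sample_id == sid, , drop = FALSE]
    n_input <- nrow(m0)

    reason <- NA_character_
    purity <- NA_real_
    if (sid %in% unknown) {
      reason <- "no_clinical_record"
    } else {
      purity <- clinical$purity[match(sid, clinical$sample_id)]
      if (is.na(purity)) {
        if (missing_purity == "assume_pure") purity <- 1 else reason <- "no_purity"
      }
    }

    m1 <- filter_depth(m0, min_depth)
    m2 <- filter_mf(m1)
    m3 <- filter_copy_neutral(m2, segments, mean_lo, mean_hi, min_probes)
    n_capped <- NA_integer_
    if (is.na(reason)) {
      vs <- compute_adjusted_vafs(m3, purity, cap = cap)
      vs$sample_id <- sid
      n_capped <- vs$n_capped
      if (length(vs$vafs) < min_mf) {
        reason <- sprintf("fewer_than_%d_mf_mutations", min_mf)
      } else {
        vs$n_input <- n_input
        vs$n_after_depth <- nrow(m1)
        vs$n_after_mf <- nrow(m2)
        vs$n_after_cnv <- nrow(m3)
        vaf_sets[[sid]] <- vs
      }
    }
    rows[[j]] <- data.frame(
      sample_id = sid, n_input = n_input, n_after_depth = nrow(m1),
      n_after_mf = nrow(m2), n_after_cnv = nrow(m3), n_capped = n_capped,
      excluded = !is.na(reason), reason = reason, stringsAsFactors = FALSE
    )
  }
  list(vaf_sets = vaf_sets, report = do.call(rbind, rows))
}
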