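#' Kaplan-Meier survival estimates per group
#'
#' Product-limit estimator for each group label. Empty groups are skipped
#' with a warning. Ties at an event time are handled by a simultaneous drop.
#'
#' @param times Non-negative follow-up times.
#' @param events Binary event indicator (1 = death observed, 0 = censored).
#' @param groups Group labels (cluster ids).
#' @return Data frame with columns `group`, `time`, `n_risk`, `n_event`,
#'   `survival`, one row per distinct time per group.
#' @export
km_estimate <- function(times, events, groups) {
  stopifnot(all(times >= 0), all(events %in% c(0, 1)))
  keep <- !is.na(times) & !is.na(events) & !is.na(groups)
  times <- times[keep]; events <- events[keep]; groups <- groups[keep]
  empty <- setdiff(unique(groups), groups)
  if (length(empty) > 0) {
    warning("empty group(s) skipped: ", paste(empty, collapse = ", "))
  }
  rows <- lapply(sort(unique(groups)), function(g) {
    i <- groups == g
    sf <- survival::survfit(survival::Surv(times[i], events[i]) ~ 1)
    data.frame(group = g, time = sf$time, n_risk = sf$n.risk,
               n_event = sf$n.event, survival = sf$surv,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

stage_to_binary <- function(stage) {
  out <- rep(NA_character_, length(stage))
  out[stage %in% c("I", "II")] <- "I/II"
  out[stage %in% c("III", "IV")] <- "III/IV"
  out
}

#' Cox proportional-hazards comparison of clusters
#'
#' Fits a Cox model with cluster as an indicator-coded factor against a
#' reference cluster, optionally adjusted for age, gender and cancer stage
#' (stage binarized to I/II vs III/IV by default). Clusters with fewer than
#' `min_cluster_size` samples are excluded before fitting and listed in the
#' result. Ties use the Efron approximation. Covariate-missing samples are
#' dropped (complete-case), with the count reported. A cluster with no
#' observed events is flagged `unstable` (its hazard ratio diverges).
#'
#' @param times,events Survival times (days) and event indicators.
#' @param labels Cluster id per sample.
#' @param reference Reference cluster id; must pass the size gate.
#' @param covariates Optional data frame with any of `age` (numeric),
#'   `gender`, `stage` (I-IV), row-aligned with `times`.
#' @param min_cluster_size Minimum samples per cluster; default 10.
#' @param stage_binary Binarize stage to I/II vs III/IV; default `TRUE`.
#' @return A `cox_result` list: `reference`, `table` (cluster, n, n_events,
#'   hr, ci_low, ci_high, p, unstable), `excluded_clusters`,
#'   `covariates_used`, `n_samples`, `n_dropped_missing`, `ph_test`
#'   (global scaled-Schoenfeld p, NA if not computable), `fit` (the
#'   underlying `coxph` object).
#' @export
fit_cox <- function(times, events, labels, reference, covariates = NULL,
                    min_cluster_size = 10, stage_binary = TRUE) {
  df <- data.frame(time = times, event = events, cluster = labels)
  covariates_used <- character(0)
  if (!is.null(covariates)) {
    if ("age" %in% names(covariates)) df$age <- covariates$age
    if ("gender" %in% names(covariates)) df$gender <- as.character(covariates$gender)
    if ("stage" %in% names(covariates)) {
      df$stage <- if (stage_binary) stage_to_binary(as.character(covariates$stage))
                  else as.character(covariates$stage)
    }
  }

  sizes <- table(df$cluster)
  eligible <- names(sizes)[sizes >= min_cluster_size]
  excluded <- sort(unique(df$cluster[!df$cluster %in% eligible]))
  if (!as.character(reference) %in% eligible) {
    stop("reference cluster ", reference, " fails the size gate (n >= ",
         min_cluster_size, ")", call. = FALSE)
  }
  if (length(eligible) < 2) {
    stop("fewer than 2 clusters pass the size gate; nothing to compare",
         call. = FALSE)
  }
  df <- df[df$cluster %in% eligible, , drop = FALSE]

  n0 <- nrow(df)
  df <- df[stats::complete.cases(df[, c("time", "event", "cluster")]), , drop = FALSE]
  terms <- "cluster"
  for (cv in intersect(c("age", "gender", "stage"), names(df))) {
    ok <- !is.na(df[[cv]])
    # only use a covariate if observed for (nearly) all samples would be too
    # strict; complete-case per model: drop rows missing a requested covariate
    df <- df[ok, , drop = FALSE]
    if (cv %in% c("gender", "stage") && length(unique(df[[cv]])) < 2) next
    terms <- c(terms, cv)
    covariates_used <- c(covariates_used, cv)
  }
  n_dropped <- n0 - nrow(df)

  df$cluster <- stats::relevel(factor(df$cluster), ref = as.character(reference))
  fml <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                 paste(terms, collapse = " + ")))
  fit <- survival::coxph(fml, data = df, ties = "efron")
  if (!is.null(fit$info) && isTRUE(fit$info$flag)) {
    stop("Cox model failed to converge", call. = FALSE)
  }
  sm <- summary(fit)

  other <- setdiff(levels(df$cluster), as.character(reference))
  coef_names <- paste0("cluster", other)
  events_by_cluster <- tapply(df$event, df$cluster, sum)
  tab <- data.frame(
    cluster = other,
    n = as.integer(table(df$cluster)[other]),
    n_events = as.integer(events_by_cluster[other]),
    hr = sm$conf.int[coef_names, "exp(coef)"],
    ci_low = sm$conf.int[coef_names, "lower .95"],
    ci_high = sm$conf.int[coef_names, "upper .95"],
    p = sm$coefficients[coef_names, "Pr(>|z|)"],
    stringsAsFactors = FALSE
  )
  tab$unstable <- tab$n_events == 0 | !is.finite(tab$hr) | tab$ci_high > 1e4
  rownames(tab) <- NULL

  ph_p <- tryCatch(
    {
      z <- survival::cox.zph(fit)
      z$table["GLOBAL", "p"]
    },
    error = function(e) NA_real_
  )

  structure(
    list(
      reference = reference, table = tab,
      excluded_clusters = excluded, covariates_used = covariates_used,
      n_samples = nrow(df), n_dropped_missing = n_dropped,
      reference_n = as.integer(sum(df$cluster == as.character(reference))),
      reference_events = as.integer(events_by_cluster[as.character(reference)]),
      ph_test = ph_p, fit = fit
    ),
    class = "cox_result"
  )
}

#' Univariate Cox comparison of clusters
#'
#' [fit_cox()] with no covariates: the cluster factor is the only term.
#'
#' @inheritParams fit_cox
#' @return A `cox_result`; see [fit_cox()].
#' @export
univariate_cluster_cox <- function(times, events, labels, reference,
                                   min_cluster_size = 10) {
  fit_cox(times, events, labels, reference, covariates = NULL,
          min_cluster_size = min_cluster_size)
}

#' Hazard-ratio matrix over all candidate references
#'
#' Fits a single Cox model and derives, for every ordered pair of eligible
#' clusters, the hazard ratio of cluster `j` relative to reference `r`
#' (`HR[r, j] = exp(beta_j - beta_r)`). Used by
#' [select_reference_cluster()].
#'
#' @inheritParams fit_cox
#' @return Square matrix with reference clusters as rows, compared clusters
#'   as columns, and `NA` on the diagonal.
#' @export
cox_hr_matrix <- function(times, events, labels, covariates = NULL,
                          min_cluster_size = 10, stage_binary = TRUE) {
  sizes <- table(labels)
  eligible <- sort(names(sizes)[sizes >= min_cluster_size])
  if (length(eligible) < 2) {
    stop("fewer than 2 clusters pass the size gate", call. = FALSE)
  }
  res <- fit_cox(times, events, labels, reference = eligible[1],
                 covariates = covariates, min_cluster_size = min_cluster_size,
                 stage_binary = stage_binary)
  logh <- stats::setNames(c(0, log(res$table$hr)),
                          c(as.character(eligible[1]), res$table$cluster))
  logh <- logh[eligible]
  hr <- outer(logh, logh, function(r, j) exp(j - r))
  diag(hr) <- NA
  dimnames(hr) <- list(reference = eligible, cluster = eligible)
  hr
}

#' Select the reference cluster for survival comparisons
#'
#' Returns the cluster which, used as reference, yields a hazard ratio > 1
#' for every other cluster (i.e. the uniformly lowest-hazard cluster). If no
#' cluster — or more than one — qualifies, falls back to the cluster
#' minimizing the worst-case reciprocal hazard ratio
#' `max_j 1/HR[r, j]` (ties to the lowest cluster id) and sets a flag.
#'
#' @param hr_table Square hazard-ratio matrix as from [cox_hr_matrix()]:
#'   rows are candidate references, `hr_table[r, j]` is the HR of cluster
#'   `j` vs reference `r`, diagonal `NA`.
#' @return List with `reference` (dimname of the chosen row), `qualified`
#'   (logical: did a unique all-HR>1 reference exist) and `candidates`
#'   (dimnames of all qualifying rows).
#' @export
select_reference_cluster <- function(hr_table) {
  stopifnot(nrow(hr_table) == ncol(hr_table), nrow(hr_table) >= 2)
  refs <- rownames(hr_table)
  all_gt1 <- apply(hr_table, 1, function(r) all(r[!is.na(r)] > 1))
  if (sum(all_gt1) == 1) {
    return(list(reference = refs[all_gt1], qualified = TRUE,
                candidates = refs[all_gt1]))
  }
  worst <- apply(hr_table, 1, function(r) max(1 / r[!is.na(r)]))
  list(reference = refs[which.min(worst)], qualified = FALSE,
       candidates = refs[all_gt1])
}
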