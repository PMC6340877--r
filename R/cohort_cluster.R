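#' Principal component analysis of the three shape parameters
#'
#' Centers (and, by default, scales to unit variance) the columns
#' `m_peak`, `m_count`, `m_math` and computes the principal axes. The three
#' parameters live on incommensurate scales (m_count roughly 1-10, the other
#' two in [0, 1]), so standardization is on by default.
#'
#' @param params Shape-parameter data frame (see [profile_cohort()]).
#' @param standardize Scale features to unit variance; default `TRUE`.
#' @return An `ith_pca` list: `feature_means`, `feature_scales`, `loadings`
#'   (3x3 orthonormal), `explained` (variance fractions, descending, summing
#'   to 1), `scores` (n x 3 matrix, rownames = sample ids).
#' @export
fit_pca <- function(params, standardize = TRUE) {
  feats <- c("m_peak", "m_count", "m_math")
  x <- as.matrix(params[, feats])
  if (nrow(x) < 3) {
    stop("PCA requires at least 3 samples", call. = FALSE)
  }
  sds <- apply(x, 2, stats::sd)
  if (standardize && any(sds == 0)) {
    stop("zero-variance feature(s): ",
         paste(feats[sds == 0], collapse = ", "), call. = FALSE)
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = standardize)
  scores <- pc$x
  rownames(scores) <- params$sample_id
  structure(
    list(
      feature_means = pc$center,
      feature_scales = if (standardize) pc$scale else stats::setNames(rep(1, 3), feats),
      loadings = pc$rotation,
      explained = pc$sdev^2 / sum(pc$sdev^2),
      scores = scores
    ),
    class = "ith_pca"
  )
}

#' Embed shape parameters with a fitted PCA
#'
#' @param pca An `ith_pca` model.
#' @param params Shape-parameter data frame (any number of rows).
#' @return n x 3 score matrix.
#' @export
pca_transform <- function(pca, params) {
  feats <- c("m_peak", "m_count", "m_math")
  x <- as.matrix(params[, feats])
  xs <- sweep(sweep(x, 2, pca$feature_means[feats]), 2,
              pca$feature_scales[feats], "/")
  out <- xs %*% pca$loadings
  rownames(out) <- params$sample_id
  out
}

sq_dist_matrix <- function(points) {
  as.matrix(stats::dist(points))^2
}

# Run code with a temporary RNG seed, restoring the caller's stream.
with_local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' k-medoids (PAM) clustering under squared Euclidean distance
#'
#' Partitioning around medoids on the squared Euclidean dissimilarity:
#' BUILD initialization followed by SWAP passes to a local optimum of the
#' total within-cluster cost. Because SWAP explores single-medoid exchanges
#' only, it can stall in local optima (squared distances make these more
#' frequent than for plain Euclidean), so the search is additionally
#' restarted from `restarts` seeded random medoid sets and the lowest-cost
#' solution is kept — the k-medoids analogue of `kmeans`'s `nstart`.
#' Deterministic given `seed` and the input order; medoid ties resolve to
#' the first point in input order.
#'
#' @param points Numeric matrix (n x d) of embedded samples; rownames are
#'   used as sample ids.
#' @param k Number of clusters, `1 <= k <= n`.
#' @param seed Seed for the random restarts; default 1.
#' @param restarts Number of random-initialization restarts in addition to
#'   the deterministic BUILD start; default 20.
#' @return An `ith_kmedoids` list: `k`, `medoid_idx`, `medoid_ids`,
#'   `medoid_coords`, `labels` (named integer vector), `cost` (total
#'   within-cluster squared Euclidean distance).
#' @export
fit_kmedoids <- function(points, k, seed = 1, restarts = 20) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (is.null(rownames(points))) rownames(points) <- as.character(seq_len(n))
  if (k > n) stop("k must not exceed the number of points", call. = FALSE)
  if (n < 1) stop("need at least one point", call. = FALSE)
  if (is.null(seed)) seed <- 1

  d2 <- sq_dist_matrix(points)
  cost_of <- function(med) sum(apply(d2[, med, drop = FALSE], 1, min))
  if (k == n) {
    medoid_idx <- seq_len(n)
    labels <- seq_len(n)
  } else if (k == 1) {
    # exact for a single medoid: the point minimizing total squared
    # distance, first by input order on ties
    medoid_idx <- which.min(colSums(d2))
    labels <- rep(1L, n)
  } else {
    dd <- stats::as.dist(d2)
    fits <- list(cluster::pam(dd, k = k, diss = TRUE))
    inits <- with_local_seed(seed, lapply(seq_len(restarts), function(i) {
      sort(sample.int(n, k))
    }))
    for (ini in unique(inits)) {
      fits[[length(fits) + 1L]] <- cluster::pam(dd, k = k, diss = TRUE,
                                                medoids = ini)
    }
    costs <- vapply(fits, function(f) cost_of(as.integer(f$id.med)),
                    numeric(1))
    fit <- fits[[which.min(costs)]]
    medoid_idx <- as.integer(fit$id.med)
    labels <- as.integer(fit$clustering)
  }
  cost <- sum(d2[cbind(seq_len(n), medoid_idx[labels])])
  structure(
    list(
      k = k,
      medoid_idx = medoid_idx,
      medoid_ids = rownames(points)[medoid_idx],
      medoid_coords = points[medoid_idx, , drop = FALSE],
      labels = stats::setNames(as.integer(labels), rownames(points)),
      cost = cost
    ),
    class = "ith_kmedoids"
  )
}

#' Diagnostics over a range of k
#'
#' Reports the total within-cluster squared Euclidean cost and mean
#' silhouette width for each candidate k. No automatic selection is made:
#' the choice of k is the analyst's (the archetype analysis uses k = 5).
#'
#' @param points Numeric matrix of embedded samples.
#' @param k_range Integer vector of candidate k, each in `[2, n-1]`.
#' @return Data frame with columns `k`, `cost`, `mean_silhouette`.
#' @export
choose_k_diagnostics <- function(points, k_range) {
  points <- as.matrix(points)
  n <- nrow(points)
  stopifnot(all(k_range >= 2), all(k_range <= n - 1))
  d2 <- stats::as.dist(sq_dist_matrix(points))
  rows <- lapply(k_range, function(k) {
    km <- fit_kmedoids(points, k)
    sil <- cluster::silhouette(km$labels, d2)
    data.frame(k = k, cost = km$cost,
               mean_silhouette = mean(sil[, "sil_width"]))
  })
  do.call(rbind, rows)
}

#' Fit the full cohort clustering model
#'
#' PCA embedding of the three shape parameters followed by k-medoids on the
#' first `n_components` principal components (the archetype analysis uses
#' the first two). After fitting, cluster ids are re-ordered by descending
#' median m_count, ties by descending median m_peak, giving stable archetype
#' semantics: clusters 1-2 are mutation-rich (1 clonal-peaked, 2
#' subclone-shifted), clusters 3-5 mutation-poor with decreasing peak VAF
#' and increasing dispersion.
#'
#' @param params Shape-parameter data frame (see [profile_cohort()]).
#' @param k Number of clusters; default 5.
#' @param standardize Standardize features before PCA; default `TRUE`.
#' @param n_components Number of leading components used for clustering;
#'   default 2 (3 clusters on the full space).
#' @param seed Passed to [fit_kmedoids()] (no effect; PAM is deterministic).
#' @return An `ith_cohort_model` list: `pca`, `kmedoids`, `n_components`,
#'   `labels` (named, re-ordered ids), `medoid_sample_ids` (by final id),
#'   `medoid_coords`, `k`.
#' @export
fit_cohort_clusters <- function(params, k = 5, standardize = TRUE,
                                n_components = 2, seed = NULL) {
  pca <- fit_pca(params, standardize = standardize)
  pts <- pca$scores[, seq_len(n_components), drop = FALSE]
  km <- fit_kmedoids(pts, k, seed = seed)

  med_count <- tapply(params$m_count, km$labels, stats::median)
  med_peak <- tapply(params$m_peak, km$labels, stats::median)
  ord <- order(-med_count, -med_peak)  # old ids in new-id order
  relabel <- integer(k)
  relabel[as.integer(names(med_count))[ord]] <- seq_len(k)
  labels <- stats::setNames(relabel[km$labels], names(km$labels))

  medoid_ids <- km$medoid_ids[ord]
  medoid_coords <- km$medoid_coords[ord, , drop = FALSE]
  rownames(medoid_coords) <- medoid_ids
  structure(
    list(
      pca = pca, kmedoids = km, n_components = n_components, k = k,
      labels = labels, medoid_sample_ids = medoid_ids,
      medoid_coords = medoid_coords
    ),
    class = "ith_cohort_model"
  )
}

#' Assign a new sample to a fitted cluster
#'
#' Embeds the sample with the frozen PCA transform and returns the cluster
#' of the nearest medoid under squared Euclidean distance; ties go to the
#' lowest cluster id.
#'
#' @param model An `ith_cohort_model`.
#' @param params One-row shape-parameter data frame (or several rows).
#' @return Integer cluster id(s) in `1..k`.
#' @export
assign_new_sample <- function(model, params) {
  emb <- pca_transform(model$pca, params)[, seq_len(model$n_components),
                                          drop = FALSE]
  apply(emb, 1, function(p) {
    d2 <- colSums((t(model$medoid_coords) - p)^2)
    which.min(d2)  # medoids stored in cluster-id order; first min = lowest id
  })
}

#' Persist a fitted cohort model as JSON
#'
#' @param model An `ith_cohort_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_cohort_model <- function(model, path) {
  payload <- list(
    k = model$k,
    n_components = model$n_components,
    feature_means = as.list(model$pca$feature_means),
    feature_scales = as.list(model$pca$feature_scales),
    loadings = model$pca$loadings,
    explained = model$pca$explained,
    medoid_sample_ids = model$medoid_sample_ids,
    medoid_coords = model$medoid_coords,
    labels = as.list(model$labels)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a cohort model saved with [save_cohort_model()]
#'
#' The PCA score matrix of the training cohort is not persisted; the loaded
#' model supports [assign_new_sample()] but not refitting.
#'
#' @param path JSON file written by [save_cohort_model()].
#' @return An `ith_cohort_model`.
#' @export
load_cohort_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  feats <- c("m_peak", "m_count", "m_math")
  loadings <- as.matrix(p$loadings)
  dimnames(loadings) <- list(feats, paste0("PC", 1:3))
  medoid_coords <- as.matrix(p$medoid_coords)
  rownames(medoid_coords) <- p$medoid_sample_ids
  structure(
    list(
      pca = structure(
        list(
          feature_means = unlist(p$feature_means)[feats],
          feature_scales = unlist(p$feature_scales)[feats],
          loadings = loadings,
          explained = p$explained,
          scores = NULL
        ),
        class = "ith_pca"
      ),
      kmedoids = NULL,
      n_components = p$n_components, k = p$k,
      labels = stats::setNames(as.integer(unlist(p$labels)), names(p$labels)),
      medoid_sample_ids = p$medoid_sample_ids,
      medoid_coords = medoid_coords
    ),
    class = "ith_cohort_model"
  )
}
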