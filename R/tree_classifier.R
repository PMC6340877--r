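#' CART decision tree over the three shape parameters
#'
#' Grows a Gini-impurity classification tree on (m_peak, m_count, m_math)
#' and prunes it with a complexity parameter: a split survives only if it
#' reduces the tree's risk by at least `cp` times the root risk (the rpart
#' convention). Splits send values below the threshold left, values at or
#' above it right. Deterministic given the input order.
#'
#' @param params Shape-parameter data frame with columns `m_peak`,
#'   `m_count`, `m_math`.
#' @param labels Cluster id per row of `params`.
#' @param cp Complexity parameter for pruning; default 0.1.
#' @param min_leaf Minimum samples per leaf; default 5.
#' @return An `ith_tree` list: `rpart` (the fitted, pruned rpart object),
#'   `cp`, `min_leaf`, `classes`, `n_leaves`, `training_accuracy`.
#' @export
fit_cart <- function(params, labels, cp = 0.1, min_leaf = 5) {
  df <- data.frame(
    label = factor(labels),
    m_peak = params$m_peak, m_count = params$m_count, m_math = params$m_math
  )
  if (nlevels(df$label) < 2) {
    warning("single-class input: returning a one-leaf tree")
  }
  fit <- rpart::rpart(
    label ~ m_peak + m_count + m_math, data = df, method = "class",
    control = rpart::rpart.control(
      cp = 0, minbucket = min_leaf, minsplit = max(2L, 2L * min_leaf),
      xval = 0, maxsurrogate = 0, usesurrogate = 0
    )
  )
  fit <- rpart::prune(fit, cp = cp)
  pred <- stats::predict(fit, df, type = "class")
  structure(
    list(
      rpart = fit, cp = cp, min_leaf = min_leaf,
      classes = levels(df$label),
      n_leaves = sum(fit$frame$var == "<leaf>"),
      training_accuracy = mean(pred == df$label)
    ),
    class = "ith_tree"
  )
}

#' Predict cluster labels with a fitted tree
#'
#' Routes each sample down the tree by comparing features to split
#' thresholds (value below the threshold goes left, at or above goes right)
#' and returns the leaf's majority class.
#'
#' @param object An `ith_tree` from [fit_cart()].
#' @param newdata Shape-parameter data frame.
#' @param ... Unused.
#' @return Character vector of predicted cluster ids.
#' @export
predict.ith_tree <- function(object, newdata, ...) {
  as.character(stats::predict(object$rpart, newdata, type = "class"))
}

#' Stratified k-fold cross-validation of the tree classifier
#'
#' Assigns folds stratified by cluster label (falling back to unstratified
#' assignment, with a warning, if any class has fewer members than folds),
#' fits the pruned tree on each training split and evaluates accuracy on
#' the held-out fold.
#'
#' @param params Shape-parameter data frame.
#' @param labels Cluster id per row.
#' @param folds Number of folds; default 10.
#' @param seed Seed for the fold assignment.
#' @param cp,min_leaf Passed to [fit_cart()].
#' @return List with `fold_accuracy` (numeric vector), `mean`, `sd`, `max`.
#' @export
cross_validate <- function(params, labels, folds = 10, seed = 1,
                           cp = 0.1, min_leaf = 5) {
  n <- nrow(params)
  stopifnot(folds >= 2, folds <= n)
  labels <- as.character(labels)
  set.seed(seed)
  sizes <- table(labels)
  if (any(sizes < folds)) {
    warning("class with fewer members than folds: unstratified assignment")
    fold_id <- sample(rep_len(seq_len(folds), n))
  } else {
    fold_id <- integer(n)
    for (cl in names(sizes)) {
      idx <- which(labels == cl)
      fold_id[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
  }
  acc <- vapply(seq_len(folds), function(f) {
    train <- fold_id != f
    tree <- fit_cart(params[train, , drop = FALSE], labels[train],
                     cp = cp, min_leaf = min_leaf)
    mean(predict(tree, params[!train, , drop = FALSE]) == labels[!train])
  }, numeric(1))
  list(fold_accuracy = acc, mean = mean(acc), sd = stats::sd(acc),
       max = max(acc))
}

#' Render a fitted tree's split rules as text
#'
#' Indented listing of the split rules (feature, inequality, threshold) and
#' leaf classes with their purity, suitable for reports.
#'
#' @param tree An `ith_tree`.
#' @return Character vector of lines.
#' @export
render_tree <- function(tree) {
  utils::capture.output(print(tree$rpart))
}
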