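#' Stratified train/test split
#'
#' Splits samples into disjoint, exhaustive train and test sets, sampling
#' `round(fraction * n_c)` test members within each class so class
#' proportions are preserved to rounding.
#'
#' @param labels factor or character class label per sample (two classes).
#' @param fraction test fraction (default 0.2).
#' @param seed integer seed controlling the draw.
#' @return list with integer index vectors `train` and `test`.
#' @export
split_train_test <- function(labels, fraction = 0.2, seed = 1L) {
  labels <- as.factor(labels)
  counts <- table(labels)
  if (any(counts < 5L))
    stop("every class needs >= 5 members for an 80/20 split plus 5-fold CV")
  rng <- local_rng(seed)
  test <- integer()
  for (cl in levels(labels)) {
    idx <- which(labels == cl)
    n_test <- max(1L, round(fraction * length(idx)))
    test <- c(test, rng$sample(idx, n_test))
  }
  test <- sort(test)
  list(train = setdiff(seq_along(labels), test), test = test)
}

#' Default random-forest tuning grid
#'
#' Number of trees \{100, 300, 500\}, tree depth \{3, 5, unlimited\}
#' (implemented as `maxnodes` \{8, 32, unlimited\}) and minimum terminal node
#' size \{2, 5, 10\} (`nodesize`, the randomForest analogue of a minimum
#' split size).
#'
#' @return a data.frame with columns `ntree`, `maxnodes`, `nodesize`
#'   (`maxnodes = NA` means unlimited).
#' @export
default_rf_grid <- function() {
  expand.grid(ntree = c(100L, 300L, 500L), maxnodes = c(8L, 32L, NA),
              nodesize = c(2L, 5L, 10L))
}

fit_rf <- function(x, y, cfg, seed) {
  set.seed(seed)
  args <- list(x = x, y = y, ntree = cfg$ntree, nodesize = cfg$nodesize,
               importance = FALSE)
  # a tree on n samples cannot have more than n terminal nodes
  if (!is.na(cfg$maxnodes)) args$maxnodes <- min(cfg$maxnodes, nrow(x))
  do.call(randomForest::randomForest, args)
}

#' Tune and fit a random forest by stratified cross-validation
#'
#' Grid search over the declared hyperparameter grid: each configuration is
#' scored by mean accuracy over `folds` stratified CV folds of the training
#' set, the best configuration (ties broken by grid order) is refit on the
#' full training set.
#'
#' @param x numeric feature matrix (training rows).
#' @param y class labels (factor, two levels).
#' @param folds number of CV folds (default 5).
#' @param grid hyperparameter grid, see [default_rf_grid()].
#' @param seed integer seed for fold assignment and forest randomness.
#' @return list with `model` (a `randomForest`), `best` (one grid row),
#'   `cv_accuracy` (per-configuration mean CV accuracy).
#' @export
tune_and_fit <- function(x, y, folds = 5L, grid = default_rf_grid(), seed = 1L) {
  y <- droplevels(as.factor(y))
  x <- as.matrix(x)
  fold_id <- stratified_folds(y, folds, seed)
  acc <- numeric(nrow(grid))
  for (ci in seq_len(nrow(grid))) {
    correct <- 0L
    for (k in seq_len(folds)) {
      tr <- fold_id != k
      if (length(unique(y[tr])) < 2L) stop("degenerate fold: single class")
      fit <- fit_rf(x[tr, , drop = FALSE], y[tr], grid[ci, ], seed + k)
      pred <- predict(fit, x[!tr, , drop = FALSE])
      correct <- correct + sum(pred == y[!tr])
    }
    acc[ci] <- correct / length(y)
  }
  best <- grid[which.max(acc), ]
  model <- fit_rf(x, y, best, seed)
  list(model = model, best = best, cv_accuracy = acc)
}

stratified_folds <- function(y, folds, seed) {
  rng <- local_rng(seed)
  fold_id <- integer(length(y))
  for (cl in levels(y)) {
    idx <- rng$sample(which(y == cl), sum(y == cl))
    fold_id[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fold_id
}

#' Hold-out classification metrics
#'
#' Accuracy plus class-weighted (support-weighted) precision, recall and F1.
#' With weighting by class support, recall coincides with accuracy.
#'
#' @param predicted,actual class labels of equal length.
#' @return named numeric vector `accuracy`, `precision`, `recall`, `f1`.
#' @export
classification_metrics <- function(predicted, actual) {
  if (length(actual) == 0L) stop("empty test set")
  actual <- as.factor(actual)
  predicted <- factor(predicted, levels = levels(actual))
  acc <- mean(predicted == actual)
  per_class <- t(vapply(levels(actual), function(cl) {
    tp <- sum(predicted == cl & actual == cl)
    prec <- if (sum(predicted == cl) > 0) tp / sum(predicted == cl) else 0
    rec <- if (sum(actual == cl) > 0) tp / sum(actual == cl) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    c(prec = prec, rec = rec, f1 = f1, n = sum(actual == cl))
  }, c(prec = 0, rec = 0, f1 = 0, n = 0)))
  w <- per_class[, "n"] / sum(per_class[, "n"])
  c(accuracy = acc,
    precision = sum(w * per_class[, "prec"]),
    recall = sum(w * per_class[, "rec"]),
    f1 = sum(w * per_class[, "f1"]))
}

#' Normalized random-forest feature importances
#'
#' Impurity-based (mean decrease in Gini) importances rescaled to sum to 1
#' and sorted descending.
#'
#' @param model a fitted `randomForest`.
#' @return named numeric vector summing to 1.
#' @export
feature_importance <- function(model) {
  imp <- randomForest::importance(model, type = 2)[, 1L]
  imp[imp < 0] <- 0
  if (sum(imp) > 0) imp <- imp / sum(imp)
  sort(imp, decreasing = TRUE)
}

#' Binary classification of subject groups from hyperedge weights
#'
#' The full protocol for one binary task: restrict the weight table to the
#' two groups (and optionally to the statistically significant hyperedges),
#' make a stratified 80/20 train/test split, tune and fit a random forest by
#' 5-fold CV on the training set, and report hold-out metrics and normalized
#' feature importances.
#'
#' @param wt a `weight_table` with group labels.
#' @param task character vector of the two group labels to contrast, e.g.
#'   `c("HC", "AD")`.
#' @param significant_ids optional hyperedge ids to use as features (default:
#'   all).
#' @param fraction hold-out fraction (default 0.2).
#' @param folds CV folds (default 5).
#' @param grid hyperparameter grid (default [default_rf_grid()]).
#' @param seed integer seed (split, folds, forests).
#' @return an object of class `hyperfc_classifier`: list with `task`,
#'   `metrics`, `best_hyperparameters`, `feature_importance`, `model`,
#'   `split`, `seed`.
#' @export
classify_weights <- function(wt, task, significant_ids = NULL, fraction = 0.2,
                             folds = 5L, grid = default_rf_grid(), seed = 1L) {
  stopifnot(inherits(wt, "weight_table"), length(task) == 2L)
  keep <- wt$group_labels %in% task
  if (!all(task %in% wt$group_labels)) stop("task groups absent from weight table")
  x <- wt$values[keep, , drop = FALSE]
  if (!is.null(significant_ids)) {
    cols <- match(significant_ids, colnames(x))
    if (anyNA(cols)) stop("unknown hyperedge id(s) in significant_ids")
    x <- x[, cols, drop = FALSE]
  }
  y <- factor(wt$group_labels[keep], levels = task)
  sp <- split_train_test(y, fraction, seed)
  tuned <- tune_and_fit(x[sp$train, , drop = FALSE], y[sp$train],
                        folds = folds, grid = grid, seed = seed)
  pred <- predict(tuned$model, x[sp$test, , drop = FALSE])
  structure(list(task = paste(task, collapse = " vs "),
                 metrics = classification_metrics(pred, y[sp$test]),
                 best_hyperparameters = tuned$best,
                 cv_accuracy = tuned$cv_accuracy,
                 feature_importance = feature_importance(tuned$model),
                 model = tuned$model, split = sp, seed = as.integer(seed)),
            class = "hyperfc_classifier")
}

#' @export
print.hyperfc_classifier <- function(x, ...) {
  cat(sprintf("Random-forest task %s (seed %d)\n", x$task, x$seed))
  cat(sprintf("  hold-out: accuracy %.3f, precision %.3f, recall %.3f, F1 %.3f\n",
              x$metrics["accuracy"], x$metrics["precision"],
              x$metrics["recall"], x$metrics["f1"]))
  b <- x$best_hyperparameters
  cat(sprintf("  best config: ntree %d, maxnodes %s, nodesize %d\n",
              b$ntree, ifelse(is.na(b$maxnodes), "unlimited", b$maxnodes),
              b$nodesize))
  cat("  top features:", paste(names(head(x$feature_importance, 5L)),
                               collapse = ", "), "\n")
  invisible(x)
}
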