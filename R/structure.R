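#' Non-negative LASSO fit for one centroid region
#'
#' Regresses the centroid region's z-scored time series on all other regions
#' under an L1 penalty and a non-negativity constraint, the sparse-regression
#' step of hypergraph structure inference. The objective is the per-sample
#' averaged form
#' \deqn{\min_{\alpha \ge 0} \frac{1}{2P} \|x_n - X_n \alpha\|_2^2 +
#'       \lambda \|\alpha\|_1,}
#' where the centroid's own column of the design is replaced by zeros (so its
#' coefficient is structurally 0). Solved by cyclic projected coordinate
#' descent to a coefficient-change tolerance of `tol`.
#'
#' @param panel a z-scored [ts_panel()].
#' @param centroid region index of the response series.
#' @param lambda non-negative sparsity penalty.
#' @param tol convergence tolerance on the maximum coefficient change per
#'   sweep (default 1e-10).
#' @param max_iter maximum coordinate-descent sweeps (default 1e5).
#' @return numeric length-`N` coefficient vector, all entries `>= 0`, with
#'   entry `centroid` exactly 0.
#' @export
fit_nonneg_lasso <- function(panel, centroid, lambda, tol = 1e-10,
                             max_iter = 100000L) {
  assert_zscored(panel)
  if (lambda < 0) stop("lambda must be >= 0")
  N <- nrow(panel$data)
  centroid <- as.integer(centroid)
  if (centroid < 1L || centroid > N) stop("centroid index out of range")
  X <- t(panel$data)                  # P x N design; column = region series
  y <- X[, centroid]
  alpha <- nnlasso_cd(X, y, lambda, exclude = centroid, tol = tol,
                      max_iter = as.integer(max_iter))
  names(alpha) <- panel$region_labels
  alpha
}

#' Per-subject coefficient matrix
#'
#' Fits [fit_nonneg_lasso()] with every region in turn as the centroid. Row
#' `n` of the result is the coefficient vector predicting region `n` from the
#' others; the diagonal is exactly zero.
#'
#' @inheritParams fit_nonneg_lasso
#' @return an object of class `coef_matrix`: list with `entries` (`N x N`
#'   non-negative matrix), `subject_id`, `lambda`.
#' @export
coefficient_matrix <- function(panel, lambda, tol = 1e-10, max_iter = 100000L) {
  assert_zscored(panel)
  N <- nrow(panel$data)
  A <- matrix(0, N, N, dimnames = list(panel$region_labels, panel$region_labels))
  for (n in seq_len(N)) A[n, ] <- fit_nonneg_lasso(panel, n, lambda, tol, max_iter)
  structure(list(entries = A, subject_id = panel$subject_id, lambda = lambda),
            class = "coef_matrix")
}

#' @export
print.coef_matrix <- function(x, ...) {
  cat(sprintf("<coef_matrix> subject %s, %d regions, lambda %.4g, %d positive entries\n",
              x$subject_id, nrow(x$entries), x$lambda, sum(x$entries > 0)))
  invisible(x)
}

#' Select the sparsity penalty by cross-validation over timepoints
#'
#' For every candidate lambda, subject and centroid region, the timepoints
#' are split into `folds` contiguous blocks; the model is fitted on the
#' held-in blocks and scored (mean squared reconstruction error) on the
#' held-out block. The chosen lambda minimizes the mean validation MSE over
#' all (subject, centroid, fold) cells. Folds are contiguous blocks, so the
#' procedure is deterministic; the seed is recorded in the result only.
#'
#' @param panels list of z-scored [ts_panel()] objects.
#' @param grid candidate lambda values; defaults to `seq(0.01, 0.30, 0.01)`.
#' @param folds number of CV folds over timepoints (default 5).
#' @param seed integer recorded in the selection record.
#' @param tol,max_iter solver controls, see [fit_nonneg_lasso()].
#' @return an object of class `lambda_selection`: list with `grid`, `chosen`,
#'   `cv_train_mse`, `cv_val_mse` (each a data.frame of per-lambda mean and
#'   sd), `folds`, `seed`.
#' @export
select_lambda_cv <- function(panels, grid = seq(0.01, 0.30, by = 0.01),
                             folds = 5L, seed = 1L, tol = 1e-8,
                             max_iter = 100000L) {
  if (length(grid) == 0L) stop("empty lambda grid")
  if (folds < 2L) stop("folds must be >= 2")
  if (!is.list(panels) || inherits(panels, "ts_panel")) panels <- list(panels)
  for (p in panels) {
    assert_zscored(p)
    if (ncol(p$data) < folds) stop("panel has fewer timepoints than folds")
  }
  grid <- sort(as.numeric(grid))
  nl <- length(grid)
  tr_mse <- rep(list(numeric(0)), nl)
  va_mse <- rep(list(numeric(0)), nl)
  for (p in panels) {
    X <- t(p$data); P <- nrow(X); N <- ncol(X)
    fold_id <- cv_fold_blocks(P, folds)
    for (n in seq_len(N)) {
      for (k in seq_len(folds)) {
        tr <- fold_id != k
        Xtr <- X[tr, , drop = FALSE]; Xva <- X[!tr, , drop = FALSE]
        warm <- NULL
        for (li in rev(seq_len(nl))) {  # descending lambda, warm starts
          a <- nnlasso_cd(Xtr, Xtr[, n], grid[li], exclude = n, tol = tol,
                          max_iter = as.integer(max_iter), warm = warm)
          warm <- a
          tr_mse[[li]] <- c(tr_mse[[li]], mean((Xtr[, n] - Xtr %*% a)^2))
          va_mse[[li]] <- c(va_mse[[li]], mean((Xva[, n] - Xva %*% a)^2))
        }
      }
    }
  }
  summ <- function(lst) data.frame(
    lambda = grid,
    mean = vapply(lst, mean, 0),
    sd = vapply(lst, function(v) if (length(v) > 1L) sd(v) else 0, 0))
  val <- summ(va_mse)
  structure(list(grid = grid, chosen = grid[which.min(val$mean)],
                 cv_train_mse = summ(tr_mse), cv_val_mse = val,
                 folds = as.integer(folds), seed = as.integer(seed)),
            class = "lambda_selection")
}

cv_fold_blocks <- function(P, folds) {
  # contiguous blocks of timepoints, fold k = [floor((k-1)P/folds), floor(kP/folds))
  bounds <- floor(seq_len(folds + 1L) - 1L) * P / folds
  rep(seq_len(folds), times = diff(floor(bounds)))
}

#' @export
print.lambda_selection <- function(x, ...) {
  i <- match(x$chosen, x$grid)
  cat(sprintf("<lambda_selection> chosen lambda = %.3g over %d candidates (%d-fold CV)\n",
              x$chosen, length(x$grid), x$folds))
  cat(sprintf("  validation MSE %.4g +/- %.4g; training MSE %.4g +/- %.4g\n",
              x$cv_val_mse$mean[i], x$cv_val_mse$sd[i],
              x$cv_train_mse$mean[i], x$cv_train_mse$sd[i]))
  invisible(x)
}

#' Threshold and binarize a coefficient matrix
#'
#' The threshold is the given percentile (linear interpolation between order
#' statistics) of the strictly positive entries of the coefficient matrix;
#' entries below it are removed, entries at or above it become 1. The
#' percentile is taken over positive entries only: the non-negative LASSO
#' leaves most cells exactly zero, and including them would make a low
#' percentile identically zero and the threshold vacuous.
#'
#' @param A a `coef_matrix` or non-negative numeric matrix.
#' @param percentile percentile in `[0, 100]` of the positive entries
#'   (default 5).
#' @return binary matrix of the same shape (all-zero if `A` has no positive
#'   entry).
#' @export
threshold_binarize <- function(A, percentile = 5) {
  if (inherits(A, "coef_matrix")) A <- A$entries
  A <- as.matrix(A)
  if (percentile < 0 || percentile > 100) stop("percentile must be in [0, 100]")
  pos <- A[A > 0]
  out <- matrix(0, nrow(A), ncol(A), dimnames = dimnames(A))
  if (length(pos) == 0L) return(out)
  t <- unname(quantile(pos, percentile / 100, type = 7))  # linear interpolation
  out[A >= t & A > 0] <- 1
  out
}

#' Enforce minimum hyperedge cardinality on a membership matrix
#'
#' Operates on the full `N x N` per-subject membership layout (column `r` =
#' hyperedge centred at region `r`). The centroid's own cell is forced to 1
#' for every column that has at least one other member, then any column whose
#' total membership (centroid included) falls below `min_regions` is zeroed
#' entirely.
#'
#' @param Hs binary `N x N` membership matrix.
#' @param min_regions minimum regions per hyperedge, centroid included
#'   (default 3).
#' @return filtered binary `N x N` matrix.
#' @export
filter_min_cardinality <- function(Hs, min_regions = 3L) {
  Hs <- as.matrix(Hs)
  if (min_regions < 1L) stop("min_regions must be >= 1")
  if (nrow(Hs) != ncol(Hs)) stop("per-subject membership must be N x N")
  N <- nrow(Hs)
  off <- colSums(Hs) - diag(Hs)
  diag(Hs) <- as.numeric(off > 0)        # centroid joins its own hyperedge
  drop <- colSums(Hs) < min_regions
  Hs[, drop] <- 0
  Hs
}

#' Majority-vote consensus over per-subject structures
#'
#' Each cell of the consensus is 1 iff the fraction of subjects with a 1
#' there is at least `quorum` (a tie at exactly 50% counts as a vote in
#' favour). The minimum-cardinality filter is re-applied to the voted matrix
#' — voting can shrink memberships below the minimum — and all-zero columns
#' are dropped, yielding the shared backbone.
#'
#' @param Hs_list list of binary `N x N` per-subject membership matrices.
#' @param quorum required fraction of subjects in `(0, 1]` (default 0.5).
#' @param min_regions minimum hyperedge cardinality (default 3).
#' @param region_labels optional region labels for the result.
#' @return an [incidence_matrix()] with `M <= N` surviving hyperedges.
#' @export
majority_vote <- function(Hs_list, quorum = 0.5, min_regions = 3L,
                          region_labels = NULL) {
  if (length(Hs_list) == 0L) stop("empty list of per-subject structures")
  if (quorum <= 0 || quorum > 1) stop("quorum must be in (0, 1]")
  dims <- dim(as.matrix(Hs_list[[1L]]))
  votes <- Reduce(`+`, lapply(Hs_list, function(m) {
    m <- as.matrix(m)
    if (!all(dim(m) == dims)) stop("all membership matrices must share a shape")
    m
  }))
  voted <- (votes / length(Hs_list) >= quorum) * 1
  voted <- filter_min_cardinality(voted, min_regions)
  keep <- which(colSums(voted) > 0)
  if (is.null(region_labels)) region_labels <- rownames(as.matrix(Hs_list[[1L]]))
  incidence_matrix(voted[, keep, drop = FALSE], region_labels,
                   centroids = keep, min_regions = min_regions)
}
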