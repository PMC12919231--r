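#' Fit the shared hypergraph backbone from a reference cohort
#'
#' The central fitting function. For each subject, every region is regressed
#' on all the others with a non-negative LASSO ([fit_nonneg_lasso()]); the
#' resulting coefficient matrix is thresholded at the given percentile of its
#' positive entries, binarized, and filtered to hyperedges with at least
#' `min_regions` regions (centroid included). Majority voting across subjects
#' at quorum `quorum`, followed by re-filtering and removal of empty columns,
#' yields the shared backbone: one hyperedge per surviving centroid region.
#'
#' @param panels list of z-scored [ts_panel()] objects (the reference
#'   cohort), all with the same region set in the same order.
#' @param lambda sparsity penalty; either a fixed value or `"cv"` to select
#'   it with [select_lambda_cv()] on these panels.
#' @param percentile coefficient-threshold percentile (default 5).
#' @param min_regions minimum hyperedge cardinality (default 3).
#' @param quorum majority-vote quorum (default 0.5).
#' @param grid,folds,seed passed to [select_lambda_cv()] when
#'   `lambda = "cv"`.
#' @param tol,max_iter solver controls, see [fit_nonneg_lasso()].
#' @param keep_coefficients keep the per-subject coefficient matrices in the
#'   fit (memory proportional to `S * N^2`; default `FALSE`).
#' @return an object of class `hyperfc_fit`: list with `incidence` (an
#'   [incidence_matrix()]), `lambda`, `lambda_selection` (when CV was run),
#'   `percentile`, `min_regions`, `quorum`, `subject_ids`, `region_labels`,
#'   `subject_structures` (list of per-subject filtered `N x N` membership
#'   matrices), optionally `coefficients`, and `call`.
#' @examples
#' sim <- simulate_panels(simulation_config(
#'   n_regions = 12, n_timepoints = 120, n_subjects_per_group = c(ref = 6),
#'   planted_hyperedges = list(1:4, 5:8), seed = 7))
#' fit <- fit_hypergraph(sim$panels, lambda = 0.05)
#' fit
#' @seealso [hyperedge_weights()], [truncation_stability()]
#' @export
fit_hypergraph <- function(panels, lambda = 0.05, percentile = 5,
                           min_regions = 3L, quorum = 0.5,
                           grid = seq(0.01, 0.30, by = 0.01), folds = 5L,
                           seed = 1L, tol = 1e-10, max_iter = 100000L,
                           keep_coefficients = FALSE) {
  if (inherits(panels, "ts_panel")) panels <- list(panels)
  if (length(panels) == 0L) stop("no panels supplied")
  labels <- panels[[1L]]$region_labels
  for (p in panels) {
    assert_zscored(p)
    if (!identical(p$region_labels, labels))
      stop("all panels must share the same region set and order")
  }
  sel <- NULL
  if (identical(lambda, "cv")) {
    sel <- select_lambda_cv(panels, grid = grid, folds = folds, seed = seed,
                            max_iter = max_iter)
    lambda <- sel$chosen
  }
  coefs <- vector("list", length(panels))
  structs <- vector("list", length(panels))
  for (i in seq_along(panels)) {
    A <- coefficient_matrix(panels[[i]], lambda, tol, max_iter)
    if (keep_coefficients) coefs[[i]] <- A
    # row n of A predicts centroid n, so the membership column of the
    # hyperedge centred at n is the binarized row n
    Hs <- t(threshold_binarize(A, percentile))
    structs[[i]] <- filter_min_cardinality(Hs, min_regions)
  }
  names(structs) <- vapply(panels, `[[`, "", "subject_id")
  H <- majority_vote(structs, quorum = quorum, min_regions = min_regions,
                     region_labels = labels)
  structure(list(incidence = H, lambda = lambda, lambda_selection = sel,
                 percentile = percentile, min_regions = as.integer(min_regions),
                 quorum = quorum, subject_ids = names(structs),
                 region_labels = labels, subject_structures = structs,
                 coefficients = if (keep_coefficients) coefs else NULL,
                 call = match.call()),
            class = "hyperfc_fit")
}

#' @export
print.hyperfc_fit <- function(x, ...) {
  M <- ncol(x$incidence$entries)
  cat(sprintf("Hypergraph backbone: %d hyperedges over %d regions (%d subjects)\n",
              M, length(x$region_labels), length(x$subject_ids)))
  cat(sprintf("  lambda = %.4g%s, threshold percentile = %g, min regions = %d, quorum = %g\n",
              x$lambda, if (!is.null(x$lambda_selection)) " (CV-selected)" else "",
              x$percentile, x$min_regions, x$quorum))
  if (M > 0L) {
    deg <- hyperedge_degrees(x$incidence)
    cat(sprintf("  cardinality: min %d, max %d, mean %.2f\n",
                min(deg), max(deg), mean(deg)))
  }
  invisible(x)
}

#' @export
summary.hyperfc_fit <- function(object, ...) {
  deg <- if (ncol(object$incidence$entries)) hyperedge_degrees(object$incidence) else integer()
  per_subj <- vapply(object$subject_structures, function(m) sum(colSums(m) > 0), 0)
  out <- list(n_regions = length(object$region_labels),
              n_hyperedges = length(deg),
              degree_table = if (length(deg)) table(deg) else table(integer()),
              mean_degree = if (length(deg)) mean(deg) else NA_real_,
              lambda = object$lambda,
              per_subject_hyperedges = summary(per_subj))
  class(out) <- "summary.hyperfc_fit"
  out
}

#' @export
print.summary.hyperfc_fit <- function(x, ...) {
  cat(sprintf("Backbone of %d hyperedges over %d regions; mean cardinality %.2f\n",
              x$n_hyperedges, x$n_regions, x$mean_degree))
  cat("Cardinality distribution:\n"); print(x$degree_table)
  cat("Per-subject hyperedge counts before voting:\n"); print(x$per_subject_hyperedges)
  invisible(x)
}

#' @export
plot.hyperfc_fit <- function(x, ...) {
  E <- x$incidence$entries
  if (ncol(E) == 0L) stop("empty backbone; nothing to plot")
  image(seq_len(ncol(E)), seq_len(nrow(E)), t(E), col = c("white", "grey20"),
        xlab = "hyperedge (by centroid)", ylab = "region",
        main = "Hypergraph incidence matrix", ...)
  invisible(x)
}

#' @export
coef.hyperfc_fit <- function(object, ...) {
  if (is.null(object$coefficients))
    stop("refit with keep_coefficients = TRUE to retain coefficient matrices")
  object$coefficients
}

#' Backbone stability under time-series truncation
#'
#' Rebuilds the backbone from the first `P'` timepoints of every panel
#' (re-z-scored after truncation) for each requested length, holding lambda
#' and all filter settings fixed, and compares each truncated backbone to the
#' full-length one with [structure_stability()].
#'
#' @param panels list of z-scored [ts_panel()] objects.
#' @param lambda fixed sparsity penalty (not re-selected per length).
#' @param lengths integer vector of truncated lengths `P' <= P`.
#' @param ... further arguments passed to [fit_hypergraph()].
#' @return a `data.frame` with one row per length: `n_timepoints`, `jaccard`,
#'   `pearson`, `n_hyperedges`; the full-length backbone is attached as
#'   attribute `"reference"`.
#' @export
truncation_stability <- function(panels, lambda, lengths, ...) {
  if (inherits(panels, "ts_panel")) panels <- list(panels)
  P <- ncol(panels[[1L]]$data)
  if (any(lengths > P)) stop("truncation lengths must be <= panel length")
  full <- fit_hypergraph(panels, lambda = lambda, ...)
  rows <- lapply(lengths, function(Pp) {
    sub <- lapply(panels, truncate_panel, n_timepoints = Pp)
    fit <- fit_hypergraph(sub, lambda = lambda, ...)
    st <- structure_stability(fit$incidence, full$incidence)
    data.frame(n_timepoints = Pp, jaccard = st$jaccard, pearson = st$pearson,
               n_hyperedges = st$n_hyperedges_a)
  })
  out <- do.call(rbind, rows)
  attr(out, "reference") <- full
  out
}
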