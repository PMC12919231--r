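#' Cliff's delta effect size
#'
#' The nonparametric dominance statistic
#' `delta = (#\{x_i > y_j\} - #\{x_i < y_j\}) / (n_x * n_y)`, in `[-1, 1]`;
#' 1 means every `x` exceeds every `y`, 0 means stochastic equality.
#'
#' @param x,y non-empty numeric vectors.
#' @return scalar in `[-1, 1]`.
#' @export
cliffs_delta <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) stop("cliffs_delta needs non-empty inputs")
  d <- sign(outer(x, y, `-`))
  mean(d)
}

#' Global effect size over three groups
#'
#' The mean absolute Cliff's delta over the three unordered group pairs, a
#' single `[0, 1]` summary of how separated the groups are.
#'
#' @param groups list of (at least two) numeric vectors.
#' @return scalar in `[0, 1]`.
#' @export
global_effect_size <- function(groups) {
  g <- length(groups)
  if (g < 2L) stop("need at least two groups")
  pairs <- utils::combn(g, 2L)
  mean(apply(pairs, 2L, function(ij)
    abs(cliffs_delta(groups[[ij[1L]]], groups[[ij[2L]]]))))
}

#' Kruskal-Wallis omnibus test
#'
#' Thin wrapper around [stats::kruskal.test()] (rank-based H with tie
#' correction, chi-square reference with `g - 1` degrees of freedom) adding
#' the degenerate rule: if every pooled observation is identical the test is
#' uninformative and `H = 0`, `p = 1` is returned.
#'
#' @param groups list of non-empty numeric vectors.
#' @return list with `statistic` (H) and `p.value`.
#' @export
kruskal_wallis <- function(groups) {
  if (any(lengths(groups) == 0L)) stop("empty group")
  if (length(groups) < 2L) stop("need at least two groups")
  pooled <- unlist(groups, use.names = FALSE)
  if (length(unique(pooled)) == 1L)
    return(list(statistic = 0, p.value = 1))
  g <- factor(rep(seq_along(groups), lengths(groups)))
  kt <- kruskal.test(pooled, g)
  list(statistic = unname(kt$statistic), p.value = kt$p.value)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted p-values via [stats::p.adjust()] with rejection flags at
#' level `alpha`.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @param alpha FDR level (default 0.05).
#' @return list with `p_adjusted` and logical `reject`.
#' @export
fdr_bh <- function(p, alpha = 0.05) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  adj <- p.adjust(p, method = "BH")
  list(p_adjusted = adj, reject = !is.na(adj) & adj < alpha)
}

#' Shapiro-Wilk normality screen of a weight table
#'
#' Tests each hyperedge-by-group cell for normality. The screen is
#' informational: the analysis battery is nonparametric regardless, but the
#' flag records whether any cell rejects normality at 0.05.
#'
#' @param wt a `weight_table` with group labels.
#' @return list with `p_values` (hyperedges x groups matrix) and logical
#'   `non_normal` (any cell p < 0.05). Groups need at least 3 subjects.
#' @export
normality_screen <- function(wt) {
  stopifnot(inherits(wt, "weight_table"))
  groups <- split(seq_along(wt$group_labels), wt$group_labels)
  if (any(lengths(groups) < 3L)) stop("every group needs >= 3 subjects")
  P <- sapply(groups, function(idx)
    apply(wt$values[idx, , drop = FALSE], 2L, function(v) {
      if (length(unique(v)) == 1L) return(0)  # degenerate: certainly non-Gaussian
      shapiro.test(v)$p.value
    }))
  P <- matrix(P, ncol = length(groups),
              dimnames = list(wt$hyperedge_ids, names(groups)))
  list(p_values = P, non_normal = any(P < 0.05))
}

#' Nonparametric group comparison of hyperedge weights
#'
#' The full statistical battery applied to a subjects-by-hyperedges weight
#' table: a Kruskal-Wallis omnibus test per hyperedge across groups,
#' Benjamini-Hochberg FDR correction across hyperedges, a global effect size
#' (mean absolute pairwise Cliff's delta), and, for the FDR-significant
#' hyperedges only, two-sided Mann-Whitney post-hoc tests per group pair with
#' FDR applied within each pair's family.
#'
#' @param wt a `weight_table` with group labels.
#' @param alpha FDR level (default 0.05).
#' @return an object of class `hyperfc_stats`: list with `omnibus` (a
#'   data.frame: `hyperedge_id`, `H`, `p_raw`, `p_fdr`, `significant`,
#'   `effect_size`), `pairwise` (a data.frame: `hyperedge_id`, `pair`, `U`,
#'   `p_raw`, `p_fdr`, `cliffs_delta`), `alpha`, `groups`, `method`.
#' @export
group_stats <- function(wt, alpha = 0.05) {
  stopifnot(inherits(wt, "weight_table"))
  if (all(is.na(wt$group_labels))) stop("weight table has no group labels")
  idx <- split(seq_along(wt$group_labels), wt$group_labels)
  gnames <- names(idx)
  M <- ncol(wt$values)
  kw <- lapply(seq_len(M), function(m) {
    g <- lapply(idx, function(i) wt$values[i, m])
    c(kruskal_wallis(g), effect = global_effect_size(g))
  })
  p_raw <- vapply(kw, `[[`, 0, "p.value")
  adj <- fdr_bh(p_raw, alpha)
  omnibus <- data.frame(hyperedge_id = wt$hyperedge_ids,
                        H = vapply(kw, `[[`, 0, "statistic"),
                        p_raw = p_raw, p_fdr = adj$p_adjusted,
                        significant = adj$reject,
                        effect_size = vapply(kw, `[[`, 0, "effect"),
                        row.names = NULL)
  sig <- which(adj$reject)
  pairwise <- posthoc_pairwise(wt, wt$hyperedge_ids[sig], alpha)
  structure(list(omnibus = omnibus, pairwise = pairwise, alpha = alpha,
                 groups = gnames, method = wt$method),
            class = "hyperfc_stats")
}

#' Pairwise Mann-Whitney post-hoc tests
#'
#' Two-sided Mann-Whitney U tests between every pair of groups, restricted
#' to the given (omnibus-significant) hyperedges, with BH-FDR applied within
#' each group pair's family across those hyperedges, plus the signed Cliff's
#' delta per comparison.
#'
#' @param wt a `weight_table` with group labels.
#' @param significant_ids hyperedge ids to test (typically the
#'   FDR-significant ones from the omnibus stage).
#' @param alpha FDR level.
#' @return a data.frame (empty when `significant_ids` is empty).
#' @export
posthoc_pairwise <- function(wt, significant_ids, alpha = 0.05) {
  empty <- data.frame(hyperedge_id = character(), pair = character(),
                      U = numeric(), p_raw = numeric(), p_fdr = numeric(),
                      cliffs_delta = numeric())
  if (length(significant_ids) == 0L) return(empty)
  idx <- split(seq_along(wt$group_labels), wt$group_labels)
  gnames <- names(idx)
  cols <- match(significant_ids, wt$hyperedge_ids)
  if (anyNA(cols)) stop("unknown hyperedge id(s)")
  pairs <- utils::combn(length(gnames), 2L)
  out <- list()
  for (pi in seq_len(ncol(pairs))) {
    i <- pairs[1L, pi]; j <- pairs[2L, pi]
    res <- t(vapply(cols, function(m) {
      x <- wt$values[idx[[i]], m]; y <- wt$values[idx[[j]], m]
      wt_ <- suppressWarnings(wilcox.test(x, y, alternative = "two.sided"))
      c(U = unname(wt_$statistic), p = wt_$p.value, d = cliffs_delta(x, y))
    }, c(U = 0, p = 0, d = 0)))
    adj <- fdr_bh(res[, "p"], alpha)
    out[[pi]] <- data.frame(hyperedge_id = significant_ids,
                            pair = paste(gnames[i], gnames[j], sep = " vs "),
                            U = res[, "U"], p_raw = res[, "p"],
                            p_fdr = adj$p_adjusted, cliffs_delta = res[, "d"],
                            row.names = NULL)
  }
  do.call(rbind, out)
}

#' @export
print.hyperfc_stats <- function(x, ...) {
  nsig <- sum(x$omnibus$significant)
  cat(sprintf("Group comparison ('%s' weights): %d hyperedges, groups %s\n",
              x$method, nrow(x$omnibus), paste(x$groups, collapse = "/")))
  cat(sprintf("  %d FDR-significant at alpha = %g\n", nsig, x$alpha))
  if (nsig > 0L) {
    sig <- x$omnibus[x$omnibus$significant, ]
    sig <- sig[order(sig$p_fdr), ]
    print(head(sig[, c("hyperedge_id", "H", "p_fdr", "effect_size")], 10L),
          row.names = FALSE)
  }
  invisible(x)
}

#' @export
summary.hyperfc_stats <- function(object, ...) {
  cat(sprintf("Omnibus: %d/%d significant (alpha %g, BH-FDR)\n",
              sum(object$omnibus$significant), nrow(object$omnibus), object$alpha))
  if (nrow(object$pairwise)) {
    cat("Post-hoc rejections per pair family:\n")
    print(tapply(object$pairwise$p_fdr < object$alpha, object$pairwise$pair, sum))
  }
  invisible(object)
}
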