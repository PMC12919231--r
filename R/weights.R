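#' Functional-connectivity subgraph of one hyperedge
#'
#' Builds the weighted graph a hyperedge induces on its member regions: the
#' adjacency is the absolute Pearson correlation between member time series
#' (diagonal set to 0 — self-correlation is not an edge), and the Laplacian
#' is `L = D - A` with `D` the diagonal of row sums.
#'
#' @param panel a [ts_panel()].
#' @param members region indices of the hyperedge (at least 3).
#' @return an object of class `subgraph_fc`: list with `member_indices`,
#'   `adjacency`, `laplacian`.
#' @export
subgraph_fc <- function(panel, members) {
  stopifnot(inherits(panel, "ts_panel"))
  members <- as.integer(members)
  if (length(members) < 3L) stop("a hyperedge subgraph needs at least 3 members")
  X <- panel$data[members, , drop = FALSE]
  s <- apply(X, 1L, sd)
  if (any(s == 0)) stop("constant member series: correlation undefined")
  A <- abs(cor(t(X)))
  diag(A) <- 0
  L <- diag(rowSums(A)) - A
  structure(list(member_indices = members, adjacency = A, laplacian = L),
            class = "subgraph_fc")
}

#' Algebraic connectivity (Fiedler value) of a subgraph
#'
#' The second-smallest eigenvalue of the graph Laplacian, computed by dense
#' symmetric eigendecomposition (exact at hyperedge sizes; all backbone
#' hyperedges have at most a few dozen members). Eigenvalues with magnitude
#' below `tol` are treated as 0, so a disconnected subgraph (two or more
#' zero eigenvalues) returns 0; small negatives from round-off are clipped.
#'
#' @param g a [subgraph_fc()], or a Laplacian matrix.
#' @param tol zero-detection tolerance (default 1e-10).
#' @return non-negative scalar.
#' @examples
#' L <- 4 * diag(4) - matrix(1, 4, 4)  # complete graph K4, unit weights
#' algebraic_connectivity(L)           # a(K_n) = n
#' @export
algebraic_connectivity <- function(g, tol = 1e-10) {
  L <- if (inherits(g, "subgraph_fc")) g$laplacian else as.matrix(g)
  k <- nrow(L)
  if (k < 2L) stop("algebraic connectivity needs at least 2 nodes")
  ev <- eigen(L, symmetric = TRUE, only.values = TRUE)$values
  ev[abs(ev) < tol] <- 0
  ev[ev < 0] <- 0
  sort(ev)[2L]
}

weight_methods <- c("algebraic", "gaussian", "mean_corr", "lasso_l2")

#' Per-subject hyperedge weights
#'
#' Computes one weight per hyperedge and subject under the chosen scheme:
#' \describe{
#'   \item{`algebraic`}{algebraic connectivity of the hyperedge's induced
#'     absolute-correlation subgraph ([algebraic_connectivity()]); 0 with a
#'     warning for a subgraph disconnected at tolerance.}
#'   \item{`gaussian`}{mean over unordered member pairs of the Gaussian
#'     similarity kernel `exp(-||x_i - x_j||^2 / (2 sigma^2))`, with `sigma`
#'     the median of the pairwise Euclidean distances among the member series
#'     (computed per hyperedge and subject); 1 if all members are identical.}
#'   \item{`mean_corr`}{mean signed Pearson correlation over member pairs.}
#'   \item{`lasso_l2`}{squared L2 norm of the subject's non-negative LASSO
#'     coefficients for the hyperedge's centroid, refit at the backbone's
#'     lambda and restricted to the non-centroid members.}
#' }
#'
#' @param panels list of z-scored [ts_panel()] objects (the analysis cohort),
#'   or a single panel.
#' @param structure a [fit_hypergraph()] fit or an [incidence_matrix()].
#' @param method one of `"algebraic"`, `"gaussian"`, `"mean_corr"`,
#'   `"lasso_l2"`.
#' @param groups optional group label per panel (recycled into the result).
#' @param lambda penalty for the `lasso_l2` refits; defaults to the fit's
#'   lambda when `structure` is a `hyperfc_fit`.
#' @param tol zero/connectivity tolerance for `algebraic`.
#' @return an object of class `weight_table`: list with `values` (subjects x
#'   hyperedges matrix), `method`, `subject_ids`, `group_labels`,
#'   `hyperedge_ids`.
#' @export
hyperedge_weights <- function(panels, structure, method = weight_methods,
                              groups = NULL, lambda = NULL, tol = 1e-10) {
  method <- match.arg(method)
  if (inherits(panels, "ts_panel")) panels <- list(panels)
  H <- if (inherits(structure, "hyperfc_fit")) structure$incidence else structure
  stopifnot(inherits(H, "incidence_matrix"))
  if (method == "lasso_l2" && is.null(lambda)) {
    if (inherits(structure, "hyperfc_fit")) lambda <- structure$lambda
    else stop("lasso_l2 needs lambda (the backbone's penalty)")
  }
  M <- ncol(H$entries)
  members <- lapply(seq_len(M), function(m) which(H$entries[, m] == 1))
  vals <- matrix(NA_real_, length(panels), M,
                 dimnames = list(vapply(panels, `[[`, "", "subject_id"),
                                 colnames(H$entries)))
  for (i in seq_along(panels)) {
    p <- panels[[i]]
    if (!identical(p$region_labels, H$region_labels))
      stop("panel region set does not match the backbone")
    vals[i, ] <- switch(method,
      algebraic = weights_algebraic_one(p, members, H$centroids, tol),
      gaussian  = vapply(members, function(mm) gaussian_weight_one(p, mm), 0),
      mean_corr = vapply(members, function(mm) mean_corr_one(p, mm), 0),
      lasso_l2  = weights_lasso_l2_one(p, members, H$centroids, lambda))
  }
  weight_table(vals, method, groups)
}

weight_table <- function(values, method, groups = NULL) {
  if (is.null(groups)) groups <- rep(NA_character_, nrow(values))
  if (length(groups) != nrow(values)) stop("one group label per subject required")
  structure(list(values = values, method = method,
                 subject_ids = rownames(values),
                 group_labels = as.character(groups),
                 hyperedge_ids = colnames(values)),
            class = "weight_table")
}

weights_algebraic_one <- function(panel, members, centroids, tol) {
  vapply(seq_along(members), function(m) {
    g <- subgraph_fc(panel, members[[m]])
    a <- algebraic_connectivity(g, tol)
    if (a == 0)
      warning(sprintf("hyperedge e%d disconnected for subject %s; weight 0",
                      centroids[m], panel$subject_id), call. = FALSE)
    a
  }, 0)
}

gaussian_weight_one <- function(panel, members) {
  if (length(members) < 2L) stop("gaussian weight needs >= 2 members")
  X <- panel$data[members, , drop = FALSE]
  d <- dist(X)                         # pairwise Euclidean distances
  sigma <- stats::median(d)            # median heuristic, raw distances
  if (sigma == 0) return(1)            # all member series identical
  mean(exp(-(as.vector(d)^2) / (2 * sigma^2)))
}

mean_corr_one <- function(panel, members) {
  if (length(members) < 2L) stop("mean correlation needs >= 2 members")
  X <- panel$data[members, , drop = FALSE]
  s <- apply(X, 1L, sd)
  if (any(s == 0)) stop("constant member series: correlation undefined")
  R <- cor(t(X))
  mean(R[upper.tri(R)])
}

weights_lasso_l2_one <- function(panel, members, centroids, lambda) {
  vapply(seq_along(members), function(m) {
    a <- fit_nonneg_lasso(panel, centroids[m], lambda)
    rest <- setdiff(members[[m]], centroids[m])
    sum(a[rest]^2)
  }, 0)
}

#' Squared L2 weight from an existing coefficient matrix
#'
#' Variant of the `lasso_l2` scheme that reuses a precomputed
#' [coefficient_matrix()] instead of refitting: the weight of hyperedge `m`
#' is the squared L2 norm of the centroid's coefficient row restricted to the
#' hyperedge's non-centroid members.
#'
#' @param A a `coef_matrix` for one subject.
#' @param H an [incidence_matrix()].
#' @return numeric vector of length `M`.
#' @export
weight_lasso_l2 <- function(A, H) {
  stopifnot(inherits(H, "incidence_matrix"))
  if (inherits(A, "coef_matrix")) A <- A$entries
  M <- ncol(H$entries)
  vapply(seq_len(M), function(m) {
    cm <- H$centroids[m]
    rest <- setdiff(which(H$entries[, m] == 1), cm)
    sum(A[cm, rest]^2)
  }, 0)
}

#' Parse functional-network assignments from Schaefer-style region labels
#'
#' Labels like `"LH Vis 1"`, `"RH SomMot 3"` or `"7Networks_LH_Default_10"`
#' are split into hemisphere, network and index; the network token is
#' validated against the seven canonical large-scale systems (Vis, SomMot,
#' DorsAttn, SalVentAttn, Limbic, Cont, Default).
#'
#' @param labels character vector of region labels.
#' @return factor of network names, one per region.
#' @export
parse_fn_labels <- function(labels) {
  canonical <- c("Vis", "SomMot", "DorsAttn", "SalVentAttn", "Limbic",
                 "Cont", "Default")
  toks <- strsplit(sub("^7Networks[_ ]", "", labels), "[ _]+")
  net <- vapply(toks, function(t) if (length(t) >= 2L) t[2L] else NA_character_, "")
  bad <- is.na(net) | !(net %in% canonical)
  if (any(bad))
    stop("cannot parse functional network from label(s): ",
         paste(utils::head(labels[bad], 5L), collapse = ", "))
  factor(net, levels = canonical)
}

#' Mean within-network correlation weights
#'
#' Treats each functional network of the atlas as one hyperedge and computes,
#' per subject and network, the mean signed Pearson correlation over
#' unordered within-network region pairs.
#'
#' @param panels list of z-scored [ts_panel()] objects (or one panel).
#' @param groups optional group label per panel.
#' @return a `weight_table` with method `"fn_mean_corr"`, one column per
#'   network present in the labels; a network with fewer than 2 regions is an
#'   error.
#' @export
fn_weights <- function(panels, groups = NULL) {
  if (inherits(panels, "ts_panel")) panels <- list(panels)
  nets <- parse_fn_labels(panels[[1L]]$region_labels)
  counts <- table(nets)
  present <- names(counts)[counts > 0]
  small <- names(counts)[counts > 0 & counts < 2]
  if (length(small))
    stop("functional network(s) with < 2 regions: ", paste(small, collapse = ", "))
  vals <- matrix(NA_real_, length(panels), length(present),
                 dimnames = list(vapply(panels, `[[`, "", "subject_id"), present))
  for (i in seq_along(panels)) {
    p <- panels[[i]]
    if (!identical(p$region_labels, panels[[1L]]$region_labels))
      stop("panels must share the same region labels")
    for (nw in present)
      vals[i, nw] <- mean_corr_one(p, which(nets == nw))
  }
  weight_table(vals, "fn_mean_corr", groups)
}

#' @export
print.weight_table <- function(x, ...) {
  cat(sprintf("<weight_table> method '%s': %d subjects x %d hyperedges\n",
              x$method, nrow(x$values), ncol(x$values)))
  if (!all(is.na(x$group_labels)))
    cat("  groups:", paste(sprintf("%s (n=%d)", names(table(x$group_labels)),
                                   table(x$group_labels)), collapse = ", "), "\n")
  cat(sprintf("  weight range [%.4g, %.4g]\n", min(x$values), max(x$values)))
  invisible(x)
}

#' @export
plot.weight_table <- function(x, hyperedge = 1L, ...) {
  v <- x$values[, hyperedge]
  if (all(is.na(x$group_labels))) boxplot(v, ylab = "weight", ...)
  else boxplot(v ~ x$group_labels, xlab = "group", ylab = "weight",
               main = paste0(colnames(x$values)[hyperedge], " (", x$method, ")"), ...)
  invisible(x)
}

#' Write / read a weight table as delimited text
#'
#' Rows are subjects; the first two columns are `subject_id` and `group`,
#' followed by one column per hyperedge. The method name is stored on the
#' first header comment line.
#'
#' @param wt a `weight_table`.
#' @param path TSV file path.
#' @return `path` (write) or a `weight_table` (read).
#' @export
write_weight_table <- function(wt, path) {
  stopifnot(inherits(wt, "weight_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# method=", wt$method), con)
  df <- data.frame(subject_id = wt$subject_ids, group = wt$group_labels,
                   wt$values, check.names = FALSE)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_weight_table
#' @export
read_weight_table <- function(path) {
  first <- readLines(path, n = 1L)
  method <- sub("^# method=", "", first)
  df <- read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                   check.names = FALSE)
  vals <- as.matrix(df[, -(1:2), drop = FALSE])
  rownames(vals) <- df$subject_id
  weight_table(vals, method, df$group)
}
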