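#' Construct a hypergraph incidence matrix
#'
#' The incidence matrix `H` is the binary `N x M` node-by-hyperedge membership
#' matrix of a hypergraph: `H[n, m] = 1` iff region `n` belongs to hyperedge
#' `m`. Here every hyperedge is identified by a centroid region (the region
#' whose time series the other members jointly predict), belongs to its own
#' hyperedge, and has at least `min_regions` members; hyperedges are ordered
#' by centroid index so the structure is reproducible across runs.
#'
#' @param entries binary `N x M` matrix (0/1).
#' @param region_labels character vector of length `N`.
#' @param centroids integer vector of length `M`: the centroid region index of
#'   each hyperedge (column). Must be unique and each centroid must be a
#'   member of its own hyperedge.
#' @param min_regions minimum hyperedge cardinality enforced by the validator
#'   (default 3).
#' @return an object of class `incidence_matrix`.
#' @examples
#' H <- incidence_matrix(cbind(c(1, 1, 1, 0)), paste0("R", 1:4), centroids = 1L)
#' hyperedge_degrees(H)
#' @export
incidence_matrix <- function(entries, region_labels = rownames(entries),
                             centroids, min_regions = 3L) {
  entries <- as.matrix(entries)
  storage.mode(entries) <- "double"
  if (!all(entries %in% c(0, 1))) stop("incidence entries must be exactly 0 or 1")
  N <- nrow(entries); M <- ncol(entries)
  if (is.null(region_labels)) region_labels <- paste0("region_", seq_len(N))
  centroids <- as.integer(centroids)
  if (length(centroids) != M) stop("one centroid index per hyperedge required")
  if (anyDuplicated(centroids)) stop("centroid indices must be unique")
  if (M > N) stop("more hyperedges than regions (M must be <= N)")
  if (M > 0L) {
    if (any(centroids < 1L | centroids > N)) stop("centroid index out of range")
    if (any(entries[cbind(centroids, seq_len(M))] != 1))
      stop("every centroid must belong to its own hyperedge")
    deg <- colSums(entries)
    if (any(deg < min_regions))
      stop("hyperedge cardinality below ", min_regions, " (invalid hypergraph)")
    ord <- order(centroids)
    entries <- entries[, ord, drop = FALSE]
    centroids <- centroids[ord]
  }
  dimnames(entries) <- list(region_labels, if (M) paste0("e", centroids) else NULL)
  structure(list(entries = entries, region_labels = as.character(region_labels),
                 centroids = centroids),
            class = "incidence_matrix")
}

#' @export
print.incidence_matrix <- function(x, ...) {
  deg <- hyperedge_degrees(x)
  cat("<incidence_matrix>", length(x$region_labels), "regions,",
      ncol(x$entries), "hyperedges")
  if (length(deg))
    cat(sprintf("; cardinality %d-%d (mean %.2f)", min(deg), max(deg), mean(deg)))
  cat("\n")
  invisible(x)
}

as_incidence_entries <- function(H) {
  if (inherits(H, "incidence_matrix")) H$entries else as.matrix(H)
}

#' Hyperedge degrees
#'
#' The degree of hyperedge `m` is its cardinality: the number of regions it
#' contains (the number of ones in column `m` of `H`).
#'
#' @param H an [incidence_matrix()] or binary matrix.
#' @return integer vector of length `M`; an empty column is an error.
#' @export
hyperedge_degrees <- function(H) {
  E <- as_incidence_entries(H)
  deg <- as.integer(colSums(E))
  if (any(deg == 0L)) stop("invalid hypergraph: hyperedge with degree 0")
  names(deg) <- colnames(E)
  deg
}

#' Weighted node degrees
#'
#' The degree of node `n` is the sum of the weights of the hyperedges it
#' belongs to: `d(v_n) = sum_m w[m] * H[n, m]`.
#'
#' @param H an [incidence_matrix()] or binary matrix.
#' @param w numeric hyperedge weight vector of length `M`.
#' @return numeric vector of length `N`.
#' @export
node_degrees <- function(H, w) {
  E <- as_incidence_entries(H)
  if (length(w) != ncol(E)) stop("length(w) must equal the number of hyperedges")
  d <- drop(E %*% w)
  names(d) <- rownames(E)
  d
}

#' Hypergraph similarity matrix
#'
#' Computes `S = H W De^-1 H^T`, the node-by-node similarity induced by the
#' weighted hypergraph, where `W = diag(w)` and `De` is the diagonal matrix of
#' hyperedge degrees. `S[i, j]` accumulates, over the hyperedges containing
#' both `i` and `j`, the hyperedge weight divided by its cardinality. `S` is
#' symmetric and linear in `w`.
#'
#' @inheritParams node_degrees
#' @return symmetric `N x N` numeric matrix.
#' @export
similarity_matrix <- function(H, w) {
  E <- as_incidence_entries(H)
  if (length(w) != ncol(E)) stop("length(w) must equal the number of hyperedges")
  deg <- hyperedge_degrees(E)  # errors on degree-0 columns
  Ew <- sweep(E, 2L, w / deg, `*`)
  S <- Ew %*% t(E)
  S <- (S + t(S)) / 2  # exact symmetry against round-off
  dimnames(S) <- list(rownames(E), rownames(E))
  S
}

#' Assemble a weighted hypergraph model
#'
#' Bundles an incidence matrix with one subject's hyperedge weights and the
#' derived quantities: node degrees, hyperedge degrees and the similarity
#' matrix.
#'
#' @param H an [incidence_matrix()].
#' @param w numeric hyperedge weight vector.
#' @return an object of class `hypergraph_model` with elements `incidence`,
#'   `weights`, `node_degrees`, `hyperedge_degrees`, `similarity`.
#' @export
hypergraph_model <- function(H, w) {
  stopifnot(inherits(H, "incidence_matrix"))
  structure(list(incidence = H, weights = w,
                 node_degrees = node_degrees(H, w),
                 hyperedge_degrees = hyperedge_degrees(H),
                 similarity = similarity_matrix(H, w)),
            class = "hypergraph_model")
}

#' @export
print.hypergraph_model <- function(x, ...) {
  print(x$incidence)
  cat(sprintf("weights: [%.4g, %.4g]; mean node degree %.4g\n",
              min(x$weights), max(x$weights), mean(x$node_degrees)))
  invisible(x)
}

expand_membership <- function(H) {
  # full N x N layout: column r = hyperedge centred at region r (zero if absent)
  E <- as_incidence_entries(H)
  N <- nrow(E)
  full <- matrix(0, N, N)
  if (inherits(H, "incidence_matrix")) {
    if (length(H$centroids)) full[, H$centroids] <- E
  } else {
    if (ncol(E) != N) stop("plain membership matrices must be N x N")
    full <- E
  }
  full
}

#' Compare two hypergraph structures
#'
#' Expands both structures to the full N x N membership layout (columns
#' indexed by centroid region; absent hyperedges are zero columns) and
#' compares them cell-wise with the Jaccard index of their 1-cells and the
#' Pearson correlation of the flattened 0/1 vectors.
#'
#' @param Ha,Hb [incidence_matrix()] objects (or N x N binary matrices) over
#'   the same region set.
#' @return an object of class `stability_report`: list with `jaccard`,
#'   `pearson`, `n_hyperedges_a`, `n_hyperedges_b`.
#' @export
structure_stability <- function(Ha, Hb) {
  A <- expand_membership(Ha); B <- expand_membership(Hb)
  if (!all(dim(A) == dim(B))) stop("structures must share the same region set")
  a <- as.vector(A); b <- as.vector(B)
  uni <- sum(a == 1 | b == 1)
  if (uni == 0L) stop("both structures are empty; Jaccard undefined")
  jac <- sum(a == 1 & b == 1) / uni
  pea <- suppressWarnings(cor(a, b))
  structure(list(jaccard = jac, pearson = pea,
                 n_hyperedges_a = sum(colSums(A) > 0),
                 n_hyperedges_b = sum(colSums(B) > 0)),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("<stability_report> Jaccard %.3f, Pearson %.3f (%d vs %d hyperedges)\n",
              x$jaccard, x$pearson, x$n_hyperedges_a, x$n_hyperedges_b))
  invisible(x)
}

#' Serialize an incidence matrix to delimited text plus a JSON sidecar
#'
#' Writes the binary membership table (one row per region, one column per
#' hyperedge centroid) as TSV and a `<path>.json` sidecar holding the
#' centroid list and, when available, inference provenance (lambda,
#' percentile, quorum, subject count).
#'
#' @param H an [incidence_matrix()].
#' @param path output TSV path.
#' @param provenance optional named list stored in the sidecar.
#' @return `path`, invisibly.
#' @export
write_incidence <- function(H, path, provenance = NULL) {
  stopifnot(inherits(H, "incidence_matrix"))
  df <- data.frame(region = H$region_labels, H$entries, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  side <- list(centroids = H$centroids, region_labels = H$region_labels,
               provenance = provenance)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an incidence matrix written by [write_incidence()]
#'
#' @param path TSV path (the `.json` sidecar must sit next to it).
#' @return an [incidence_matrix()]; the sidecar's provenance, if any, is
#'   attached as attribute `"provenance"`.
#' @export
read_incidence <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  E <- as.matrix(df[, -1L, drop = FALSE])
  H <- incidence_matrix(E, as.character(df[[1L]]), as.integer(side$centroids))
  attr(H, "provenance") <- side$provenance
  H
}
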