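#' Construct a regional time-series panel
#'
#' A panel holds one subject's parcellated time series as an `N x P` matrix
#' (rows = brain regions, columns = timepoints) together with ordered region
#' labels. All structure-inference and weighting functions expect z-scored
#' panels (each regional series standardized to mean 0, sample sd 1).
#'
#' @param data numeric `N x P` matrix, rows = regions, columns = timepoints.
#' @param region_labels character vector of length `N`; defaults to rownames.
#' @param subject_id subject identifier string.
#' @param zscore if `TRUE` (default), z-score each row using the sample
#'   standard deviation (denominator `P - 1`). Constant rows are an error,
#'   as Pearson correlation is undefined for them downstream.
#' @return An object of class `ts_panel`: a list with elements `subject_id`,
#'   `data`, `region_labels`, `zscored`.
#' @examples
#' p <- ts_panel(matrix(rnorm(40), 4, 10), paste0("R", 1:4), "s1")
#' range(rowMeans(p$data))
#' @export
ts_panel <- function(data, region_labels = rownames(data), subject_id = "s1",
                     zscore = TRUE) {
  data <- as.matrix(data)
  if (is.null(region_labels)) region_labels <- paste0("region_", seq_len(nrow(data)))
  if (nrow(data) < 3L) stop("a panel needs at least 3 regions")
  if (ncol(data) < 2L) stop("a panel needs at least 2 timepoints")
  if (anyNA(data)) stop("panel contains missing values")
  if (length(region_labels) != nrow(data)) stop("region_labels length must match nrow(data)")
  if (anyDuplicated(region_labels)) stop("duplicate region labels: ",
    paste(unique(region_labels[duplicated(region_labels)]), collapse = ", "))
  if (zscore) data <- zscore_rows(data, region_labels)
  dimnames(data) <- list(region_labels, NULL)
  structure(list(subject_id = as.character(subject_id), data = data,
                 region_labels = as.character(region_labels), zscored = zscore),
            class = "ts_panel")
}

zscore_rows <- function(data, labels = rownames(data)) {
  s <- apply(data, 1L, sd)  # sample sd, denominator P - 1
  if (any(s == 0)) stop("constant time series cannot be z-scored (region ",
                        paste(labels[s == 0], collapse = ", "), ")")
  (data - rowMeans(data)) / s
}

assert_zscored <- function(panel) {
  stopifnot(inherits(panel, "ts_panel"))
  if (!isTRUE(panel$zscored)) stop("panel must be z-scored (zscore = TRUE)")
  invisible(panel)
}

#' @export
print.ts_panel <- function(x, ...) {
  cat("<ts_panel> subject", x$subject_id, "-", nrow(x$data), "regions x",
      ncol(x$data), "timepoints", if (x$zscored) "(z-scored)" else "", "\n")
  invisible(x)
}

#' Read a panel from delimited text
#'
#' Expects tab-separated text with the region label in the first column and
#' one numeric column per timepoint. Parse failures name the offending cell.
#'
#' @param path file path.
#' @param subject_id subject identifier; defaults to the file name sans extension.
#' @param zscore z-score rows on load (default `TRUE`).
#' @param sep field separator (default tab).
#' @return a [ts_panel()].
#' @seealso [write_panel()]
#' @export
read_panel <- function(path, subject_id = sub("\\.[^.]*$", "", basename(path)),
                       zscore = TRUE, sep = "\t") {
  df <- read.delim(path, header = TRUE, sep = sep, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop("panel file needs a label column plus >= 2 timepoints: ", path)
  labels <- as.character(df[[1L]])
  num <- as.matrix(df[, -1L, drop = FALSE])
  suppressWarnings(storage.mode(num) <- "double")  # coercion NAs reported below
  if (anyNA(num)) {
    idx <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stop(sprintf("missing or non-numeric value in %s at row '%s', timepoint column %d",
                 path, labels[idx[1L]], idx[2L]))
  }
  ts_panel(num, labels, subject_id, zscore = zscore)
}

#' Write a panel to delimited text
#'
#' @param panel a [ts_panel()].
#' @param path output file path.
#' @param sep field separator (default tab).
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path, sep = "\t") {
  stopifnot(inherits(panel, "ts_panel"))
  df <- data.frame(region = panel$region_labels, panel$data, check.names = FALSE)
  colnames(df) <- c("region", paste0("t", seq_len(ncol(panel$data))))
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Truncate a panel to its first timepoints and re-z-score
#'
#' @param panel a z-scored [ts_panel()].
#' @param n_timepoints number of leading timepoints to keep.
#' @return a re-z-scored [ts_panel()].
#' @export
truncate_panel <- function(panel, n_timepoints) {
  stopifnot(inherits(panel, "ts_panel"))
  if (n_timepoints > ncol(panel$data)) stop("n_timepoints exceeds panel length")
  ts_panel(panel$data[, seq_len(n_timepoints), drop = FALSE],
           panel$region_labels, panel$subject_id, zscore = TRUE)
}

#' Read a cohort manifest
#'
#' A manifest is a delimited-text table with columns `subject_id`,
#' `panel_path`, `cohort_role` (`backbone` or `analysis`) and `group`.
#' Relative panel paths are resolved against the manifest's directory.
#'
#' @param path manifest file path.
#' @return a `data.frame` with the four columns above.
#' @export
read_manifest <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("subject_id", "panel_path", "cohort_role", "group")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stop("manifest missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$subject_id)) stop("duplicate subject_id in manifest")
  if (!all(df$cohort_role %in% c("backbone", "analysis")))
    stop("cohort_role must be 'backbone' or 'analysis'")
  base <- dirname(path)
  abs <- ifelse(grepl("^(/|[A-Za-z]:)", df$panel_path), df$panel_path,
                file.path(base, df$panel_path))
  bad <- !file.exists(abs)
  if (any(bad)) stop("panel files not found: ", paste(abs[bad], collapse = ", "))
  df$panel_path <- abs
  df
}

#' Load the panels listed in a manifest
#'
#' @param manifest a data frame from [read_manifest()].
#' @param role restrict to one `cohort_role`, or `NULL` for all.
#' @param zscore z-score on load.
#' @return named list of [ts_panel()] objects keyed by subject id.
#' @export
load_panels <- function(manifest, role = NULL, zscore = TRUE) {
  if (!is.null(role)) manifest <- manifest[manifest$cohort_role == role, , drop = FALSE]
  if (nrow(manifest) == 0L) stop("no subjects with role '", role, "' in manifest")
  panels <- lapply(seq_len(nrow(manifest)), function(i)
    read_panel(manifest$panel_path[i], manifest$subject_id[i], zscore = zscore))
  names(panels) <- manifest$subject_id
  panels
}
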