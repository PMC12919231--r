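#' Run the full analysis pipeline from a configuration
#'
#' Executes the staged analysis — backbone inference on the reference cohort,
#' per-subject hyperedge weights under the requested schemes, nonparametric
#' group statistics, and optionally binary classification and the mediation
#' battery — writing every table to `out_dir` along with a provenance JSON
#' (configuration, seeds, package version). Identical configurations yield
#' byte-identical numeric outputs.
#'
#' @param config a named list, or the path of a YAML file holding one, with
#'   elements:
#'   \describe{
#'     \item{`manifest`}{path of the cohort manifest ([read_manifest()]).}
#'     \item{`lambda`}{numeric penalty or `"cv"` (default 0.05).}
#'     \item{`percentile`, `min_regions`, `quorum`}{backbone settings
#'       (defaults 5, 3, 0.5).}
#'     \item{`methods`}{weighting schemes to compute (default all four of
#'       [hyperedge_weights()]; add `"fn_mean_corr"` for network weights,
#'       which requires Schaefer-style labels).}
#'     \item{`alpha`}{FDR level (default 0.05).}
#'     \item{`tasks`}{optional list of 2-vectors of group labels to classify.}
#'     \item{`mediation`}{optional list with `clinical` (path), `z_var`,
#'       `outcomes`, `covariates`, `n_boot`.}
#'     \item{`seed`}{integer seed (default 1).}
#'   }
#' @param out_dir output directory (created if absent).
#' @return invisibly, a list with the fitted backbone, weight tables, stats,
#'   classifier reports and mediation battery.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  dflt <- list(lambda = 0.05, percentile = 5, min_regions = 3L, quorum = 0.5,
               methods = weight_methods, alpha = 0.05, seed = 1L)
  config <- utils::modifyList(dflt, config)
  if (is.null(config$manifest)) stop("config must name a manifest")
  fn_requested <- "fn_mean_corr" %in% config$methods
  methods <- setdiff(config$methods, "fn_mean_corr")
  if (!all(methods %in% weight_methods))
    stop("unknown weighting method(s): ",
         paste(setdiff(methods, weight_methods), collapse = ", "))
  manifest <- read_manifest(config$manifest)
  if (fn_requested) {
    probe <- read_panel(manifest$panel_path[1L], zscore = FALSE)
    parse_fn_labels(probe$region_labels)  # fail before any heavy computation
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  message("stage: structure inference")
  backbone_panels <- load_panels(manifest, role = "backbone")
  fit <- fit_hypergraph(backbone_panels, lambda = config$lambda,
                        percentile = config$percentile,
                        min_regions = config$min_regions,
                        quorum = config$quorum, seed = config$seed)
  write_incidence(fit$incidence, file.path(out_dir, "incidence.tsv"),
                  provenance = list(lambda = fit$lambda,
                                    percentile = fit$percentile,
                                    quorum = fit$quorum,
                                    min_regions = fit$min_regions,
                                    n_subjects = length(fit$subject_ids)))
  ana <- manifest[manifest$cohort_role == "analysis", , drop = FALSE]
  analysis_panels <- load_panels(ana, role = "analysis")
  groups <- ana$group
  message("stage: hyperedge weights")
  weights <- list()
  for (m in methods) {
    weights[[m]] <- hyperedge_weights(analysis_panels, fit, method = m,
                                      groups = groups)
    write_weight_table(weights[[m]], file.path(out_dir, paste0("weights_", m, ".tsv")))
  }
  if (fn_requested) {
    weights[["fn_mean_corr"]] <- fn_weights(analysis_panels, groups)
    write_weight_table(weights[["fn_mean_corr"]],
                       file.path(out_dir, "weights_fn_mean_corr.tsv"))
  }
  message("stage: group statistics")
  stats_out <- lapply(weights, group_stats, alpha = config$alpha)
  for (m in names(stats_out)) {
    write.table(stats_out[[m]]$omnibus,
                file.path(out_dir, paste0("stats_", m, "_omnibus.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(stats_out[[m]]$pairwise,
                file.path(out_dir, paste0("stats_", m, "_pairwise.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  classifiers <- list()
  if (!is.null(config$tasks)) {
    message("stage: classification")
    for (task in config$tasks) {
      task <- unlist(task)
      for (m in names(weights)) {
        sig <- stats_out[[m]]$omnibus$hyperedge_id[stats_out[[m]]$omnibus$significant]
        if (length(sig) == 0L) next
        key <- paste0(m, "_", paste(task, collapse = "-"))
        classifiers[[key]] <- classify_weights(weights[[m]], task,
                                               significant_ids = sig,
                                               seed = config$seed)
      }
    }
    if (length(classifiers)) {
      rep_df <- do.call(rbind, lapply(names(classifiers), function(k)
        data.frame(run = k, t(classifiers[[k]]$metrics))))
      write.table(rep_df, file.path(out_dir, "classification.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  med <- NULL
  if (!is.null(config$mediation)) {
    message("stage: mediation")
    mcfg <- config$mediation
    clinical <- read.delim(mcfg$clinical, sep = "\t", stringsAsFactors = FALSE)
    m1 <- names(weights)[1L]
    sig <- stats_out[[m1]]$omnibus$hyperedge_id[stats_out[[m1]]$omnibus$significant]
    if (length(sig)) {
      med <- run_mediation_battery(weights[[m1]], sig, clinical,
                                   z_var = mcfg$z_var, outcomes = mcfg$outcomes,
                                   covariates = mcfg$covariates,
                                   n_boot = if (is.null(mcfg$n_boot)) 1000L else mcfg$n_boot,
                                   seed = config$seed)
      write.table(as.data.frame(med), file.path(out_dir, "mediation.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  prov <- list(config = config, seed = config$seed,
               package_version = as.character(utils::packageVersion("hyperfc")),
               r_version = R.version.string)
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(fit = fit, weights = weights, stats = stats_out,
                 classifiers = classifiers, mediation = med))
}
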