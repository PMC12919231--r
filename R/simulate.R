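#' Configuration for the synthetic-cohort simulator
#'
#' Describes a latent-factor cohort: each planted hyperedge `h` carries an
#' independent standard-Gaussian latent series `f_h`; a member region `i` of
#' a subject in group `g` is generated as
#' \deqn{x_i = \rho f_h + \sqrt{1 - \rho^2}\, \sigma\, \eta_i}
#' with `eta_i` independent standard Gaussian noise, `rho` the
#' (hyperedge, group) coupling and `sigma = noise_sd`. Unassigned regions are
#' pure noise. With `noise_sd = 1`, `rho` is exactly the member-to-factor
#' correlation; `rho = 1` gives perfectly coupled members regardless of
#' `noise_sd`, and `rho = 0` gives independent noise. All series are z-scored
#' afterwards, as the pipeline expects.
#'
#' @param n_regions number of regions `N`.
#' @param n_timepoints series length `P`.
#' @param n_subjects_per_group named integer vector, group -> subject count.
#' @param planted_hyperedges list of region-index sets (each of size >= 3).
#'   Regions claimed by several hyperedges follow the first-listed one (a
#'   message reports the conflict).
#' @param coupling either a single value in `[0, 1]` applied everywhere, or a
#'   `hyperedges x groups` matrix of loadings (default 0.9).
#' @param noise_sd per-region noise scale (default 0.2).
#' @param mediation optional list with `a`, `b`, `c_prime` and `noise_sds`
#'   (length 2: mediator and outcome noise) used by [simulate_mediation()].
#' @param region_labels optional region names (default `region_<i>`).
#' @param seed integer seed; all randomness flows from it.
#' @return a list of class `simulation_config`.
#' @export
simulation_config <- function(n_regions, n_timepoints, n_subjects_per_group,
                              planted_hyperedges = list(), coupling = 0.9,
                              noise_sd = 0.2,
                              mediation = NULL, region_labels = NULL,
                              seed = 1L) {
  if (is.null(names(n_subjects_per_group)))
    names(n_subjects_per_group) <- paste0("g", seq_along(n_subjects_per_group))
  K <- length(planted_hyperedges)
  G <- length(n_subjects_per_group)
  for (h in planted_hyperedges) {
    if (length(h) < 3L) stop("every planted hyperedge needs >= 3 regions")
    if (any(h < 1L | h > n_regions)) stop("planted region index out of range")
  }
  if (is.matrix(coupling)) {
    if (!all(dim(coupling) == c(K, G))) stop("coupling matrix must be K x G")
  } else {
    coupling <- matrix(coupling, K, G)
  }
  if (any(coupling < 0 | coupling > 1)) stop("coupling must lie in [0, 1]")
  colnames(coupling) <- names(n_subjects_per_group)
  if (noise_sd <= 0) stop("noise_sd must be positive")
  if (is.null(region_labels)) region_labels <- paste0("region_", seq_len(n_regions))
  structure(list(n_regions = as.integer(n_regions),
                 n_timepoints = as.integer(n_timepoints),
                 n_subjects_per_group = n_subjects_per_group,
                 planted_hyperedges = planted_hyperedges,
                 coupling = coupling, noise_sd = noise_sd,
                 mediation = mediation, region_labels = region_labels,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Simulate a cohort of regional time-series panels
#'
#' Draws one [ts_panel()] per subject from the latent-factor model described
#' in [simulation_config()], together with the ground-truth membership
#' matrix of the planted hyperedges (full `N x N` layout, column = hyperedge
#' centred at its first-listed region).
#'
#' @param config a [simulation_config()].
#' @return list with `panels` (named list of z-scored panels), `groups`
#'   (group label per panel), `membership` (binary `N x N` ground truth),
#'   `config`.
#' @export
simulate_panels <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  N <- config$n_regions; P <- config$n_timepoints
  K <- length(config$planted_hyperedges)
  # resolve overlapping claims: first-listed hyperedge wins
  owner <- integer(N)
  for (h in seq_len(K)) {
    mem <- config$planted_hyperedges[[h]]
    clash <- mem[owner[mem] != 0L]
    if (length(clash))
      message("region(s) ", paste(clash, collapse = ", "),
              " already claimed; keeping first-listed hyperedge")
    mem <- mem[owner[mem] == 0L]
    owner[mem] <- h
  }
  # ground truth in the pipeline's centroid layout: every member region of a
  # planted hyperedge is the centroid of a hyperedge containing the whole set
  membership <- matrix(0, N, N,
                       dimnames = list(config$region_labels, config$region_labels))
  for (h in seq_len(K)) {
    mem <- which(owner == h)
    membership[mem, mem] <- 1
  }
  panels <- list(); groups <- character(); si <- 0L
  for (g in seq_along(config$n_subjects_per_group)) {
    gname <- names(config$n_subjects_per_group)[g]
    for (s in seq_len(config$n_subjects_per_group[[g]])) {
      si <- si + 1L
      X <- matrix(rnorm(N * P, sd = config$noise_sd), N, P)
      for (h in seq_len(K)) {
        mem <- which(owner == h)
        rho <- config$coupling[h, g]
        f <- rnorm(P)
        X[mem, ] <- rho * matrix(f, length(mem), P, byrow = TRUE) +
          sqrt(1 - rho^2) * X[mem, , drop = FALSE]
      }
      id <- sprintf("%s_%02d", gname, s)
      panels[[id]] <- ts_panel(X, config$region_labels, id, zscore = TRUE)
      groups[si] <- gname
    }
  }
  list(panels = panels, groups = groups, membership = membership,
       config = config)
}

#' Simulate a linear mediation triple with known ground truth
#'
#' Generates `z ~ N(0, 1)`, `w = a z + e_2`, `y = c' z + b w + e_1` with
#' independent Gaussian noise, the generative counterpart of the three
#' mediation regressions, and returns the true path coefficients alongside
#' the data.
#'
#' @param n sample size.
#' @param a,b,c_prime true path coefficients.
#' @param noise_sds length-2 vector: noise sd of the mediator and outcome
#'   equations (default `c(1, 1)`).
#' @param seed integer seed.
#' @return list with vectors `z`, `w`, `y` and `truth = c(a, b, c_prime,
#'   indirect, total)`.
#' @export
simulate_mediation <- function(n, a = 0.5, b = 0.4, c_prime = 0.3,
                               noise_sds = c(1, 1), seed = 1L) {
  set.seed(as.integer(seed))
  z <- rnorm(n)
  w <- a * z + rnorm(n, sd = noise_sds[1L])
  y <- c_prime * z + b * w + rnorm(n, sd = noise_sds[2L])
  list(z = z, w = w, y = y,
       truth = c(a = a, b = b, c_prime = c_prime, indirect = a * b,
                 total = c_prime + a * b))
}

#' Simulate a full study: backbone cohort, analysis groups and clinical table
#'
#' Convenience wrapper emulating the full study design: a reference
#' ("backbone") cohort used only for structure inference, three analysis
#' groups with a group-dependent coupling drop in one planted hyperedge (the
#' "affected" hyperedge, weaker in the last-listed group), and a clinical
#' table with an exposure, outcomes generated through the affected
#' hyperedge's coupling, and nuisance covariates.
#'
#' @param n_regions,n_timepoints panel dimensions.
#' @param n_backbone reference-cohort size (default 30).
#' @param n_per_group analysis subjects per group (default 20), groups
#'   `HC`, `MCI`, `AD`.
#' @param planted_hyperedges list of region-index sets; default three
#'   disjoint 4-region hyperedges.
#' @param affected index (in `planted_hyperedges`) of the group-sensitive
#'   hyperedge (default 1).
#' @param coupling_healthy,coupling_affected coupling of the affected
#'   hyperedge in the unaffected groups and in `AD` (defaults 0.9 / 0.4).
#' @param noise_sd per-region noise (default 0.2).
#' @param seed integer seed.
#' @return list with `backbone_panels`, `analysis_panels`, `groups`,
#'   `membership`, `clinical` (data.frame with `subject_id`, `tau_suvr`,
#'   `memory`, `adas13`, `age`, `sex`), `affected_centroids` (region indices
#'   of the group-sensitive hyperedge's members).
#' @export
simulate_study <- function(n_regions = 20L, n_timepoints = 192L,
                           n_backbone = 30L, n_per_group = 20L,
                           planted_hyperedges = list(1:4, 5:8, 9:12),
                           affected = 1L, coupling_healthy = 0.9,
                           coupling_affected = 0.4, noise_sd = 0.2,
                           seed = 1L) {
  seed <- as.integer(seed)
  K <- length(planted_hyperedges)
  labels <- schaefer_like_labels(n_regions)
  cfg_bb <- simulation_config(n_regions, n_timepoints,
                              c(BB = n_backbone), planted_hyperedges,
                              coupling = coupling_healthy, noise_sd = noise_sd,
                              region_labels = labels, seed = seed)
  bb <- simulate_panels(cfg_bb)
  coup <- matrix(coupling_healthy, K, 3L)
  coup[affected, 3L] <- coupling_affected
  cfg_an <- simulation_config(n_regions, n_timepoints,
                              c(HC = n_per_group, MCI = n_per_group,
                                AD = n_per_group),
                              planted_hyperedges, coupling = coup,
                              region_labels = labels,
                              noise_sd = noise_sd, seed = seed + 1L)
  an <- simulate_panels(cfg_an)
  set.seed(seed + 2L)
  nA <- length(an$panels)
  # exposure raised along the disease gradient; memory depends on the exposure
  # directly and on the affected hyperedge's coupling (so its measured weight
  # carries a genuine mediated component)
  grp_shift <- c(HC = 0, MCI = 0.5, AD = 1)[an$groups]
  rho_s <- ifelse(an$groups == "AD", coupling_affected, coupling_healthy)
  tau <- grp_shift + rnorm(nA, sd = 0.3)
  clinical <- data.frame(subject_id = names(an$panels),
                         tau_suvr = tau,
                         memory = -0.4 * tau + 0.8 * rho_s + rnorm(nA, sd = 0.3),
                         adas13 = 8 * tau + rnorm(nA, sd = 3),
                         age = round(rnorm(nA, 73, 7), 1),
                         sex = sample(0:1, nA, replace = TRUE))
  list(backbone_panels = bb$panels, analysis_panels = an$panels,
       groups = an$groups, membership = bb$membership, clinical = clinical,
       affected_centroids = planted_hyperedges[[affected]])
}

# Schaefer-style labels cycling the seven canonical networks over both
# hemispheres so network parsing and FN weights work on simulated cohorts
schaefer_like_labels <- function(n_regions) {
  nets <- c("Vis", "SomMot", "DorsAttn", "SalVentAttn", "Limbic", "Cont",
            "Default")
  hemi <- rep(c("LH", "RH"), length.out = n_regions)
  net <- rep(rep(nets, each = 2L), length.out = n_regions)
  idx <- stats::ave(seq_len(n_regions), paste(hemi, net), FUN = seq_along)
  paste(hemi, net, idx)
}
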