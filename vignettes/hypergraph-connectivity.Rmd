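---
title: "High-order functional connectivity with hypergraphs and algebraic connectivity"
author: "hyperfc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{High-order functional connectivity with hypergraphs and algebraic connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hyperfc)
```

## The model

Conventional functional-connectivity analysis describes the brain as a graph
whose edges are pairwise correlations between regional BOLD time series. Many
of the interactions that matter in neurodegeneration, however, involve more
than two regions at once. `hyperfc` models these high-order interactions with
a **hypergraph**: a set of `N` regions (nodes) and `M` hyperedges, each
hyperedge a set of at least three regions, encoded in a binary incidence
matrix `H` (`N x M`). The package implements the whole analysis chain around
that object:

1. **Structure inference.** Each hyperedge is anchored at a *centroid*
   region. For every subject of a reference cohort and every centroid `n`, a
   non-negative LASSO regresses the centroid's z-scored series on all other
   regions:
   \[
     \min_{\alpha \ge 0}\; \frac{1}{2P}\lVert x_n - X_n\alpha\rVert_2^2
       + \lambda \lVert\alpha\rVert_1 ,
   \]
   with the centroid's own column zeroed. The non-negativity constraint keeps
   membership interpretable (a region either helps reconstruct the centroid
   or it does not); the L1 penalty enforces sparsity. Coefficient matrices
   are thresholded at the 5th percentile of their positive entries,
   binarized, filtered to hyperedges with at least 3 regions, and combined
   across subjects by majority voting (a cell survives when at least 50% of
   subjects carry it). The surviving columns form the shared backbone `H`.
2. **Hyperedge weighting.** Per analysis subject, each hyperedge is weighted
   by the **algebraic connectivity** (Fiedler value) of the graph its
   members induce: the adjacency is the absolute Pearson correlation matrix
   of the member series with zero diagonal, and the weight is the
   second-smallest eigenvalue of its Laplacian `L = D - A`. The Fiedler
   value is 0 exactly when the subgraph is disconnected and grows with how
   coherently the members co-fluctuate, which makes it a natural high-order
   coupling summary. Three baselines (Gaussian similarity kernel with the
   median heuristic, mean pairwise Pearson correlation, squared L2 norm of
   the member-restricted LASSO coefficients) and within-network mean
   correlations over the seven canonical functional systems are provided for
   comparison.
3. **Downstream battery.** Nonparametric group comparison per hyperedge
   (Kruskal–Wallis omnibus, Benjamini–Hochberg FDR across hyperedges,
   Cliff's delta effect sizes, Mann–Whitney post-hoc within each group pair
   restricted to omnibus-significant hyperedges), random-forest
   classification of group pairs from hyperedge weights, and a
   three-equation OLS mediation analysis with a case-resampling bootstrap
   for the indirect effect.

The hypergraph algebra (node degrees \(d(v_n) = \sum_m w_m H_{nm}\),
hyperedge degrees \(\delta(e_m) = \sum_n H_{nm}\), similarity
\(S = H\,W\,D_e^{-1}H^\top\)) is exposed as first-class operations.
`S` is computed and returned for completeness although no downstream stage
consumes it; it is the natural node-level summary of a weighted hypergraph
and is useful for inspection.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `lambda` | 0.05 | L1 penalty of the non-negative LASSO, on the per-sample-averaged objective shown above. `select_lambda_cv()` scans 0.01–0.30 in steps of 0.01 with 5-fold cross-validation over timepoints when data-driven selection is wanted. |
| `percentile` | 5 | threshold percentile of the *positive* coefficient entries. Computed over positive entries only: the solver returns many exact zeros, and a percentile over all cells would be identically zero, making the threshold vacuous. |
| `min_regions` | 3 | minimum hyperedge cardinality (centroid included); pairs are the territory of ordinary graph analysis. |
| `quorum` | 0.5 | majority-vote fraction; a tie at exactly 50% counts in favour, the literal reading of "at least half". |
| `alpha` | 0.05 | FDR level, applied across all hyperedges for the omnibus family and within each group pair for the post-hoc family. |
| `n_boot` | 1000 | bootstrap repetitions for the indirect-effect interval. |

The LASSO objective is the per-sample-averaged convention: a grid of
0.01–0.30 for `lambda` is only meaningful when the quadratic term is scaled
by `1/(2P)`, which is also what standard solvers implement; the
equivalent unaveraged penalty is `lambda * P`. The solver is cyclic
projected coordinate descent run to a coefficient-change tolerance of
`1e-10` (at most `1e5` sweeps), tight enough that sparsity patterns near the
threshold are reproducible bit-for-bit.

Further numerical choices, each made once and kept:

* **Percentile method** — linear interpolation between order statistics
  (type-7 quantile); entries strictly below the threshold are removed, ties
  at the threshold kept, so a degenerate all-equal coefficient distribution
  keeps its entries.
* **CV folds over timepoints** are contiguous blocks, not shuffled, because
  fMRI series are autocorrelated; shuffled folds would leak information
  between train and validation.
* **Cardinality filter placement** — the minimum-3 filter runs per subject
  before voting *and* again on the voted consensus, since voting can shrink
  a membership below 3.
* **Centroid self-membership** is forced before filtering: a hyperedge is
  defined as the centroid plus its predictors.
* **Eigen-solver** — dense symmetric eigendecomposition. Backbone hyperedges
  have at most a handful of members, where the dense solve is exact and
  cheap; iterative tricks (trace minimization, LU) only pay off on large
  graphs. Eigenvalues with magnitude below `1e-10` are treated as zero, so
  numerically disconnected subgraphs yield weight 0 (with a warning naming
  the hyperedge) rather than spurious tiny positives.
* **Median heuristic** — the Gaussian kernel bandwidth is the median of the
  raw (not squared) pairwise Euclidean distances, computed per hyperedge and
  per subject; kernel values are averaged (not summed) over pairs so weights
  are comparable across hyperedge cardinalities.
* **L2-norm weights** are per-subject refits at the backbone's `lambda`,
  restricted to the hyperedge's non-centroid members, keeping the weight
  subject-specific while the structure stays shared.
* **Mann–Whitney** tests are two-sided with the usual exact/normal-with-ties
  switching of `stats::wilcox.test`.
* **Bootstrap flavour** — percentile interval over case resamples, p-value
  `2 * min(P(ab <= 0), P(ab >= 0))` floored at `1/n_boot`. Degenerate
  (collinear) resamples are redrawn.
* **Random-forest grid** — trees {100, 300, 500}, depth {3, 5, unlimited}
  (as `maxnodes` {8, 32, unlimited}), minimum node size {2, 5, 10};
  selection by mean 5-fold CV accuracy, ties to the first grid row. Reported
  precision/recall/F1 are class-support-weighted, under which recall equals
  accuracy.

## What the simulator emulates — and what it does not

`simulate_panels()` draws each planted hyperedge's members from a shared
latent factor: member `i` of hyperedge `h` in group `g` is
\[ x_i = \rho\, f_h + \sqrt{1-\rho^2}\,\sigma\,\eta_i , \]
with `f_h` and `eta_i` independent standard Gaussian series, then z-scores
every series. `rho` is the coupling knob that the Fiedler weight responds
to (with `sigma = 1`, `rho` is exactly the member–factor correlation);
`rho = 1` gives perfectly coherent members regardless of `sigma`, `rho = 0`
pure noise. Defaults are `rho = 0.9` and `sigma = 0.2`: strong but not
degenerate within-module coherence, the regime in which resting-state
modules are usually described. Group effects are planted by lowering `rho`
for one hyperedge in one group; mediation triples follow the generative form
of the three regressions with chosen `(a, b, c')`.

This emulates the *statistical* structure the pipeline assumes — z-scored
stationary series with block-correlated communities and group-dependent
coupling — and nothing of the physiology: no hemodynamic response, no 1/f
noise spectrum, no motion or scanner artifacts, no spatial autocorrelation
between neighbouring parcels. Passing tests therefore show that the
machinery recovers planted structure and effects under its own model; they
do not certify performance on real fMRI, where preprocessing quality and
deviations from stationarity dominate.

Default study sizes (30 reference subjects, three analysis groups of 20,
`N = 20` regions, `P = 192` timepoints; statistics calibrations at 96
hyperedges with groups of 20–80; mediation at `n = 500–2000` with 1000
bootstrap draws) were chosen as the smallest designs at which every
stage's behaviour — recovery, error control, power, coverage — is cleanly
measurable.

## Worked example

```{r example, eval = FALSE}
study <- simulate_study(seed = 7)
fit <- fit_hypergraph(study$backbone_panels, lambda = 0.05)
fit
wt <- hyperedge_weights(study$analysis_panels, fit, method = "algebraic",
                        groups = study$groups)
st <- group_stats(wt)
st
sig <- st$omnibus$hyperedge_id[st$omnibus$significant]
classify_weights(wt, c("HC", "AD"), significant_ids = sig, seed = 1)
run_mediation_battery(wt, sig[1], study$clinical, z_var = "tau_suvr",
                      outcomes = c("memory", "adas13"), n_boot = 1000,
                      seed = 1)
```

## Known limitations

* The Fiedler weight requires the induced subgraph to be connected; a
  disconnected subgraph gets weight 0 with a warning, which conflates "no
  coupling" with "two coupled sub-blocks". Sample correlations almost never
  vanish exactly, so this arises only at the zero-tolerance boundary.
* Hyperedges are undirected and binary; weighted membership and directed
  prediction relations are out of scope.
* Majority voting assumes the reference cohort is homogeneous; a bimodal
  cohort can vote away structure present in both modes separately.
* The mediation model is the linear three-equation decomposition; it is a
  descriptive path analysis, not a causal identification strategy.
* With very short series (`P` below ~50 timepoints) the LASSO designs become
  noisy and backbone stability degrades; `truncation_stability()` is the
  diagnostic for choosing a safe minimum length.
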