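test_that("percentile threshold interpolates over the positive entries", {
  A <- matrix(0, 11, 10)
  A[2:101] <- seq(0.01, 1, by = 0.01)  # 100 positive entries, rest zero
  B <- threshold_binarize(A, percentile = 5)
  # 5th percentile by linear interpolation: 0.05 + 0.95 * 0.01 = 0.0595
  expect_equal(sum(A > 0) - sum(B), 5)           # exactly 0.01..0.05 removed
  expect_equal(B[A >= 0.06], rep(1, 95))
  expect_equal(B[A == 0], rep(0, sum(A == 0)))
})

test_that("threshold keeps a degenerate all-equal distribution", {
  A <- matrix(0, 4, 4); A[1, 2:4] <- 0.5
  expect_equal(sum(threshold_binarize(A, 5)), 3)
  expect_equal(threshold_binarize(matrix(0, 3, 3)), matrix(0, 3, 3))
})

test_that("cardinality filter zeroes small hyperedges and keeps centroids", {
  Hs <- matrix(0, 5, 5)
  Hs[2, 1] <- 1                 # centroid 1 + one member: below 3, zeroed
  Hs[c(3, 4), 2] <- 1           # centroid 2 + two members: kept (3 regions)
  out <- filter_min_cardinality(Hs, 3)
  expect_equal(sum(out[, 1]), 0)
  expect_equal(unname(out[, 2]), c(0, 1, 1, 1, 0))  # diagonal forced to 1
  expect_equal(sum(filter_min_cardinality(diag(5), 3)), 0)  # all below threshold
  expect_error(filter_min_cardinality(Hs, 0), "min_regions")
})

test_that("majority vote implements the at-least-50% tie rule", {
  base <- matrix(0, 4, 4)
  mk <- function(cells) { m <- base; m[cells] <- 1; m }
  # hyperedge at centroid 1 with members 2,3; vary support per cell
  all3 <- mk(cbind(c(1, 2, 3), 1))
  two <- mk(cbind(c(1, 2, 3), 1))
  H <- majority_vote(list(all3, two, base * 0), quorum = 0.5)  # 2/3 support
  expect_equal(unname(H$entries[, 1]), c(1, 1, 1, 0))
  # exactly 50% over 2 subjects passes
  H2 <- majority_vote(list(all3, base), quorum = 0.5)
  expect_equal(ncol(H2$entries), 1L)
  # 1/3 support fails
  H3 <- majority_vote(list(all3, base, base), quorum = 0.5)
  expect_equal(ncol(H3$entries), 0L)
  expect_error(majority_vote(list()), "empty")
})

test_that("vote re-applies the cardinality filter to the consensus", {
  m1 <- matrix(0, 4, 4); m1[c(1, 2, 3), 1] <- 1
  m2 <- matrix(0, 4, 4); m2[c(1, 2, 4), 1] <- 1
  # cells (1,1),(2,1) have 2/2 support; (3,1),(4,1) only 1/2 under quorum .51
  H <- majority_vote(list(m1, m2), quorum = 0.51)
  expect_equal(ncol(H$entries), 0L)  # voted column fell below 3 members
})

test_that("single-element lambda grid is chosen as-is", {
  p <- rand_panel(N = 4, P = 30, seed = 6)
  sel <- select_lambda_cv(list(p), grid = 0.07, folds = 3)
  expect_equal(sel$chosen, 0.07)
  expect_error(select_lambda_cv(list(p), grid = numeric(0)), "empty")
})

test_that("CV selection equals an exhaustive independent loop on the same folds", {
  panels <- lapply(1:2, function(s)
    factor_panel(N = 5, P = 45, members = 1:3, rho = 0.8, seed = 100 + s,
                 id = paste0("s", s)))
  grid <- c(0.03, 0.08, 0.15)
  folds <- 3L
  sel <- select_lambda_cv(panels, grid = grid, folds = folds)
  # independent oracle: glmnet fits over identical contiguous fold blocks
  P <- 45L
  bounds <- floor((seq_len(folds + 1) - 1) * P / folds)
  fold_id <- rep(seq_len(folds), times = diff(bounds))
  val <- matrix(NA_real_, 0, length(grid))
  for (p in panels) {
    X <- t(p$data)
    for (n in 1:5) {
      for (k in seq_len(folds)) {
        tr <- fold_id != k
        mses <- sapply(grid, function(l) {
          g <- glmnet::glmnet(X[tr, -n], X[tr, n], lambda = l,
                              lower.limits = 0, intercept = FALSE,
                              standardize = FALSE, thresh = 1e-14)
          b <- as.vector(coef(g))[-1]
          mean((X[!tr, n] - X[!tr, -n] %*% b)^2)
        })
        val <- rbind(val, mses)
      }
    }
  }
  oracle_mean <- colMeans(val)
  expect_equal(sel$cv_val_mse$mean, oracle_mean, tolerance = 1e-4)
  expect_equal(sel$chosen, grid[which.min(oracle_mean)])
})

test_that("backbone inference is deterministic and recovers planted structure", {
  cfg <- simulation_config(12, 120, c(ref = 12), list(1:4, 5:8), seed = 17)
  sim <- simulate_panels(cfg)
  fit1 <- fit_hypergraph(sim$panels, lambda = 0.05)
  fit2 <- fit_hypergraph(sim$panels, lambda = 0.05)
  expect_identical(fit1$incidence$entries, fit2$incidence$entries)
  st <- structure_stability(fit1$incidence, sim$membership)
  expect_gte(st$jaccard, 0.9)
})

test_that("truncation at the full length reproduces the backbone exactly", {
  sim <- simulate_panels(simulation_config(10, 80, c(ref = 8), list(1:4), seed = 23))
  tb <- truncation_stability(sim$panels, lambda = 0.05, lengths = c(80, 60))
  expect_equal(tb$jaccard[tb$n_timepoints == 80], 1.0)
  expect_true(all(c("n_timepoints", "jaccard", "pearson", "n_hyperedges")
                  %in% colnames(tb)))
  expect_error(truncation_stability(sim$panels, 0.05, lengths = 100), "<=")
})
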