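test_that("subgraph adjacency is |Pearson r| with a zero diagonal", {
  p <- rand_panel(N = 5, P = 60, seed = 1)
  g <- subgraph_fc(p, 1:5)
  for (i in 1:4) for (j in (i + 1):5)
    expect_equal(g$adjacency[i, j],
                 abs(oracle_pearson(p$data[i, ], p$data[j, ])), tolerance = 1e-12)
  expect_equal(unname(diag(g$adjacency)), rep(0, 5))
  expect_lt(max(abs(rowSums(g$laplacian))), 1e-12)
  ev <- eigen(g$laplacian, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-12)  # positive semidefinite
})

test_that("identical and sign-flipped series give unit adjacency", {
  set.seed(2)
  x <- rnorm(50)
  X <- rbind(x, x, -x)
  p <- ts_panel(X, c("a", "b", "c"))
  g <- subgraph_fc(p, 1:3)
  expect_equal(unname(g$adjacency[upper.tri(g$adjacency)]), rep(1, 3))
})

test_that("closed-form Fiedler values: complete graph, path, disconnected", {
  K4 <- matrix(1, 4, 4); diag(K4) <- 0
  expect_equal(algebraic_connectivity(diag(rowSums(K4)) - K4), 4.0)
  P3 <- matrix(0, 3, 3); P3[1, 2] <- P3[2, 1] <- P3[2, 3] <- P3[3, 2] <- 1
  expect_equal(algebraic_connectivity(diag(rowSums(P3)) - P3), 1.0)
  D2 <- matrix(0, 4, 4); D2[1, 2] <- D2[2, 1] <- D2[3, 4] <- D2[4, 3] <- 1
  expect_equal(algebraic_connectivity(diag(rowSums(D2)) - D2), 0.0)
  expect_error(algebraic_connectivity(matrix(0, 1, 1)), "2 nodes")
})

test_that("Fiedler value matches the SVD oracle on random weighted graphs", {
  for (s in 1:100) {
    k <- sample(3:7, 1)
    A <- rand_graph(k, seed = s)
    L <- diag(rowSums(A)) - A
    expect_equal(algebraic_connectivity(L), oracle_fiedler(A), tolerance = 1e-8)
  }
})

test_that("algebraic connectivity is bounded by k and monotone in edge weight", {
  for (s in 1:50) {
    k <- sample(3:6, 1)
    A <- rand_graph(k, seed = 200 + s)
    a0 <- algebraic_connectivity(diag(rowSums(A)) - A)
    expect_gte(a0, 0); expect_lte(a0, k + 1e-12)
    ij <- sort(sample(k, 2))
    A2 <- A; A2[ij[1], ij[2]] <- A2[ij[2], ij[1]] <- A[ij[1], ij[2]] + 0.5
    a1 <- algebraic_connectivity(diag(rowSums(A2)) - A2)
    expect_gte(a1, a0 - 1e-10)
  }
})

test_that("algebraic weights: coupled triple gives a(K3)=3, disconnection warns", {
  set.seed(5)
  x <- rnorm(40)
  X <- rbind(x, x, x, matrix(rnorm(2 * 40), 2))
  p <- ts_panel(X, paste0("R", 1:5))
  E <- matrix(0, 5, 1); E[1:3, 1] <- 1
  H <- incidence_matrix(E, paste0("R", 1:5), centroids = 1L)
  wt <- hyperedge_weights(p, H, method = "algebraic")
  expect_equal(unname(wt$values[1, 1]), 3.0, tolerance = 1e-12)
  # a block-zero adjacency cannot arise from sample correlations, so force a
  # disconnected Laplacian directly
  L <- matrix(0, 4, 4); L[1:2, 1:2] <- matrix(c(1, -1, -1, 1), 2)
  L[3:4, 3:4] <- matrix(c(1, -1, -1, 1), 2)
  expect_equal(algebraic_connectivity(L), 0)
})

test_that("mean weight under the latent-factor model increases with coupling", {
  rhos <- c(0.2, 0.4, 0.6, 0.8)
  means <- sapply(seq_along(rhos), function(i) {
    w <- sapply(1:60, function(s) {
      p <- factor_panel(N = 4, P = 100, members = 1:4, rho = rhos[i],
                        seed = 1000 * i + s)
      algebraic_connectivity(subgraph_fc(p, 1:4))
    })
    mean(w)
  })
  expect_true(all(diff(means) > 0))
})

test_that("gaussian kernel weight: identical members, closed form, range", {
  set.seed(7)
  x <- rnorm(30)
  p_id <- ts_panel(rbind(x, x, x), paste0("R", 1:3))
  E <- matrix(1, 3, 1)
  H <- incidence_matrix(E, paste0("R", 1:3), centroids = 1L)
  wt <- hyperedge_weights(p_id, H, method = "gaussian")
  expect_equal(unname(wt$values[1, 1]), 1.0)
  # two members at distance d with sigma = d (median of one distance)
  p2 <- rand_panel(N = 3, P = 25, seed = 8)
  expect_equal(hyperfc:::gaussian_weight_one(p2, 1:2), exp(-1 / 2),
               tolerance = 1e-12)
  for (s in 1:10) {
    p <- rand_panel(N = 6, P = 40, seed = 300 + s)
    w <- hyperfc:::gaussian_weight_one(p, 1:5)
    expect_gt(w, 0); expect_lte(w, 1)
  }
})

test_that("mean-correlation weight equals the brute-force pair loop", {
  for (s in 1:10) {
    p <- rand_panel(N = 6, P = 50, seed = 400 + s)
    mem <- sort(sample(6, 4))
    pairs <- combn(mem, 2)
    oracle <- mean(apply(pairs, 2, function(ij)
      oracle_pearson(p$data[ij[1], ], p$data[ij[2], ])))
    expect_equal(hyperfc:::mean_corr_one(p, mem), oracle, tolerance = 1e-12)
  }
})

test_that("squared-L2 weight restricts to non-centroid members", {
  A <- matrix(0, 5, 5)
  A[1, 2] <- 0.3; A[1, 3] <- 0.4; A[1, 5] <- 9  # region 5 outside the hyperedge
  E <- matrix(0, 5, 1); E[1:3, 1] <- 1
  H <- incidence_matrix(E, paste0("R", 1:5), centroids = 1L)
  expect_equal(weight_lasso_l2(A, H), 0.25)
  expect_equal(weight_lasso_l2(matrix(0, 5, 5), H), 0)
  # end-to-end refit agrees with applying weight_lasso_l2 to the refit matrix
  p <- factor_panel(N = 5, P = 80, members = 1:3, rho = 0.9, seed = 9)
  wt <- hyperedge_weights(p, H, method = "lasso_l2", lambda = 0.05)
  Afit <- coefficient_matrix(p, 0.05)
  expect_equal(unname(wt$values[1, 1]), weight_lasso_l2(Afit, H),
               tolerance = 1e-12)
})

test_that("functional-network parsing and within-network weights", {
  nets <- c("Vis", "SomMot", "DorsAttn", "SalVentAttn", "Limbic", "Cont", "Default")
  labels <- as.vector(t(outer(c("LH", "RH"), nets, function(h, n) paste(h, n, "1"))))
  expect_equal(levels(parse_fn_labels(labels)), nets)
  expect_error(parse_fn_labels("LH Mystery 1"), "cannot parse")
  set.seed(11)
  X <- matrix(rnorm(14 * 40), 14, 40)
  vis <- which(parse_fn_labels(labels) == "Vis")
  X[vis[2], ] <- X[vis[1], ]  # identical series within Vis
  p <- ts_panel(X, labels)
  wt <- fn_weights(p)
  expect_equal(ncol(wt$values), 7L)
  expect_equal(unname(wt$values[1, "Vis"]), 1.0, tolerance = 1e-12)
})

test_that("weights are invariant to member ordering", {
  p <- rand_panel(N = 6, P = 50, seed = 12)
  mem <- c(2, 4, 5, 6)
  perm <- c(5, 2, 6, 4)
  expect_equal(algebraic_connectivity(subgraph_fc(p, mem)),
               algebraic_connectivity(subgraph_fc(p, perm)))
  expect_equal(hyperfc:::gaussian_weight_one(p, mem),
               hyperfc:::gaussian_weight_one(p, perm))
  expect_equal(hyperfc:::mean_corr_one(p, mem),
               hyperfc:::mean_corr_one(p, perm))
})

test_that("weight table I/O round-trips", {
  vals <- matrix(runif(6), 3, 2, dimnames = list(c("a", "b", "c"), c("e1", "e2")))
  wt <- hyperfc:::weight_table(vals, "algebraic", c("HC", "MCI", "AD"))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_weight_table(wt, f)
  wt2 <- read_weight_table(f)
  expect_equal(wt2$values, wt$values, tolerance = 1e-12)
  expect_identical(wt2$method, "algebraic")
  expect_identical(wt2$group_labels, wt$group_labels)
})
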