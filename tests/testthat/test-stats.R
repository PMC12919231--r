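make_wt <- function(values, groups, method = "algebraic") {
  rownames(values) <- paste0("s", seq_len(nrow(values)))
  colnames(values) <- paste0("e", seq_len(ncol(values)))
  hyperfc:::weight_table(values, method, groups)
}

test_that("Cliff's delta: separation, ties, antisymmetry, brute force", {
  expect_equal(cliffs_delta(c(1, 2, 3), c(4, 5, 6)), -1.0)
  expect_equal(cliffs_delta(c(1, 2), c(1, 2)), 0.0)
  expect_equal(cliffs_delta(c(5, 6), c(1, 2, 3)), 1.0)
  expect_error(cliffs_delta(numeric(0), 1), "non-empty")
  for (s in 1:20) {
    set.seed(s)
    x <- sample(1:10, 5, TRUE); y <- sample(1:10, 6, TRUE)
    expect_equal(cliffs_delta(x, y), oracle_cliffs(x, y))
    expect_equal(cliffs_delta(x, y), -cliffs_delta(y, x))
  }
})

test_that("global effect size averages |delta| over the three pairs", {
  expect_equal(global_effect_size(list(1:3, 4:6, 7:9)), 1.0)
  expect_equal(global_effect_size(list(1:3, 1:3, 1:3)), 0.0)
  for (s in 1:10) {
    set.seed(s)
    g <- replicate(3, rnorm(7), simplify = FALSE)
    oracle <- mean(c(abs(oracle_cliffs(g[[1]], g[[2]])),
                     abs(oracle_cliffs(g[[1]], g[[3]])),
                     abs(oracle_cliffs(g[[2]], g[[3]]))))
    expect_equal(global_effect_size(g), oracle)
  }
})

test_that("Kruskal-Wallis: hand-ranked H, degenerate rule, invariance", {
  kw <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))
  expect_equal(kw$statistic, 7.2)
  expect_equal(kruskal_wallis(list(c(2, 2), c(2, 2, 2)))$p.value, 1)
  expect_error(kruskal_wallis(list(1:3, numeric(0))), "empty")
  set.seed(3)
  g <- list(rnorm(8), rnorm(6) + 1, rnorm(7))
  kw1 <- kruskal_wallis(g)
  kw2 <- kruskal_wallis(lapply(g, function(v) exp(v)))  # strictly monotone map
  expect_equal(kw1$statistic, kw2$statistic)
  expect_equal(kw1$p.value, kw2$p.value)
})

test_that("Kruskal-Wallis holds its nominal type-I rate", {
  set.seed(7)
  rej <- mean(replicate(1000, {
    kruskal_wallis(list(rnorm(8), rnorm(8), rnorm(8)))$p.value < 0.05
  }))
  expect_gte(rej, 0.03); expect_lte(rej, 0.07)
})

test_that("BH adjustment matches the step-up formula", {
  out <- fdr_bh(c(0.01, 0.02, 0.03, 0.04))
  expect_equal(out$p_adjusted, rep(0.04, 4))
  expect_equal(fdr_bh(0.03)$p_adjusted, 0.03)
  expect_error(fdr_bh(c(0.5, 1.2)), "\\[0, 1\\]")
  for (s in 1:20) {
    set.seed(s)
    p <- runif(sample(3:8, 1))
    adj <- fdr_bh(p)$p_adjusted
    expect_equal(adj, oracle_bh(p))
    expect_true(all(adj >= p))
  }
})

test_that("normality screen flags heavy tails and reports all cells", {
  set.seed(9)
  vals <- cbind(rlnorm(300), rnorm(300))
  groups <- rep(c("HC", "MCI", "AD"), each = 100)
  wt <- make_wt(vals, groups)
  ns <- normality_screen(wt)
  expect_equal(dim(ns$p_values), c(2L, 3L))
  expect_true(all(ns$p_values >= 0 & ns$p_values <= 1))
  expect_true(ns$non_normal)
  expect_error(normality_screen(make_wt(matrix(rnorm(8), 4), c("a", "a", "b", "b"))),
               ">= 3")
})

test_that("Mann-Whitney post-hoc matches brute-force U counts", {
  wt <- make_wt(matrix(c(1, 2, 3, 4), 4, 1), c("x", "x", "y", "y"))
  ph <- posthoc_pairwise(wt, "e1")
  expect_equal(ph$U, oracle_u(c(1, 2), c(3, 4)))  # = 0
  expect_equal(ph$cliffs_delta, -1)
  set.seed(11)
  v <- rnorm(12)
  wt2 <- make_wt(matrix(rep(v, 2), 24, 1), rep(c("x", "y"), each = 12))
  ph2 <- posthoc_pairwise(wt2, "e1")
  expect_gt(ph2$p_raw, 0.9)  # identical groups: two-sided p near 1
  expect_identical(nrow(posthoc_pairwise(wt, character(0))), 0L)
})

test_that("omnibus pipeline: significance, effect sizes, post-hoc gating", {
  set.seed(13)
  n <- 30
  vals <- cbind(c(rnorm(n), rnorm(n), rnorm(n) + 3),  # strong group effect
                rnorm(3 * n), rnorm(3 * n))           # two null hyperedges
  groups <- rep(c("HC", "MCI", "AD"), each = n)
  st <- group_stats(make_wt(vals, groups))
  expect_true(st$omnibus$significant[1])
  expect_true(all(st$omnibus$p_fdr >= st$omnibus$p_raw))
  expect_true(all(st$omnibus$effect_size >= 0 & st$omnibus$effect_size <= 1))
  # post-hoc only for omnibus-significant hyperedges
  expect_true(all(st$pairwise$hyperedge_id %in%
                  st$omnibus$hyperedge_id[st$omnibus$significant]))
  expect_equal(sort(unique(st$pairwise$pair)),
               c("AD vs HC", "AD vs MCI", "HC vs MCI"))
})

test_that("planted one-sd shift is detected with high power", {
  set.seed(17)
  hits <- replicate(50, {
    n <- 80
    vals <- cbind(c(rnorm(n), rnorm(n), rnorm(n) - 1), rnorm(3 * n))
    st <- group_stats(make_wt(vals, rep(c("HC", "MCI", "AD"), each = n)))
    sig <- st$omnibus$significant[1]
    ph <- st$pairwise[st$pairwise$hyperedge_id == "e1" &
                      st$pairwise$pair == "AD vs HC", ]
    sig && nrow(ph) == 1 && ph$p_fdr < 0.05
  })
  expect_gte(mean(hits), 0.9)
})

test_that("two-group screening works through the same pipeline", {
  set.seed(19)
  vals <- matrix(rnorm(40 * 3), 40, 3)
  st <- group_stats(make_wt(vals, rep(c("HCh", "HCa"), each = 20)))
  expect_equal(nrow(st$omnibus), 3L)
  expect_true(all(st$omnibus$p_raw > 0 & st$omnibus$p_raw <= 1))
})
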