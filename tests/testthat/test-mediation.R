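test_that("worked 4-point design recovers the closed-form paths", {
  z <- c(0, 1, 2, 3); w <- c(1, 0, 3, 2); y <- z + 2 * w
  f <- fit_mediation(z, w, y)
  expect_equal(f$a, 0.6, tolerance = 1e-12)
  expect_equal(f$b, 2, tolerance = 1e-12)
  expect_equal(f$c_prime, 1, tolerance = 1e-12)
  expect_equal(f$c, 2.2, tolerance = 1e-12)
  expect_equal(f$indirect, 1.2, tolerance = 1e-12)
  expect_equal(f$total, f$direct + f$indirect, tolerance = 1e-10)
})

test_that("OLS decomposition total = direct + indirect holds generally", {
  for (s in 1:20) {
    set.seed(s)
    n <- 40
    z <- rnorm(n); w <- 0.5 * z + rnorm(n); y <- 0.3 * z + 0.7 * w + rnorm(n)
    f <- fit_mediation(z, w, y)
    expect_lt(abs(f$total - (f$direct + f$indirect)), 1e-10)
    cov <- data.frame(age = rnorm(n), sex = rbinom(n, 1, 0.5))
    fc <- fit_mediation(z, w, y, covariates = cov)
    expect_lt(abs(fc$total - (fc$direct + fc$indirect)), 1e-10)
  }
})

test_that("noise-free null mediator path gives exactly zero indirect effect", {
  z <- seq(-2, 2, length.out = 12)
  w <- c(1, 3, 2, 5, 4, 6, 5, 8, 7, 9, 8, 11)
  y <- 2 * z  # y depends on z only
  f <- fit_mediation(z, w, y)
  expect_equal(f$b, 0, tolerance = 1e-12)
  expect_equal(f$indirect, 0, tolerance = 1e-12)
})

test_that("a covariate orthogonal to z, w, y leaves the paths unchanged", {
  set.seed(5)
  n <- 50
  z <- rnorm(n); w <- 0.4 * z + rnorm(n); y <- 0.2 * z + 0.6 * w + rnorm(n)
  base <- cbind(1, z, w, y)
  raw <- rnorm(n)
  ortho <- raw - base %*% solve(crossprod(base), crossprod(base, raw))
  f0 <- fit_mediation(z, w, y)
  f1 <- fit_mediation(z, w, y, covariates = data.frame(o = ortho))
  expect_equal(f1$a, f0$a, tolerance = 1e-10)
  expect_equal(f1$b, f0$b, tolerance = 1e-10)
  expect_equal(f1$c, f0$c, tolerance = 1e-10)
  expect_equal(f1$c_prime, f0$c_prime, tolerance = 1e-10)
})

test_that("collinear designs raise an explicit error", {
  z <- rnorm(20)
  expect_error(fit_mediation(z, 2 * z, rnorm(20)), "collinear")
})

test_that("bootstrap is deterministic, bounded and floored", {
  sim <- simulate_mediation(80, seed = 11)
  b1 <- bootstrap_indirect(sim$z, sim$w, sim$y, n_boot = 500, seed = 3)
  b2 <- bootstrap_indirect(sim$z, sim$w, sim$y, n_boot = 500, seed = 3)
  expect_identical(b1$ci_indirect, b2$ci_indirect)
  expect_identical(b1$p_indirect, b2$p_indirect)
  expect_gte(b1$p_indirect, 1 / 500)
  expect_lte(b1$p_indirect, 1)
  expect_lt(b1$ci_indirect[1], b1$ci_indirect[2])
  expect_error(bootstrap_indirect(rnorm(5), rnorm(5), rnorm(5)), "n >= 10")
})

test_that("paths are recovered within 3 standard errors at n = 2000", {
  sim <- simulate_mediation(2000, a = 0.5, b = 0.4, c_prime = 0.3, seed = 21)
  f <- fit_mediation(sim$z, sim$w, sim$y)
  X2 <- cbind(1, sim$z); X3 <- cbind(1, sim$z, sim$w)
  se_a <- hyperfc:::ols_fit(X2, sim$w)$se[2]
  se_b <- hyperfc:::ols_fit(X3, sim$y)$se[3]
  se_cp <- hyperfc:::ols_fit(X3, sim$y)$se[2]
  expect_lt(abs(f$a - 0.5), 3 * se_a)
  expect_lt(abs(f$b - 0.4), 3 * se_b)
  expect_lt(abs(f$c_prime - 0.3), 3 * se_cp)
})

test_that("negative exposure path with positive mediator path yields a negative indirect effect", {
  sim <- simulate_mediation(500, a = -0.5, b = 0.6, c_prime = 0.2, seed = 23)
  f <- fit_mediation(sim$z, sim$w, sim$y, n_boot = 400, seed = 24)
  expect_lt(f$a, 0); expect_gt(f$b, 0)
  expect_lt(f$indirect, 0)
  expect_lt(f$ci_indirect[2], 0)  # interval excludes zero at this n
})

test_that("battery runs hyperedge x outcome combinations with exclusions", {
  set.seed(31)
  n <- 60
  z <- rnorm(n)
  vals <- cbind(0.8 * z + 0.3 * rnorm(n), rnorm(n))
  dimnames(vals) <- list(paste0("s", 1:n), c("e1", "e2"))
  wt <- hyperfc:::weight_table(vals, "algebraic", rep("HC", n))
  clinical <- data.frame(subject_id = paste0("s", 1:n), tau = z,
                         mem = -0.3 * z - 0.9 * vals[, 1] + rnorm(n, sd = 0.3),
                         adas = 0.5 * z + rnorm(n),
                         age = rnorm(n, 70, 5))
  clinical$mem[1] <- NA  # dropped with a message
  expect_message(
    mb <- run_mediation_battery(wt, c("e1", "e2"), clinical, z_var = "tau",
                                outcomes = c("mem", "adas"),
                                n_boot = 200, seed = 5),
    "dropped")
  expect_equal(nrow(mb), 4L)
  expect_equal(mb$n[mb$outcome == "mem"], rep(n - 1L, 2))
  # only the constructed mediator shows a non-null indirect path on "mem"
  r1 <- mb[mb$hyperedge_id == "e1" & mb$outcome == "mem", ]
  r2 <- mb[mb$hyperedge_id == "e2" & mb$outcome == "mem", ]
  expect_lt(r1$ci_hi, 0)
  expect_true(r2$ci_lo < 0 && r2$ci_hi > 0)
  mbc <- run_mediation_battery(wt, "e1", clinical, z_var = "tau",
                               outcomes = "adas", covariates = "age",
                               n_boot = 100, seed = 6)
  expect_equal(nrow(mbc), 1L)
  expect_error(run_mediation_battery(wt, "e9", clinical, "tau", "adas"),
               "unknown hyperedge")
})

test_that("planted mediator is flagged while null mediators are not, across seeds", {
  hit <- sapply(1:20, function(s) {
    sim <- simulate_mediation(500, a = 0.5, b = 0.4, c_prime = 0.3, seed = 100 + s)
    null_w <- rnorm(500)
    fA <- fit_mediation(sim$z, sim$w, sim$y, n_boot = 300, seed = s)
    fB <- fit_mediation(sim$z, null_w, sim$y, n_boot = 300, seed = s)
    a_sig <- fA$ci_indirect[1] > 0
    b_null <- fB$ci_indirect[1] < 0 && fB$ci_indirect[2] > 0
    a_sig && b_null
  })
  expect_gte(sum(hit), 18)
})
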