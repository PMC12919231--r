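# Brute-force / independent-path oracles used across the suite.

# white-noise panel
rand_panel <- function(N = 5, P = 40, seed = 1, id = "s1") {
  set.seed(seed)
  ts_panel(matrix(rnorm(N * P), N, P), paste0("R", seq_len(N)), id)
}

# random valid incidence structure: each hyperedge = centroid + extra members
rand_incidence <- function(N = 6, M = 3, seed = 1, k_extra = 2:3) {
  set.seed(seed)
  cent <- sample.int(N, M)
  E <- matrix(0, N, N)
  for (c in cent) {
    others <- sample(setdiff(seq_len(N), c), sample(k_extra, 1))
    E[c(c, others), c] <- 1
  }
  incidence_matrix(E[, cent, drop = FALSE], paste0("R", seq_len(N)), cent)
}

# explicit double-loop node degrees
oracle_node_degrees <- function(E, w) {
  d <- numeric(nrow(E))
  for (n in seq_len(nrow(E)))
    for (m in seq_len(ncol(E))) d[n] <- d[n] + w[m] * E[n, m]
  d
}

# explicit triple-loop similarity S[i,j] = sum_m w_m H_im H_jm / delta_m
oracle_similarity <- function(E, w) {
  N <- nrow(E); M <- ncol(E)
  deg <- colSums(E)
  S <- matrix(0, N, N)
  for (i in seq_len(N)) for (j in seq_len(N)) for (m in seq_len(M))
    S[i, j] <- S[i, j] + w[m] * E[i, m] * E[j, m] / deg[m]
  S
}

# Pearson correlation from the explicit covariance formula
oracle_pearson <- function(x, y) {
  n <- length(x)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  sxy / sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# Fiedler value through an independent decomposition path: Laplacian built by
# explicit loops from the adjacency, spectrum via SVD (equals the eigenvalues
# for a PSD matrix)
oracle_fiedler <- function(A, tol = 1e-10) {
  k <- nrow(A)
  L <- matrix(0, k, k)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) if (i != j) {
      L[i, j] <- -A[i, j]
      L[i, i] <- L[i, i] + A[i, j]
    }
  }
  ev <- sort(svd(L)$d)
  ev[ev < tol] <- 0
  ev[2L]
}

# random symmetric weighted graph adjacency with edge weights in [0, 1]
rand_graph <- function(k, seed) {
  set.seed(seed)
  A <- matrix(0, k, k)
  A[upper.tri(A)] <- runif(k * (k - 1) / 2)
  A + t(A)
}

# brute-force Cliff's delta
oracle_cliffs <- function(x, y) {
  gt <- 0; lt <- 0
  for (xi in x) for (yj in y) {
    if (xi > yj) gt <- gt + 1
    if (xi < yj) lt <- lt + 1
  }
  (gt - lt) / (length(x) * length(y))
}

# brute-force Mann-Whitney U for x (count of pairs x_i > y_j, ties 0.5)
oracle_u <- function(x, y) {
  u <- 0
  for (xi in x) for (yj in y) u <- u + (xi > yj) + 0.5 * (xi == yj)
  u
}

# Benjamini-Hochberg step-up from the textbook formula
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  sorted <- p[o] * m / seq_len(m)
  adj[o] <- rev(cummin(rev(sorted)))
  pmin(adj, 1)
}

# closed-form OLS on small designs for the mediation oracle
oracle_ols <- function(X, y) as.vector(solve(crossprod(X), crossprod(X, y)))

# panel with a latent factor shared by `members` at loading rho
factor_panel <- function(N, P, members, rho, seed, id = "s1") {
  set.seed(seed)
  X <- matrix(rnorm(N * P), N, P)
  f <- rnorm(P)
  for (i in members) X[i, ] <- rho * f + sqrt(1 - rho^2) * X[i, ]
  ts_panel(X, paste0("R", seq_len(N)), id)
}
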