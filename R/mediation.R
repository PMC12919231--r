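#' Three-equation mediation analysis
#'
#' Fits the classical mediation triple by ordinary least squares:
#' \deqn{y = i_1 + c z + e_1}
#' \deqn{w = i_2 + a z + e_2}
#' \deqn{y = i_3 + c' z + b w + e_3}
#' where `z` is the exposure (e.g. entorhinal tau SUVR), `w` the mediator
#' (a hyperedge weight), and `y` the outcome (a cognitive composite).
#' Covariates, when supplied, enter all three equations, which preserves the
#' OLS decomposition `total = direct + indirect`, i.e. `c = c' + a*b`.
#' Binary covariates (sex, APOE4 carriage) should be coded 0/1; continuous
#' covariates need no scaling (the path coefficients are invariant to it).
#'
#' @param z,w,y numeric vectors of equal length, no missing values.
#' @param covariates optional data.frame/matrix of per-subject covariates.
#' @param n_boot bootstrap repetitions for the indirect-effect interval
#'   (default 0 = no bootstrap); see [bootstrap_indirect()].
#' @param seed seed for the bootstrap.
#' @return an object of class `mediation_fit`: list with coefficients `a`,
#'   `b`, `c`, `c_prime`, intercepts `i1`, `i2`, `i3`, effects `total`,
#'   `direct`, `indirect`, t-test p-values `p_total`, `p_direct`, `p_a`,
#'   `p_b`, sample size `n`, and — when bootstrapped — `ci_indirect`,
#'   `p_indirect`, `n_boot`, `seed`.
#' @examples
#' f <- fit_mediation(z = c(0, 1, 2, 3), w = c(1, 0, 3, 2),
#'                    y = c(0, 1, 2, 3) + 2 * c(1, 0, 3, 2))
#' c(f$a, f$b, f$c_prime, f$c)
#' @export
fit_mediation <- function(z, w, y, covariates = NULL, n_boot = 0L, seed = 1L) {
  n <- length(z)
  if (length(w) != n || length(y) != n) stop("z, w, y must have equal length")
  if (anyNA(z) || anyNA(w) || anyNA(y)) stop("missing values; exclude those subjects upstream")
  C <- prepare_covariates(covariates, n)
  if (n <= ncol(C) + 3L) stop("too few subjects for the mediation design")
  X3 <- cbind(1, z, w, C)
  if (qr(X3)$rank < ncol(X3))
    stop("collinear mediation design (is w collinear with z or a covariate?)")
  f1 <- ols_fit(cbind(1, z, C), y)   # total
  f2 <- ols_fit(cbind(1, z, C), w)   # exposure -> mediator
  f3 <- ols_fit(X3, y)               # direct + mediator
  res <- list(a = f2$coef[2L], b = f3$coef[3L], c = f1$coef[2L],
              c_prime = f3$coef[2L],
              i1 = f1$coef[1L], i2 = f2$coef[1L], i3 = f3$coef[1L],
              total = f1$coef[2L], direct = f3$coef[2L],
              indirect = f2$coef[2L] * f3$coef[3L],
              p_total = f1$p[2L], p_direct = f3$p[2L],
              p_a = f2$p[2L], p_b = f3$p[3L], n = n)
  class(res) <- "mediation_fit"
  if (n_boot > 0L) {
    bs <- bootstrap_indirect(z, w, y, covariates, n_boot = n_boot, seed = seed)
    res[c("ci_indirect", "p_indirect", "n_boot", "seed")] <-
      list(bs$ci_indirect, bs$p_indirect, bs$n_boot, bs$seed)
  }
  res
}

prepare_covariates <- function(covariates, n) {
  if (is.null(covariates)) return(matrix(nrow = n, ncol = 0L))
  C <- as.matrix(as.data.frame(covariates))
  storage.mode(C) <- "double"
  if (nrow(C) != n) stop("covariates must have one row per subject")
  if (anyNA(C)) stop("missing covariate values")
  C
}

solve_chol <- function(X, y) {
  drop(chol2inv(chol(crossprod(X))) %*% crossprod(X, y))
}

ols_fit <- function(X, y) {
  fit <- stats::lm.fit(X, y)
  cf <- fit$coefficients
  dfres <- length(y) - fit$rank
  rss <- sum(fit$residuals^2)
  XtXinv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(diag(XtXinv) * rss / max(dfres, 1L))
  tval <- cf / se
  p <- 2 * stats::pt(abs(tval), dfres, lower.tail = FALSE)
  list(coef = unname(cf), se = unname(se), p = unname(p))
}

#' Bootstrap confidence interval for the indirect effect
#'
#' Nonparametric case resampling of subjects: for each of `n_boot` resamples
#' the paths `a` and `b` are re-estimated and the indirect effect `a*b`
#' recorded. The interval is the percentile [2.5%, 97.5%] interval; the
#' p-value is the two-sided sign-proportion rule
#' `2 * min(P(ab <= 0), P(ab >= 0))`, floored at `1/n_boot`. Rank-deficient
#' resamples are redrawn (aborting after `100 * n_boot` attempts).
#'
#' @inheritParams fit_mediation
#' @param n_boot bootstrap repetitions (default 1000).
#' @param seed integer seed; the same seed reproduces the interval exactly.
#' @return list with `ci_indirect`, `p_indirect`, `indirect_draws`, `n_boot`,
#'   `seed`, `n_redrawn`.
#' @export
bootstrap_indirect <- function(z, w, y, covariates = NULL, n_boot = 1000L,
                               seed = 1L) {
  n <- length(z)
  if (n < 10L) stop("bootstrap needs n >= 10")
  C <- prepare_covariates(covariates, n)
  X2 <- cbind(1, z, C)
  rng <- local_rng(seed)
  draws <- numeric(n_boot)
  redrawn <- 0L; attempts <- 0L; b <- 1L
  while (b <= n_boot) {
    attempts <- attempts + 1L
    if (attempts > 100L * n_boot) stop("too many rank-deficient bootstrap resamples")
    idx <- rng$resample_idx(n)
    X2b <- X2[idx, , drop = FALSE]
    X3b <- cbind(1, z[idx], w[idx], C[idx, , drop = FALSE])
    ab <- tryCatch({  # normal equations; chol() fails on a degenerate resample
      a_b <- solve_chol(X2b, w[idx])[2L]
      b_b <- solve_chol(X3b, y[idx])[3L]
      a_b * b_b
    }, error = function(e) NULL)
    if (is.null(ab)) { redrawn <- redrawn + 1L; next }
    draws[b] <- ab
    b <- b + 1L
  }
  ci <- unname(quantile(draws, c(0.025, 0.975), type = 7))
  p <- max(2 * min(mean(draws <= 0), mean(draws >= 0)), 1 / n_boot)
  p <- min(p, 1)
  list(ci_indirect = ci, p_indirect = p, indirect_draws = draws,
       n_boot = as.integer(n_boot), seed = as.integer(seed),
       n_redrawn = redrawn)
}

#' @export
print.mediation_fit <- function(x, ...) {
  cat(sprintf("Mediation fit (n = %d)\n", x$n))
  cat(sprintf("  paths: a = %.4g (p = %.3g), b = %.4g (p = %.3g)\n",
              x$a, x$p_a, x$b, x$p_b))
  cat(sprintf("  total  = %.4g (p = %.3g)\n  direct = %.4g (p = %.3g)\n  indirect = %.4g",
              x$total, x$p_total, x$direct, x$p_direct, x$indirect))
  if (!is.null(x$ci_indirect))
    cat(sprintf(" [%.4g, %.4g], p = %.3g (%d bootstrap draws)",
                x$ci_indirect[1L], x$ci_indirect[2L], x$p_indirect, x$n_boot))
  cat("\n")
  invisible(x)
}

#' @export
coef.mediation_fit <- function(object, ...) {
  c(a = object$a, b = object$b, c = object$c, c_prime = object$c_prime)
}

#' Mediation battery over significant hyperedges and outcomes
#'
#' Runs [fit_mediation()] (with bootstrap) for every combination of a
#' significant hyperedge's weights (the mediator) and an outcome column of
#' the clinical table, with the exposure column `z_var` and optional
#' covariates entering all three equations. Subjects are intersected between
#' the weight table and the clinical table; subjects missing the exposure or
#' an outcome are dropped (with a message reporting the count).
#'
#' @param wt a `weight_table` (hyperedge or functional-network weights).
#' @param significant_ids hyperedge ids to mediate through.
#' @param clinical data.frame with a `subject_id` column, the exposure,
#'   outcome and covariate columns.
#' @param z_var name of the exposure column (e.g. `"tau_suvr"`).
#' @param outcomes character vector of outcome column names.
#' @param covariates optional character vector of covariate column names.
#' @param n_boot bootstrap repetitions (default 1000).
#' @param seed integer seed.
#' @return an object of class `mediation_battery`: a data.frame with one row
#'   per (hyperedge, outcome) and the fits in attribute `"fits"`.
#' @export
run_mediation_battery <- function(wt, significant_ids, clinical, z_var,
                                  outcomes, covariates = NULL, n_boot = 1000L,
                                  seed = 1L) {
  stopifnot(inherits(wt, "weight_table"))
  if (!"subject_id" %in% colnames(clinical)) stop("clinical table needs subject_id")
  need <- c(z_var, outcomes, covariates)
  miss <- setdiff(need, colnames(clinical))
  if (length(miss)) stop("clinical table missing columns: ", paste(miss, collapse = ", "))
  common <- intersect(wt$subject_ids, clinical$subject_id)
  if (length(common) == 0L) stop("no subjects shared between weights and clinical table")
  cl <- clinical[match(common, clinical$subject_id), , drop = FALSE]
  cols <- match(significant_ids, wt$hyperedge_ids)
  if (anyNA(cols)) stop("unknown hyperedge id(s)")
  W <- wt$values[match(common, wt$subject_ids), cols, drop = FALSE]
  rows <- list(); fits <- list(); k <- 0L
  for (m in seq_along(significant_ids)) {
    for (oc in outcomes) {
      ok <- !is.na(cl[[z_var]]) & !is.na(cl[[oc]])
      ndrop <- sum(!ok)
      if (ndrop > 0L)
        message(ndrop, " subject(s) dropped for missing ", z_var, " or ", oc)
      cov_df <- if (is.null(covariates)) NULL else cl[ok, covariates, drop = FALSE]
      fit <- fit_mediation(cl[[z_var]][ok], W[ok, m], cl[[oc]][ok],
                           covariates = cov_df, n_boot = n_boot, seed = seed)
      k <- k + 1L
      fits[[k]] <- fit
      rows[[k]] <- data.frame(
        hyperedge_id = significant_ids[m], outcome = oc, n = fit$n,
        a = fit$a, b = fit$b, total = fit$total, direct = fit$direct,
        indirect = fit$indirect,
        ci_lo = fit$ci_indirect[1L], ci_hi = fit$ci_indirect[2L],
        p_indirect = fit$p_indirect, p_total = fit$p_total,
        p_direct = fit$p_direct, row.names = NULL)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "fits") <- fits
  class(out) <- c("mediation_battery", "data.frame")
  out
}

#' @export
print.mediation_battery <- function(x, ...) {
  cat(sprintf("Mediation battery: %d (hyperedge x outcome) fits\n", nrow(x)))
  df <- as.data.frame(x)
  df[] <- lapply(df, function(v) if (is.numeric(v)) signif(v, 3) else v)
  print(df, row.names = FALSE)
  invisible(x)
}
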