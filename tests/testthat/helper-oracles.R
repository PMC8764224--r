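# Independent oracles used across the suite. These deliberately avoid the
# package's own computational paths: explicit dense-matrix GLS for the mixed
# model, eigendecomposition for PCA, and a literal step-up definition for BH.

# Brute-force REML for the random-intercept model: builds V = I + lambda ZZ'
# densely and grid-searches lambda (with successive zooming) on the REML
# criterion. Returns beta, sigma2_resid, sigma2_subject at the optimum.
gls_reml_oracle <- function(y, samples, covariate = NULL,
                            lambda_hi = 50, levels_grid = 6L, grid_n = 60L) {
  d <- data.frame(subject_id = samples$subject_id,
                  group = factor(samples$group,
                                 levels = c("SAL", "GOP", "VLCD", "RYGB")),
                  week4 = as.numeric(samples$timepoint == "week4"))
  d$group <- droplevels(d$group)
  X <- stats::model.matrix(~ week4 * group, data = d)
  if (!is.null(covariate)) {
    for (lev in levels(d$group)) {
      col <- d$week4 * (d$group == lev) * covariate
      if (qr(cbind(X, col))$rank > qr(X)$rank) X <- cbind(X, col)
    }
  }
  Z <- stats::model.matrix(~ 0 + factor(subject_id), data = d)
  n <- length(y); p <- ncol(X)

  crit <- function(lambda) {
    V <- diag(n) + lambda * tcrossprod(Z)
    Vi <- solve(V)
    XtViX <- t(X) %*% Vi %*% X
    beta <- solve(XtViX, t(X) %*% Vi %*% y)
    r <- y - X %*% beta
    sigma2 <- drop(t(r) %*% Vi %*% r) / (n - p)
    (n - p) * log(sigma2) +
      determinant(V, logarithm = TRUE)$modulus +
      determinant(XtViX, logarithm = TRUE)$modulus
  }
  lo <- 0; hi <- lambda_hi
  for (lvl in seq_len(levels_grid)) {
    grid <- seq(lo, hi, length.out = grid_n)
    vals <- vapply(grid, crit, 0)
    i <- which.min(vals)
    lo <- grid[max(1L, i - 1L)]
    hi <- grid[min(grid_n, i + 1L)]
  }
  lambda <- (lo + hi) / 2
  V <- diag(n) + lambda * tcrossprod(Z)
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  beta <- drop(solve(XtViX, t(X) %*% Vi %*% y))
  r <- y - X %*% beta
  sigma2 <- drop(t(r) %*% Vi %*% r) / (n - p)
  list(lambda = lambda, beta = beta, sigma2_resid = sigma2,
       sigma2_subject = lambda * sigma2,
       vcov_beta = sigma2 * solve(XtViX))
}

# Literal Benjamini-Hochberg step-up definition: q_(i) = min_{j >= i} p_(j) m / j
bh_stepup_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(1, min(ps[i:m] * m / (i:m)))
  }
  out <- numeric(m)
  out[o] <- q
  out
}

# Small complete balanced study for quick fits
tiny_sim <- function(n_per_group = c(SAL = 4L, GOP = 4L, VLCD = 5L, RYGB = 5L),
                     n_features = 4L, seed = 1L, ...) {
  simulate_study(n_per_group = n_per_group, n_features = n_features,
                 seed = seed, ...)
}
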