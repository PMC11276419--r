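# Independent oracles: deliberately naive implementations used only to
# check the package's vectorized/closed-form paths.

# Gaussian log-likelihood as a literal sum of per-observation log densities.
oracle_loglik <- function(y, mu, sigma2) {
  sum(stats::dnorm(y, mean = mu, sd = sqrt(sigma2), log = TRUE))
}

# Least squares by explicitly solving the normal equations.
oracle_normal_equations <- function(Z, y) {
  unname(drop(solve(crossprod(Z), crossprod(Z, y))))
}

# Smoothed standard errors as a literal double loop over rows and
# replicates: covhat_ij = sum_b (Y_bi - Ybar_i)(beta_j(b) - betabar_j)/B.
oracle_smoothed_sd <- function(counts, betas) {
  B <- nrow(counts)
  n <- ncol(counts)
  p <- ncol(betas)
  ybar <- colMeans(counts)
  bbar <- colMeans(betas)
  sdt <- numeric(p)
  for (j in seq_len(p)) {
    acc <- 0
    for (i in seq_len(n)) {
      cov_ij <- 0
      for (b in seq_len(B)) {
        cov_ij <- cov_ij + (counts[b, i] - ybar[i]) * (betas[b, j] - bbar[j])
      }
      acc <- acc + (cov_ij / B)^2
    }
    sdt[j] <- sqrt(acc)
  }
  sdt
}

# Argmin with the parsimony-then-order tie-break, written as a plain scan.
oracle_select <- function(aics, ks) {
  best <- 1L
  for (i in seq_along(aics)[-1]) {
    if (aics[i] < aics[best] ||
        (aics[i] == aics[best] && ks[i] < ks[best])) {
      best <- i
    }
  }
  best
}

# Random regression fixture.
make_dataset <- function(n, p, seed) {
  set.seed(seed)
  X <- matrix(stats::rnorm(n * p), n, p)
  y <- 1 + drop(X %*% seq_len(p)) + stats::rnorm(n)
  bmf_data(y, X, paste0("x", seq_len(p)))
}

# Manually assembled replicate for smoothing hand-cases.
make_replicate <- function(counts, beta_star) {
  structure(list(indices = NULL, counts = counts, aics_star = NULL,
                 adjusted = TRUE, selected = 1L, beta_star = beta_star),
            class = "bootstrap_replicate")
}
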