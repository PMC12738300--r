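# Independent oracles and tiny fixture builders shared across tests.

# Brute-force GNB posterior: scalar loops over observations, classes, and
# features using dnorm. Deliberately naive -- stays independent of the
# vectorized implementation it checks.
oracle_gnb_posterior <- function(x, priors, means, variances, subset) {
  n <- nrow(x)
  K <- length(priors)
  post <- matrix(NA_real_, n, K)
  for (i in seq_len(n)) {
    logp <- numeric(K)
    for (k in seq_len(K)) {
      s <- log(priors[k])
      for (jj in seq_along(subset)) {
        s <- s + dnorm(x[i, subset[jj]], means[k, jj],
                       sqrt(variances[k, jj]), log = TRUE)
      }
      logp[k] <- s
    }
    w <- exp(logp - max(logp))
    post[i, ] <- w / sum(w)
  }
  post
}

oracle_gnb_log_scores <- function(x, priors, means, variances, subset) {
  n <- nrow(x)
  K <- length(priors)
  s <- matrix(NA_real_, n, K)
  for (i in seq_len(n)) {
    for (k in seq_len(K)) {
      acc <- log(priors[k])
      for (jj in seq_along(subset)) {
        acc <- acc + dnorm(x[i, subset[jj]], means[k, jj],
                           sqrt(variances[k, jj]), log = TRUE)
      }
      s[i, k] <- acc
    }
  }
  s
}

# Two blob classes in p dimensions, deterministic given seed.
make_toy_dataset <- function(n = 60, p = 4, K = 2, sep = 3, seed = 42) {
  set.seed(seed)
  y <- rep(seq_len(K), length.out = n)
  x <- matrix(rnorm(n * p), n, p) + (y - 1) * sep
  labeled_dataset(x, letters[y])
}

mahalanobis_dist <- function(mu1, mu2, sigma) {
  d <- mu1 - mu2
  sqrt(drop(t(d) %*% solve(sigma, d)))
}
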