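# Synthetic class-conditional Gaussian data with controlled overlap.
# All classes share one equicorrelation covariance Sigma = (1-rho) I + rho 11';
# class separation is set by the spacing d between successive class means.

#' Equicorrelation covariance matrix
#'
#' Builds `Sigma = (1 - rho) I_p + rho 1 1'`: unit variances, all pairwise
#' correlations equal to `rho`. Eigenvalues are `1 + rho (p - 1)` (once, along
#' the ones vector) and `1 - rho` (p - 1 times), so the matrix is positive
#' definite for `rho` in \[0, 1).
#'
#' @param p dimension.
#' @param rho common correlation in \[0, 1).
#' @return p x p covariance matrix.
#' @export
equicorrelation_cov <- function(p, rho) {
  stopifnot(p >= 1)
  if (!is.numeric(rho) || length(rho) != 1L || rho < 0 || rho >= 1) {
    stop("'rho' must be a single value in [0, 1)")
  }
  s <- matrix(rho, p, p)
  diag(s) <- 1
  s
}

# Rowwise multiplication by Sigma^{1/2} in closed form, O(n p): on span(1)
# the square root scales by sqrt(1 + rho(p-1)), orthogonally by sqrt(1 - rho).
.equicorr_sqrt_mult <- function(z, rho) {
  p <- ncol(z)
  s1 <- sqrt(1 + rho * (p - 1))
  s2 <- sqrt(1 - rho)
  if (rho == 0) return(z)
  z * s2 + ((s1 - s2) / p) * rowSums(z)
}

#' Class means on a regular simplex in the Mahalanobis metric
#'
#' Places K class means so that *every* pairwise Mahalanobis distance
#' `sqrt((mu_i - mu_j)' Sigma^{-1} (mu_i - mu_j))` equals `d` under the
#' equicorrelation covariance: K regular-simplex vertices are built in R^p,
#' scaled to pairwise Euclidean distance `d`, and mapped through
#' `Sigma^{1/2}`. Requires `K <= p + 1` (a regular simplex with K vertices
#' needs K - 1 dimensions).
#'
#' @param K number of classes (>= 2).
#' @param p dimension.
#' @param d target pairwise Mahalanobis distance (>= 0).
#' @param rho equicorrelation parameter of the covariance, in \[0, 1).
#' @return K x p matrix of class means.
#' @export
simplex_class_means <- function(K, p, d, rho = 0) {
  stopifnot(K >= 2, d >= 0, rho >= 0, rho < 1)
  if (K > p + 1) stop("K = ", K, " simplex vertices need p >= K - 1 = ",
                      K - 1, " dimensions (got p = ", p, ")")
  centered <- diag(K) - matrix(1 / K, K, K)   # rows: simplex, distance sqrt(2)
  sv <- svd(centered, nu = K, nv = 0)
  coords <- sv$u[, seq_len(K - 1), drop = FALSE] %*%
    diag(sv$d[seq_len(K - 1)], K - 1)
  coords <- coords * (d / sqrt(2))
  v <- matrix(0, K, p)
  v[, seq_len(K - 1)] <- coords
  .equicorr_sqrt_mult(v, rho)
}

#' Collinear class means with a fixed per-feature spacing
#'
#' Places the K class means on a line along the ones direction: class k
#' (k = 0, ..., K-1) has mean `k * d` in every coordinate. This is the
#' benchmark placement used by all simulation scenarios: successive classes
#' are offset by `d` per feature, giving an effective Gaussian-discriminant
#' separation of `d * sqrt(p / (1 + rho (p - 1)))` (approximately `d / sqrt(rho)`
#' for large p) between adjacent classes.
#'
#' @inheritParams simplex_class_means
#' @return K x p matrix of class means.
#' @export
shift_class_means <- function(K, p, d) {
  stopifnot(K >= 2, p >= 1, d >= 0)
  matrix(rep((seq_len(K) - 1) * d, p), K, p)
}

#' Synthetic-scenario specification
#'
#' A recipe for one class-conditional Gaussian dataset: sample count, feature
#' count, class count, mean spacing `d`, equicorrelation `rho`, class balance,
#' mean placement, and seed. [generate_dataset()] consumes it.
#'
#' @param n number of observations.
#' @param p number of features.
#' @param K number of classes.
#' @param d mean spacing (per-feature offset between successive classes for
#'   `mean_structure = "shift"`; pairwise Mahalanobis distance for
#'   `"simplex"`).
#' @param rho equicorrelation in \[0, 1); the same covariance is shared by all
#'   classes.
#' @param seed integer seed stored with the recipe.
#' @param class_balance probability vector of length K (default uniform).
#' @param mean_structure `"shift"` (collinear, the benchmark default) or
#'   `"simplex"` (all pairwise Mahalanobis distances equal to `d`).
#' @return Object of class `scenario_spec`.
#' @seealso [preset_scenario()] for the named overlap levels.
#' @export
scenario_spec <- function(n, p, K = 3L, d, rho, seed = 1L,
                          class_balance = NULL,
                          mean_structure = c("shift", "simplex")) {
  mean_structure <- match.arg(mean_structure)
  stopifnot(n >= 1, p >= 1, K >= 2, d >= 0, rho >= 0, rho < 1)
  if (mean_structure == "simplex" && K > p + 1) {
    stop("simplex placement needs K <= p + 1")
  }
  if (is.null(class_balance)) class_balance <- rep(1 / K, K)
  stopifnot(length(class_balance) == K, all(class_balance > 0))
  class_balance <- class_balance / sum(class_balance)
  structure(list(n = as.integer(n), p = as.integer(p), K = as.integer(K),
                 d = d, rho = rho, seed = as.integer(seed),
                 class_balance = class_balance,
                 mean_structure = mean_structure),
            class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat("Scenario: n = ", x$n, ", p = ", x$p, ", K = ", x$K,
      ", d = ", x$d, ", rho = ", x$rho, " (", x$mean_structure,
      " means), seed = ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Named class-overlap presets
#'
#' Maps an overlap level to its (d, rho) pair: `"none"` (5, 0; identity
#' covariance), `"low"` (3.5, 0.1), `"moderate"` (2, 0.5), `"high"` (1, 0.9).
#'
#' @param level one of `"none"`, `"low"`, `"moderate"`, `"high"`.
#' @inheritParams scenario_spec
#' @param ... passed on to [scenario_spec()].
#' @return Object of class `scenario_spec`.
#' @examples
#' preset_scenario("moderate", n = 1000, p = 50)
#' @export
preset_scenario <- function(level = c("none", "low", "moderate", "high"),
                            n, p, K = 3L, seed = 1L, ...) {
  level <- match.arg(level)
  pars <- switch(level,
                 none     = c(d = 5,   rho = 0),
                 low      = c(d = 3.5, rho = 0.1),
                 moderate = c(d = 2,   rho = 0.5),
                 high     = c(d = 1,   rho = 0.9))
  scenario_spec(n = n, p = p, K = K, d = pars[["d"]], rho = pars[["rho"]],
                seed = seed, ...)
}

#' Generate a dataset from a scenario
#'
#' Draws labels from the scenario's class balance and features from the
#' class-conditional multivariate normal `N(mu_k, Sigma)` with the shared
#' equicorrelation covariance; the `Sigma^{1/2}` transform is applied in
#' closed form (O(n p), no p x p factorization). Reproducible for a fixed
#' seed. Class labels are the characters `"0" ... "K-1"` with that fixed
#' vocabulary order.
#'
#' @param spec a [scenario_spec()].
#' @param seed optional seed overriding `spec$seed`.
#' @return A [labeled_dataset()].
#' @export
generate_dataset <- function(spec, seed = NULL) {
  if (!inherits(spec, "scenario_spec")) stop("expected a 'scenario_spec'")
  set.seed(if (is.null(seed)) spec$seed else as.integer(seed))
  y_int <- sample.int(spec$K, spec$n, replace = TRUE,
                      prob = spec$class_balance)
  x <- .equicorr_sqrt_mult(matrix(rnorm(spec$n * spec$p), spec$n, spec$p),
                           spec$rho)
  means <- switch(spec$mean_structure,
                  shift = shift_class_means(spec$K, spec$p, spec$d),
                  simplex = simplex_class_means(spec$K, spec$p, spec$d,
                                                spec$rho))
  x <- x + means[y_int, , drop = FALSE]
  colnames(x) <- paste0("V", seq_len(spec$p))
  labeled_dataset(x, as.character(y_int - 1L),
                  classes = as.character(seq_len(spec$K) - 1L))
}

# Held-out evaluation protocol shared by benchmarks: an independent test set
# of max(2000, n/5) draws from the same scenario (scaled along with n).
.test_size <- function(n, scale = 1) {
  max(ceiling(2000 * min(scale, 1)), ceiling(n / 5), 50L)
}
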