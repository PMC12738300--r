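# Variance and margin-bound calculators for the averaged posterior, plus
# Monte-Carlo harnesses that verify them by simulation.

#' Variance of an average of equicorrelated ensemble members
#'
#' For T members with common marginal variance `sigma2` and common pairwise
#' correlation `rho`, the variance of the member average is
#' `sigma2 * (1 + rho * (T - 1)) / T`. At `rho = 0` this is the pure
#' `sigma2 / T` reduction; at `rho = 1` averaging achieves nothing; as
#' `T -> Inf` it tends to the irreducible correlated component `rho * sigma2`.
#'
#' @param sigma2 per-member variance (>= 0).
#' @param rho common pairwise correlation, in `[-1/(T-1), 1]`.
#' @param n_members ensemble size T (>= 1).
#' @return Variance of the ensemble average.
#' @examples
#' ensemble_posterior_variance(0.01, rho = 0.5, n_members = 10)  # 0.0055
#' @export
ensemble_posterior_variance <- function(sigma2, rho, n_members) {
  n_members <- as.integer(n_members)
  stopifnot(length(n_members) == 1L, n_members >= 1L)
  if (any(sigma2 < 0)) stop("'sigma2' must be non-negative")
  lo <- if (n_members > 1L) -1 / (n_members - 1) else -1
  if (any(rho < lo - 1e-12) || any(rho > 1 + 1e-12)) {
    stop("'rho' must lie in [", signif(lo, 4), ", 1] for T = ", n_members)
  }
  sigma2 * (1 + rho * (n_members - 1)) / n_members
}

#' Margin-based bound on the ensemble misclassification probability
#'
#' At a point with Bayes margin `gamma` (true-class posterior minus the best
#' competing posterior, > 0) and member bias `bias` on the true-class
#' posterior, the probability that the posterior-averaging ensemble
#' misclassifies is at most
#' `ensemble_posterior_variance(sigma2, rho, T) / (gamma/2 - |bias|)_+^2`.
#' When `|bias| >= gamma / 2` the denominator collapses and the bound is
#' reported as `Inf` (unbounded).
#'
#' @param gamma Bayes margin (> 0).
#' @param bias member bias of the true-class posterior.
#' @inheritParams ensemble_posterior_variance
#' @return The bound, or `Inf` when uninformative. Vectorized over
#'   `gamma`/`bias`/`sigma2`/`rho`.
#' @examples
#' margin_error_bound(gamma = 0.4, bias = 0, sigma2 = 0.01, rho = 0,
#'                    n_members = 100)  # 0.0025
#' @export
margin_error_bound <- function(gamma, bias = 0, sigma2, rho, n_members) {
  if (any(gamma <= 0)) stop("'gamma' must be positive (margin assumption)")
  v <- ensemble_posterior_variance(sigma2, rho, n_members)
  denom <- pmax(gamma / 2 - abs(bias), 0)
  ifelse(denom > 0, v / denom^2, Inf)
}

#' Monte-Carlo variance of an equicorrelated member average
#'
#' Draws `n_draws` vectors of T equicorrelated Gaussians via the single
#' common-factor construction `sqrt(rho) Z0 + sqrt(1 - rho) Z_t`, scaled to
#' marginal variance `sigma2`, and returns the sample variance of the
#' per-draw mean — an independent simulation check of
#' [ensemble_posterior_variance()].
#'
#' @inheritParams ensemble_posterior_variance
#' @param rho common correlation in \[0, 1\] (the common-factor construction
#'   needs non-negative correlation).
#' @param n_draws number of Monte-Carlo draws (>= 1000).
#' @param seed optional integer seed.
#' @return Sample variance of the member average across draws.
#' @export
simulate_equicorrelated_members <- function(sigma2, rho, n_members, n_draws,
                                            seed = NULL) {
  stopifnot(sigma2 >= 0, rho >= 0, rho <= 1, n_members >= 1,
            n_draws >= 1000)
  if (!is.null(seed)) set.seed(as.integer(seed))
  z0 <- rnorm(n_draws)
  z <- matrix(rnorm(n_draws * n_members), n_draws, n_members)
  members <- sqrt(sigma2) * (sqrt(rho) * z0 + sqrt(1 - rho) * z)
  stats::var(rowMeans(members))
}

#' Empirical check of the margin bound on a synthetic scenario
#'
#' Fits `replicates` independent ensembles on fresh training draws from a
#' scenario, then at each of `n_eval` evaluation points estimates the member
#' moments that enter [margin_error_bound()] and compares the bound with the
#' observed misclassification rate across fits.
#'
#' Per evaluation point x with true class Y:
#' \itemize{
#'   \item `gamma` and the true posterior come from the known generative
#'     model (shared covariance, closed-form Mahalanobis discriminants);
#'   \item `sigma2` is the variance of the member posteriors `P_t(Y | x)`
#'     pooled over all fits and members; `bias` is their mean minus the true
#'     posterior;
#'   \item `rho` is the average pairwise Pearson correlation between member
#'     slots, computed across replicate fits (the true-class reading of the
#'     bias/variance assumptions); near-degenerate members (`sigma2` ~ 0)
#'     get `rho = 0`;
#'   \item `empirical_error` is the fraction of fits whose ensemble
#'     prediction at x differs from Y.
#' }
#' A point is *evaluable* when `gamma / 2 - |bias| > 0` (finite bound).
#'
#' @param spec a [scenario_spec()]; the generative model must be the one the
#'   bound is stated for (shared equicorrelation covariance).
#' @param n_iter,feature_fraction ensemble configuration per fit.
#' @param replicates number of independent ensemble fits (>= 3).
#' @param n_eval number of evaluation points drawn from the scenario.
#' @param seed integer seed for evaluation draw, training draws, and fits.
#' @return A list of class `pavgnb_bound_check`: `points` (one row per
#'   evaluation point with `gamma`, `bias`, `sigma2`, `rho`, `bound`,
#'   `empirical_error`, `evaluable`), `prop_bound_holds` (fraction of
#'   evaluable points with `empirical_error <= bound`), `n_evaluable`, and
#'   `mean_bound` (mean finite bound).
#' @export
empirical_bound_check <- function(spec, n_iter = 100L, feature_fraction = 0.25,
                                  replicates = 20L, n_eval = 100L,
                                  seed = 1L) {
  if (!inherits(spec, "scenario_spec")) stop("expected a 'scenario_spec'")
  replicates <- as.integer(replicates)
  stopifnot(replicates >= 3L, n_eval >= 1L)
  set.seed(as.integer(seed))
  seeds <- matrix(sample.int(2147483646L, 2L * replicates + 1L),
                  ncol = 1L)
  eval_set <- generate_dataset(spec, seed = seeds[1L])
  keep <- seq_len(min(n_eval, nrow(eval_set$x)))
  xe <- eval_set$x[keep, , drop = FALSE]
  ye <- match(eval_set$y[keep], eval_set$classes)

  truth <- .true_posterior(xe, spec)
  p_true <- truth[cbind(seq_along(ye), ye)]
  gamma <- p_true - apply(truth * (col(truth) != ye), 1L, max)

  n_pts <- length(ye)
  member_true <- array(NA_real_, c(replicates, n_iter, n_pts))
  miss <- matrix(NA, replicates, n_pts)
  for (r in seq_len(replicates)) {
    train <- generate_dataset(spec, seed = seeds[2L * r])
    fit <- pav_gnb(train, n_iter = n_iter,
                   feature_fraction = feature_fraction,
                   seed = seeds[2L * r + 1L])
    mem <- .member_posteriors(fit, xe)            # n x K x T
    for (i in seq_len(n_pts)) member_true[r, , i] <- mem[i, ye[i], ]
    avg <- apply(mem, c(1L, 2L), mean)
    miss[r, ] <- max.col(avg, ties.method = "first") != ye
  }

  sigma2 <- bias <- rho <- numeric(n_pts)
  for (i in seq_len(n_pts)) {
    m <- member_true[, , i]                       # replicates x T
    sigma2[i] <- stats::var(as.vector(m))
    bias[i] <- mean(m) - p_true[i]
    if (sigma2[i] > 1e-12 && replicates >= 3L) {
      cm <- suppressWarnings(stats::cor(m))
      off <- cm[upper.tri(cm)]
      rho[i] <- mean(off[is.finite(off)])
      if (!is.finite(rho[i])) rho[i] <- 0
    } else {
      rho[i] <- 0
    }
  }
  lo <- if (n_iter > 1L) -1 / (n_iter - 1) else -1
  rho <- pmin(pmax(rho, lo), 1)

  denom <- pmax(gamma / 2 - abs(bias), 0)
  bound <- ifelse(denom > 0,
                  ensemble_posterior_variance(sigma2, rho, n_iter) / denom^2,
                  Inf)
  emp <- colMeans(miss)
  pts <- data.frame(gamma = gamma, bias = bias, sigma2 = sigma2, rho = rho,
                    bound = bound, empirical_error = emp,
                    evaluable = denom > 0)
  evaluable <- pts$evaluable
  structure(list(points = pts,
                 prop_bound_holds = mean(emp[evaluable] <=
                                           bound[evaluable] + 1e-12),
                 n_evaluable = sum(evaluable),
                 mean_bound = mean(pmin(bound[evaluable], 1))),
            class = "pavgnb_bound_check")
}

#' @export
print.pavgnb_bound_check <- function(x, ...) {
  cat("Margin-bound check: ", x$n_evaluable, " evaluable points; bound holds",
      " at ", round(100 * x$prop_bound_holds, 1), "% of them\n", sep = "")
  cat("mean capped bound: ", signif(x$mean_bound, 4), "\n", sep = "")
  invisible(x)
}

# Exact class posteriors of the generative scenario model: shared
# equicorrelation covariance, so log-densities differ only through
# Mahalanobis terms, computed with the closed-form inverse
# Sigma^{-1} = a I + b 11', a = 1/(1-rho), b = -rho/((1-rho)(1+rho(p-1))).
.true_posterior <- function(x, spec) {
  means <- switch(spec$mean_structure,
                  shift = shift_class_means(spec$K, spec$p, spec$d),
                  simplex = simplex_class_means(spec$K, spec$p, spec$d,
                                                spec$rho))
  a <- 1 / (1 - spec$rho)
  b <- -spec$rho / ((1 - spec$rho) * (1 + spec$rho * (spec$p - 1)))
  scores <- matrix(NA_real_, nrow(x), spec$K)
  for (k in seq_len(spec$K)) {
    dx <- sweep(x, 2L, means[k, ], "-")
    maha2 <- a * rowSums(dx * dx) + b * rowSums(dx)^2
    scores[, k] <- log(spec$class_balance[k]) - 0.5 * maha2
  }
  normalize_log_posteriors(scores)
}
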