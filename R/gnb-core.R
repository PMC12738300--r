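# Core estimator: stratified bootstrap x random feature subspace x
# Gaussian naive Bayes, aggregated by averaging normalized posteriors.

#' Class-stratified bootstrap indices
#'
#' Resamples row indices with replacement *within* each class, so the
#' per-class counts of the resample equal the original per-class counts
#' exactly (class proportions are preserved, not merely in expectation).
#' Indices are returned grouped by class in vocabulary order. Uses the
#' current RNG state.
#'
#' @param labels vector of class labels.
#' @param classes ordered class vocabulary; defaults to first-appearance
#'   order. An entry with no members is an error (degenerate stratification).
#' @return Integer vector of `length(labels)` row indices.
#' @examples
#' set.seed(1)
#' idx <- stratified_bootstrap(c("a", "a", "a", "b", "b"))
#' table(c("a", "a", "a", "b", "b")[idx])
#' @export
stratified_bootstrap <- function(labels, classes = unique(as.character(labels))) {
  labels <- as.character(labels)
  counts <- table(factor(labels, levels = classes))
  if (any(counts == 0L)) {
    stop("degenerate stratification: class '",
         names(counts)[which(counts == 0L)[1L]], "' has no members")
  }
  idx <- unlist(lapply(classes, function(cl) {
    members <- which(labels == cl)
    members[sample.int(length(members), length(members), replace = TRUE)]
  }), use.names = FALSE)
  as.integer(idx)
}

#' Uniform random feature subset
#'
#' Draws `m = min(max(floor(feature_fraction * p), 1), p)` distinct column
#' indices uniformly without replacement; the floor is clamped so at least
#' one feature is always selected. Uses the current RNG state.
#'
#' @param p number of available features.
#' @param feature_fraction fraction in (0, 1] of features per subset.
#' @return Sorted integer vector of m distinct indices in 1..p.
#' @export
sample_feature_subset <- function(p, feature_fraction) {
  stopifnot(length(p) == 1L, p >= 1)
  if (!is.numeric(feature_fraction) || length(feature_fraction) != 1L ||
      feature_fraction <= 0 || feature_fraction > 1) {
    stop("'feature_fraction' must be a single value in (0, 1]")
  }
  m <- .subset_size(p, feature_fraction)
  sort(sample.int(p, m))
}

.subset_size <- function(p, feature_fraction) {
  min(max(as.integer(floor(feature_fraction * p)), 1L), as.integer(p))
}

# Per-class Gaussian parameters on an already-resampled (x, y_int) block.
# Means are sample means; variances use the unbiased n_k - 1 denominator and
# are floored at `variance_floor`. A singleton class falls back to the pooled
# within-class variance (with a warning); an absent class is an error.
.fit_gnb_params <- function(xm, y_int, K, variance_floor) {
  counts <- tabulate(y_int, nbins = K)
  if (any(counts == 0L)) {
    stop("class ", which(counts == 0L)[1L], " has no members in this sample")
  }
  sums <- rowsum(xm, y_int)
  means <- sums / counts
  ssq <- rowsum(xm * xm, y_int)
  vars <- (ssq - counts * means^2) / (counts - 1L)
  if (any(counts == 1L)) {
    ok <- counts > 1L
    if (!any(ok)) stop("all classes are singletons; variances undefined")
    pooled <- colSums((counts[ok] - 1L) * vars[ok, , drop = FALSE]) /
      (sum(counts[ok]) - sum(ok))
    for (k in which(counts == 1L)) vars[k, ] <- pooled
    warning("singleton class (", paste(which(counts == 1L), collapse = ", "),
            "): variance replaced by pooled within-class variance")
  }
  vars <- pmax(vars, variance_floor)
  dimnames(means) <- dimnames(vars) <- NULL  # plain arrays: exact JSON round-trip
  list(priors = counts / sum(counts), means = means, variances = vars)
}

#' Fit a single Gaussian naive Bayes base learner
#'
#' Estimates per-class priors (class counts over n of the dataset passed in),
#' per-(class, feature) sample means, and unbiased (n_k - 1 denominator)
#' sample variances on the given feature subset. Variances are floored at
#' `variance_floor` so constant features keep log-densities finite. The
#' dataset is used as given; resampling, if any, happens upstream.
#'
#' @param dataset a [labeled_dataset()] (typically a bootstrap resample).
#' @param feature_subset integer vector of distinct column indices.
#' @param variance_floor small positive variance lower bound; default
#'   `1e-9 * (mean feature variance + 1)` computed from `dataset`.
#' @return A `pav_gnb_learner`: list with `priors` (length-K), `means` and
#'   `variances` (K x m matrices), `feature_subset`, `p`, `classes`, and
#'   `iteration_index` (NA when fitted standalone).
#' @export
fit_base_gnb <- function(dataset, feature_subset = seq_len(ncol(dataset$x)),
                         variance_floor = NULL) {
  dataset <- .check_dataset(dataset)
  p <- ncol(dataset$x)
  feature_subset <- as.integer(feature_subset)
  if (anyDuplicated(feature_subset) || any(feature_subset < 1L) ||
      any(feature_subset > p)) {
    stop("'feature_subset' must be distinct indices in 1..", p)
  }
  if (is.null(variance_floor)) {
    variance_floor <- .default_variance_floor(dataset$x)
  }
  y_int <- match(dataset$y, dataset$classes)
  params <- .fit_gnb_params(dataset$x[, feature_subset, drop = FALSE],
                            y_int, length(dataset$classes), variance_floor)
  structure(c(params, list(feature_subset = feature_subset, p = p,
                           classes = dataset$classes,
                           iteration_index = NA_integer_)),
            class = "pav_gnb_learner")
}

.default_variance_floor <- function(x) {
  # global feature variance = mean of per-feature variances, one pass
  n <- nrow(x)
  mu <- colMeans(x)
  gv <- mean((colSums(x * x) - n * mu^2) / (n - 1L))
  1e-9 * (gv + 1)
}

#' Log joint scores of a base learner
#'
#' Computes, for each query row and class, the unnormalized log posterior
#' `log pi_k + sum_{j in F} [ -0.5 log(2 pi sigma^2_kj)
#'  - (x_ij - mu_kj)^2 / (2 sigma^2_kj) ]` over the learner's feature subset.
#'
#' @param learner a `pav_gnb_learner` from [fit_base_gnb()].
#' @param x numeric query matrix with the original p columns.
#' @return n x K matrix of finite log scores.
#' @export
log_joint_scores <- function(learner, x) {
  if (!inherits(learner, "pav_gnb_learner")) stop("not a 'pav_gnb_learner'")
  x <- .as_query_matrix(x, learner$p)
  .log_joint_impl(learner, x)
}

.as_query_matrix <- function(x, p, feature_names = NULL) {
  if (is.data.frame(x)) {
    if (!is.null(feature_names) && all(feature_names %in% names(x))) {
      x <- x[feature_names]
    }
    x <- as.matrix(x)
  }
  if (!is.numeric(x)) stop("query data must be numeric")
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (ncol(x) != p) {
    stop("query has ", ncol(x), " columns; model expects ", p)
  }
  bad <- which(!is.finite(x), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop("non-finite query value at row ", bad[1L, 1L],
         ", column ", bad[1L, 2L])
  }
  x
}

# Hot path; assumes x already validated. Two BLAS products per learner.
.log_joint_impl <- function(learner, x) {
  xs <- x[, learner$feature_subset, drop = FALSE]
  v <- learner$variances
  m <- learner$means
  const <- log(learner$priors) - 0.5 * rowSums(log(2 * pi * v)) -
    rowSums(m * m / (2 * v))
  s <- xs %*% t(m / v) - (xs * xs) %*% t(1 / (2 * v))
  sweep(s, 2L, const, "+")
}

#' Normalize log scores into a posterior matrix
#'
#' Applies the log-sum-exp trick rowwise: the row maximum is subtracted
#' before exponentiation, so arbitrarily small log scores normalize without
#' underflow and the result is invariant to adding a constant to a row.
#'
#' @param log_scores n x K matrix of finite log scores.
#' @return n x K matrix with entries in \[0, 1\] and rows summing to 1.
#' @examples
#' normalize_log_posteriors(matrix(c(log(1), log(3)), 1))
#' @export
normalize_log_posteriors <- function(log_scores) {
  if (!is.matrix(log_scores)) log_scores <- matrix(log_scores, nrow = 1L)
  if (any(!is.finite(log_scores))) stop("log scores must be finite")
  e <- exp(log_scores -
             log_scores[cbind(seq_len(nrow(log_scores)),
                              max.col(log_scores, ties.method = "first"))])
  e / rowSums(e)
}

#' Fit a posterior-averaging Gaussian naive Bayes ensemble
#'
#' Trains `n_iter` Gaussian naive Bayes base learners. Iteration t draws a
#' class-stratified bootstrap of the rows and a uniform random subset of
#' `floor(feature_fraction * p)` (at least 1) feature columns, then estimates
#' per-class Gaussian parameters on that resample. Prediction averages the
#' members' normalized posteriors.
#'
#' The randomness of iteration t is keyed only by `(seed, t)`: a vector of
#' per-iteration seeds is drawn up front from `seed`, and each iteration
#' reseeds from its own entry. Fits are therefore bit-identical for any
#' `cores` setting and execution order.
#'
#' @param data a [labeled_dataset()], a data frame containing the response
#'   column named by `response`, or a numeric feature matrix (then `response`
#'   must be the label vector).
#' @param response response column name (data frame input) or label vector
#'   (matrix input); ignored for `labeled_dataset` input.
#' @param n_iter number of bootstrap iterations T (default 100).
#' @param feature_fraction fraction alpha in (0, 1] of features per member
#'   (default 0.5).
#' @param cores number of parallel workers (forked; an execution hint only,
#'   results do not depend on it).
#' @param seed integer base seed for the ensemble randomness.
#' @param variance_floor variance lower bound; default
#'   `1e-9 * (mean feature variance + 1)`.
#' @param resample `"stratified"` (the estimator) or `"identity"` (no
#'   resampling; every member sees the full data — used to recover a plain
#'   GNB fit when combined with `n_iter = 1`, `feature_fraction = 1`).
#' @return An object of class `pav_gnb` with elements `learners` (list of
#'   `pav_gnb_learner`), `classes`, `p`, `feature_names`, `n_train`,
#'   `class_counts`, and the fit configuration (`n_iter`, `feature_fraction`,
#'   `cores`, `seed`, `variance_floor`, `resample`).
#' @examples
#' d <- generate_dataset(preset_scenario("moderate", n = 300, p = 10, seed = 1))
#' fit <- pav_gnb(d, n_iter = 20, feature_fraction = 0.5, seed = 1)
#' head(predict(fit, d$x, type = "prob"))
#' @export
pav_gnb <- function(data, response = NULL, n_iter = 100L,
                    feature_fraction = 0.5, cores = 1L, seed = 1L,
                    variance_floor = NULL,
                    resample = c("stratified", "identity")) {
  resample <- match.arg(resample)
  dataset <- .coerce_training_data(data, response)
  n_iter <- as.integer(n_iter)
  cores <- as.integer(cores)
  stopifnot(n_iter >= 1L, cores >= 1L)
  if (feature_fraction <= 0 || feature_fraction > 1) {
    stop("'feature_fraction' must be in (0, 1]")
  }
  x <- dataset$x
  n <- nrow(x)
  p <- ncol(x)
  classes <- dataset$classes
  K <- length(classes)
  y_int <- match(dataset$y, classes)
  class_counts <- tabulate(y_int, K)
  if (is.null(variance_floor)) variance_floor <- .default_variance_floor(x)
  stopifnot(variance_floor > 0)
  m <- .subset_size(p, feature_fraction)

  set.seed(as.integer(seed))
  iter_seeds <- sample.int(2147483646L, n_iter)
  idx_by_class <- split(seq_len(n), factor(y_int, levels = seq_len(K)))

  fit_one <- function(t) {
    tryCatch({
      set.seed(iter_seeds[t])
      bidx <- if (resample == "stratified") {
        unlist(lapply(idx_by_class, function(ix) {
          ix[sample.int(length(ix), length(ix), replace = TRUE)]
        }), use.names = FALSE)
      } else {
        seq_len(n)
      }
      subset <- sort(sample.int(p, m))
      params <- .fit_gnb_params(x[bidx, subset, drop = FALSE],
                                y_int[bidx], K, variance_floor)
      structure(c(params, list(feature_subset = subset, p = p,
                               classes = classes, iteration_index = t)),
                class = "pav_gnb_learner")
    }, error = function(e) {
      structure(list(iteration = t, message = conditionMessage(e)),
                class = "pavgnb_iter_error")
    })
  }

  learners <- if (cores > 1L && .Platform$OS.type == "unix") {
    parallel::mclapply(seq_len(n_iter), fit_one, mc.cores = cores,
                       mc.set.seed = FALSE)
  } else {
    lapply(seq_len(n_iter), fit_one)
  }
  failed <- vapply(learners, inherits, logical(1L), "pavgnb_iter_error")
  if (any(failed)) {
    e <- learners[[which(failed)[1L]]]
    stop("ensemble iteration ", e$iteration, " failed: ", e$message)
  }

  structure(list(learners = learners, classes = classes, p = p,
                 feature_names = colnames(x), n_train = n,
                 class_counts = stats::setNames(class_counts, classes),
                 n_iter = n_iter, feature_fraction = feature_fraction,
                 subset_size = m, cores = cores, seed = as.integer(seed),
                 variance_floor = variance_floor, resample = resample),
            class = "pav_gnb")
}

.coerce_training_data <- function(data, response) {
  if (inherits(data, "labeled_dataset")) return(data)
  if (is.data.frame(data)) {
    if (is.null(response) || !is.character(response) ||
        !(response %in% names(data))) {
      stop("'response' must name a column of 'data'")
    }
    y <- data[[response]]
    x <- data[setdiff(names(data), response)]
    num <- vapply(x, is.numeric, logical(1L))
    if (!all(num)) {
      stop("non-numeric predictor column(s): ",
           paste(names(x)[!num], collapse = ", "))
    }
    return(labeled_dataset(as.matrix(x), y))
  }
  if (is.matrix(data)) {
    if (is.null(response)) stop("matrix input needs 'response' label vector")
    return(labeled_dataset(data, response))
  }
  stop("'data' must be a labeled_dataset, data frame, or numeric matrix")
}

#' Predict from a posterior-averaging GNB ensemble
#'
#' The ensemble posterior is the arithmetic mean of the members' normalized
#' posteriors (each member scores only its own feature subset); rows of the
#' averaged matrix sum to 1 without any second normalization. Class
#' predictions take the argmax, breaking exact ties toward the earliest
#' class in the vocabulary.
#'
#' @param object a `pav_gnb` model.
#' @param newdata numeric matrix or data frame with the model's p feature
#'   columns (a data frame is matched by the training feature names when
#'   they are all present, otherwise positionally).
#' @param type `"class"` for labels, `"prob"` for the averaged posterior
#'   matrix (one column per class, vocabulary order).
#' @param ... unused.
#' @return Character vector of labels, or an n x K probability matrix.
#' @export
predict.pav_gnb <- function(object, newdata,
                            type = c("class", "prob"), ...) {
  type <- match.arg(type)
  x <- .as_query_matrix(newdata, object$p, object$feature_names)
  post <- .average_posterior(object, x)
  if (type == "prob") return(post)
  object$classes[max.col(post, ties.method = "first")]
}

.average_posterior <- function(object, x) {
  n <- nrow(x)
  K <- length(object$classes)
  acc <- matrix(0, n, K)
  for (learner in object$learners) {
    s <- .log_joint_impl(learner, x)
    e <- exp(s - s[cbind(seq_len(n), max.col(s, ties.method = "first"))])
    acc <- acc + e / rowSums(e)
  }
  post <- acc / length(object$learners)
  colnames(post) <- object$classes
  post
}

# Member-level posteriors at x: n x K x T array. Internal; used by the
# theory harness to estimate member variance/correlation.
.member_posteriors <- function(object, x) {
  x <- .as_query_matrix(x, object$p, object$feature_names)
  n <- nrow(x)
  K <- length(object$classes)
  out <- array(NA_real_, c(n, K, length(object$learners)))
  for (t in seq_along(object$learners)) {
    s <- .log_joint_impl(object$learners[[t]], x)
    e <- exp(s - s[cbind(seq_len(n), max.col(s, ties.method = "first"))])
    out[, , t] <- e / rowSums(e)
  }
  out
}

#' @export
print.pav_gnb <- function(x, ...) {
  cat("Posterior-averaging Gaussian naive Bayes ensemble\n")
  cat("  members:          ", x$n_iter, "\n", sep = "")
  cat("  feature fraction: ", x$feature_fraction,
      "  (", x$subset_size, " of ", x$p, " features per member)\n", sep = "")
  cat("  classes:          ", paste(x$classes, collapse = ", "), "\n",
      sep = "")
  cat("  trained on:       ", x$n_train, " observations\n", sep = "")
  invisible(x)
}

#' @export
summary.pav_gnb <- function(object, ...) {
  incl <- tabulate(unlist(lapply(object$learners, `[[`, "feature_subset")),
                   nbins = object$p)
  cat("Posterior-averaging GNB ensemble summary\n")
  print(object)
  cat("  seed: ", object$seed, ", resample: ", object$resample, "\n",
      sep = "")
  cat("  per-feature inclusion count across members: min ", min(incl),
      ", mean ", round(mean(incl), 2), ", max ", max(incl), "\n", sep = "")
  invisible(list(feature_inclusion = incl))
}
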