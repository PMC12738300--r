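# Benchmark harness: named experiment grids, replicated train/test runs,
# and the accuracy / scalability-efficiency metrics.

#' Classification accuracy
#'
#' Fraction of exact label matches, `mean(predicted == truth)`.
#'
#' @param predicted,truth label vectors of equal length.
#' @return Accuracy in \[0, 1\].
#' @export
accuracy <- function(predicted, truth) {
  if (length(predicted) != length(truth)) {
    stop("length mismatch: ", length(predicted), " vs ", length(truth))
  }
  if (length(truth) < 1L) stop("need at least one observation")
  mean(as.character(predicted) == as.character(truth))
}

#' Scalability efficiency
#'
#' The fraction of ideal linear speedup realized with c workers:
#' `E_S = t1 / (c * tc)`, where `t1` is the single-core runtime and `tc` the
#' runtime on c cores.
#'
#' @param t1 single-core runtime in seconds (> 0).
#' @param tc c-core runtime in seconds (> 0).
#' @param cores number of cores c (>= 1).
#' @return Efficiency (1 = perfect linear scaling).
#' @examples
#' scalability_efficiency(15.2039, 8.0292, 2)
#' @export
scalability_efficiency <- function(t1, tc, cores) {
  if (any(t1 <= 0) || any(tc <= 0)) stop("runtimes must be positive")
  if (any(cores < 1)) stop("'cores' must be >= 1")
  t1 / (cores * tc)
}

#' Named experiment grids
#'
#' Returns the benchmark suite as named grids of scenario/fit cells:
#' \describe{
#'   \item{baseline}{four overlap levels at n=1000, p=50, K=3, alpha=0.25,
#'     T=100, single core.}
#'   \item{scalability}{moderate overlap, n=5000, p=100, cores in
#'     \{1,2,4,8,16\} (runtime-focused; accuracy is core-invariant).}
#'   \item{dimensionality}{p in \{10,50,100,500,1000,2000\} at n=5000,
#'     moderate overlap.}
#'   \item{sample-size}{n in \{500,...,200000\} at p=100, moderate overlap.}
#'   \item{feature-fraction}{alpha in \{sqrt(p)/p, 1/10, 1/5, 1/4, 1/3,
#'     1/2, 1\} at n=5000, p=100, moderate overlap.}
#'   \item{complexity}{K in \{2,3,5,10\} x \{moderate, high\} overlap at
#'     n=100000, p=1000.}
#'   \item{iterations}{T in \{10,50,100,300,500\} at n=10000, p=100,
#'     moderate overlap.}
#' }
#' `scale` multiplies the size parameters n, p, and T (floored, with small
#' lower bounds) for desk-sized runs; the per-cell replicate recommendation
#' is unchanged. The sqrt(p) feature fraction is recomputed from the scaled p.
#'
#' @param scale size multiplier in (0, 1].
#' @return Named list of data frames with columns `level`, `n`, `p`, `K`,
#'   `feature_fraction`, `fraction_label`, `n_iter`, `cores`.
#' @export
experiment_presets <- function(scale = 1) {
  stopifnot(scale > 0, scale <= 1)
  sc_n <- function(n) pmax(as.integer(floor(n * scale)), 50L)
  sc_p <- function(p) pmax(as.integer(floor(p * scale)), 4L)
  sc_t <- function(t) pmax(as.integer(floor(t * scale)), 2L)
  cell <- function(level, n, p, K, f, flab, t, cores) {
    data.frame(level = level, n = sc_n(n), p = sc_p(p), K = as.integer(K),
               feature_fraction = f, fraction_label = flab,
               n_iter = sc_t(t), cores = as.integer(cores),
               stringsAsFactors = FALSE)
  }
  p_ff <- sc_p(100)
  fracs <- c(sqrt(p_ff) / p_ff, 1 / 10, 1 / 5, 1 / 4, 1 / 3, 1 / 2, 1)
  flabs <- c("sqrt(p)", "p/10", "p/5", "p/4", "p/3", "p/2", "p")
  list(
    baseline = cell(c("none", "low", "moderate", "high"),
                    1000, 50, 3, 0.25, "p/4", 100, 1),
    scalability = cell("moderate", 5000, 100, 3, 0.25, "p/4", 100,
                       c(1, 2, 4, 8, 16)),
    dimensionality = cell("moderate", 5000,
                          c(10, 50, 100, 500, 1000, 2000), 3, 0.25, "p/4",
                          100, 4),
    `sample-size` = cell("moderate",
                         c(500, 1000, 5000, 10000, 20000, 50000, 100000,
                           200000), 100, 3, 0.25, "p/4", 100, 4),
    `feature-fraction` = cell("moderate", 5000, 100, 3, fracs, flabs,
                              100, 4),
    complexity = cell(rep(c("moderate", "high"), times = 4), 100000, 1000,
                      rep(c(2, 3, 5, 10), each = 2), 0.25, "p/4", 100, 8),
    iterations = cell("moderate", 10000, 100, 3, 0.25, "p/4",
                      c(10, 50, 100, 300, 500), 4)
  )
}

#' Run a replicated benchmark experiment
#'
#' For every cell of a grid, draws `replicates` independent train/test pairs
#' from the cell's scenario, fits the posterior-averaging GNB ensemble on the
#' training draw, and scores held-out accuracy on an independent test draw of
#' `max(2000, n/5)` observations from the same scenario. Per-replicate seeds
#' are derived from `seed` up front, so results are invariant to execution
#' order and core count. Wall-clock fit/predict times are recorded for
#' information only — they are hardware-dependent and never part of any
#' assertion.
#'
#' @param preset a preset name (see [experiment_presets()]) or a data frame
#'   of cells with the preset columns.
#' @param replicates independent repetitions per cell (default 10).
#' @param seed integer base seed.
#' @param scale size multiplier applied when `preset` is a name.
#' @param cores workers for each ensemble fit. The default 1 ignores the
#'   grid's `cores` column (an execution hint that does not affect results);
#'   pass `cores = "cell"` to honor it.
#' @return Long-format data frame: one row per (cell, replicate) with the
#'   cell factors, `replicate`, `seed`, `accuracy`, `fit_seconds`,
#'   `predict_seconds`.
#' @seealso [summarize_experiment()]
#' @export
run_experiment <- function(preset, replicates = 10L, seed = 1L, scale = 1,
                           cores = 1L) {
  cells <- if (is.character(preset)) {
    presets <- experiment_presets(scale)
    if (!preset %in% names(presets)) {
      stop("unknown preset '", preset, "'; available: ",
           paste(names(presets), collapse = ", "))
    }
    presets[[preset]]
  } else if (is.data.frame(preset)) {
    preset
  } else {
    stop("'preset' must be a preset name or a cell data frame")
  }
  replicates <- as.integer(replicates)
  stopifnot(replicates >= 1L)
  set.seed(as.integer(seed))
  seeds <- array(sample.int(2147483646L, nrow(cells) * replicates * 3L),
                 dim = c(nrow(cells), replicates, 3L))
  out <- vector("list", nrow(cells) * replicates)
  row <- 0L
  for (ci in seq_len(nrow(cells))) {
    cl <- cells[ci, ]
    fit_cores <- if (identical(cores, "cell")) cl$cores else as.integer(cores)
    for (r in seq_len(replicates)) {
      sp <- preset_scenario(cl$level, n = cl$n, p = cl$p, K = cl$K)
      train <- generate_dataset(sp, seed = seeds[ci, r, 1L])
      t_fit <- system.time(
        fit <- pav_gnb(train, n_iter = cl$n_iter,
                       feature_fraction = cl$feature_fraction,
                       cores = fit_cores, seed = seeds[ci, r, 2L])
      )[["elapsed"]]
      rm(train)
      test_spec <- preset_scenario(cl$level, n = .test_size(cl$n, scale),
                                   p = cl$p, K = cl$K)
      test <- generate_dataset(test_spec, seed = seeds[ci, r, 3L])
      t_pred <- system.time(
        pred <- predict(fit, test$x, type = "class")
      )[["elapsed"]]
      acc <- accuracy(pred, test$y)
      rm(fit, test)
      row <- row + 1L
      out[[row]] <- cbind(cl,
                          data.frame(replicate = r,
                                     seed = seeds[ci, r, 1L],
                                     accuracy = acc,
                                     fit_seconds = t_fit,
                                     predict_seconds = t_pred))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Summarize benchmark results per cell
#'
#' Mean and standard deviation of accuracy (and, informationally, of the
#' recorded wall times) across replicates for each cell of a
#' [run_experiment()] result.
#'
#' @param results long-format data frame from [run_experiment()].
#' @return Data frame with one row per cell: the cell factors plus
#'   `accuracy_mean`, `accuracy_sd`, `runtime_mean`, `runtime_sd`,
#'   `replicates`.
#' @export
summarize_experiment <- function(results) {
  cell_cols <- intersect(c("level", "n", "p", "K", "feature_fraction",
                           "fraction_label", "n_iter", "cores"),
                         names(results))
  key <- do.call(paste, c(results[cell_cols], sep = "\r"))
  split_rows <- split(seq_len(nrow(results)), factor(key, levels = unique(key)))
  rows <- lapply(split_rows, function(ix) {
    runtime <- results$fit_seconds[ix] + results$predict_seconds[ix]
    cbind(results[ix[1L], cell_cols, drop = FALSE],
          data.frame(accuracy_mean = mean(results$accuracy[ix]),
                     accuracy_sd = if (length(ix) > 1L)
                       stats::sd(results$accuracy[ix]) else 0,
                     runtime_mean = mean(runtime),
                     runtime_sd = if (length(ix) > 1L)
                       stats::sd(runtime) else 0,
                     replicates = length(ix)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
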