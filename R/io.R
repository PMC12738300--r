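# CSV ingestion and JSON model persistence.

#' Read a labeled dataset from CSV
#'
#' Reads a delimited text file with a header, takes `response` as the class
#' column, and requires every other column to be numeric with no missing
#' values (offending rows/columns are named in the error). The class
#' vocabulary is the first-appearance order of the labels.
#'
#' @param path CSV file path.
#' @param response name of the response column (default `"class"`).
#' @return A [labeled_dataset()].
#' @export
read_labeled_csv <- function(path, response = "class") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(df) == 0L) stop("empty file: ", path)
  if (!response %in% names(df)) {
    stop("response column '", response, "' not found in ", path,
         " (columns: ", paste(utils::head(names(df), 8L), collapse = ", "),
         ")")
  }
  y <- as.character(df[[response]])
  xd <- df[setdiff(names(df), response)]
  num <- vapply(xd, is.numeric, logical(1L))
  if (!all(num)) {
    stop("non-numeric predictor column(s): ",
         paste(names(xd)[!num], collapse = ", "))
  }
  x <- as.matrix(xd)
  bad <- which(!is.finite(x), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop("missing/non-finite value at row ", bad[1L, 1L], ", column '",
         colnames(x)[bad[1L, 2L]], "'")
  }
  labeled_dataset(x, y)
}

#' Write a labeled dataset to CSV
#'
#' Inverse of [read_labeled_csv()]: features with their column names plus the
#' response column. Numeric values are written at full double precision so
#' the file round-trips to an identical dataset.
#'
#' @param dataset a [labeled_dataset()].
#' @param path output file path.
#' @param response name for the response column.
#' @return `path`, invisibly.
#' @export
write_labeled_csv <- function(dataset, path, response = "class") {
  dataset <- .check_dataset(dataset)
  df <- as.data.frame(lapply(as.data.frame(dataset$x), function(col) {
    sprintf("%.17g", col)
  }), check.names = FALSE)
  df[[response]] <- dataset$y
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.MODEL_FORMAT <- "pavgnb-model"
.MODEL_VERSION <- 1L

#' Save an ensemble model as structured text
#'
#' Serializes the full model — configuration, class vocabulary, and each
#' member's feature subset, priors, means, and variances — as JSON with 17
#' significant digits, so a load round-trip reproduces every double exactly.
#' The `cores` execution hint is deliberately not serialized: it does not
#' affect the fit, and omitting it makes the saved file byte-identical for
#' any worker count.
#'
#' @param model a `pav_gnb` model.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  if (!inherits(model, "pav_gnb")) stop("expected a 'pav_gnb' model")
  payload <- list(
    format = .MODEL_FORMAT,
    version = .MODEL_VERSION,
    classes = model$classes,
    p = model$p,
    feature_names = model$feature_names,
    n_train = model$n_train,
    class_counts = as.integer(model$class_counts),
    config = list(n_iter = model$n_iter,
                  feature_fraction = model$feature_fraction,
                  subset_size = model$subset_size,
                  seed = model$seed,
                  variance_floor = model$variance_floor,
                  resample = model$resample),
    learners = lapply(model$learners, function(l) {
      list(iteration = l$iteration_index,
           feature_subset = l$feature_subset,
           priors = l$priors,
           means = l$means,
           variances = l$variances)
    })
  )
  jsonlite::write_json(payload, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' Load an ensemble model saved by [save_model()]
#'
#' @param path model file path.
#' @return A `pav_gnb` model equivalent to the saved one.
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  payload <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                      error = function(e) {
                        stop("cannot parse model file '", path, "': ",
                             conditionMessage(e))
                      })
  if (!identical(payload$format, .MODEL_FORMAT)) {
    stop("not a pavgnb model file: ", path)
  }
  if (!identical(as.integer(payload$version), .MODEL_VERSION)) {
    stop("unsupported model version ", payload$version,
         " (this build reads version ", .MODEL_VERSION, ")")
  }
  classes <- as.character(payload$classes)
  p <- as.integer(payload$p)
  learners <- lapply(seq_len(nrow_or_len(payload$learners)), function(i) {
    l <- extract_row(payload$learners, i)
    means <- as.matrix(l$means)
    vars <- as.matrix(l$variances)
    structure(list(priors = as.numeric(l$priors), means = means,
                   variances = vars,
                   feature_subset = as.integer(l$feature_subset), p = p,
                   classes = classes,
                   iteration_index = as.integer(l$iteration)),
              class = "pav_gnb_learner")
  })
  cfg <- payload$config
  structure(list(learners = learners, classes = classes, p = p,
                 feature_names = as.character(payload$feature_names),
                 n_train = as.integer(payload$n_train),
                 class_counts = stats::setNames(
                   as.integer(payload$class_counts), classes),
                 n_iter = as.integer(cfg$n_iter),
                 feature_fraction = cfg$feature_fraction,
                 subset_size = as.integer(cfg$subset_size),
                 cores = 1L, seed = as.integer(cfg$seed),
                 variance_floor = cfg$variance_floor,
                 resample = cfg$resample),
            class = "pav_gnb")
}

# jsonlite may simplify the learner list to a data frame; treat both shapes.
nrow_or_len <- function(x) if (is.data.frame(x)) nrow(x) else length(x)
extract_row <- function(x, i) {
  if (is.data.frame(x)) {
    list(iteration = x$iteration[[i]],
         feature_subset = x$feature_subset[[i]],
         priors = x$priors[[i]],
         means = x$means[[i]],
         variances = x$variances[[i]])
  } else {
    x[[i]]
  }
}
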