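#' Labeled dataset container
#'
#' Bundles a numeric feature matrix with a categorical response and an ordered
#' class vocabulary. The vocabulary defaults to first-appearance order of the
#' labels, which also fixes the column order of posterior matrices and the
#' tie-breaking order at prediction.
#'
#' @param x numeric matrix or data frame of features (rows = observations).
#' @param y vector of class labels, length `nrow(x)`; coerced to character.
#' @param classes optional ordered character vector of the K distinct classes;
#'   defaults to `unique(as.character(y))`.
#'
#' @return An object of class `labeled_dataset`: a list with elements `x`
#'   (numeric matrix), `y` (character vector) and `classes`.
#' @examples
#' d <- labeled_dataset(matrix(rnorm(12), 6, 2), rep(c("a", "b"), 3))
#' d$classes
#' @export
labeled_dataset <- function(x, y, classes = NULL) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("'x' must be a numeric matrix or data frame of numeric columns")
  }
  y <- as.character(y)
  if (length(y) != nrow(x)) {
    stop("length(y) [", length(y), "] does not match nrow(x) [", nrow(x), "]")
  }
  bad <- which(!is.finite(x), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop("non-finite feature value at row ", bad[1L, 1L],
         ", column ", bad[1L, 2L])
  }
  if (is.null(classes)) classes <- unique(y)
  classes <- as.character(classes)
  if (anyDuplicated(classes)) stop("'classes' must be distinct")
  if (!all(y %in% classes)) {
    stop("labels outside the class vocabulary: ",
         paste(utils::head(setdiff(y, classes), 3L), collapse = ", "))
  }
  if (length(classes) < 2L) stop("need at least 2 classes")
  if (nrow(x) < length(classes)) stop("need n >= K observations")
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  structure(list(x = x, y = y, classes = classes),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat("Labeled dataset: ", nrow(x$x), " observations, ", ncol(x$x),
      " features, ", length(x$classes), " classes\n", sep = "")
  cat("Class counts:\n")
  print(table(factor(x$y, levels = x$classes)))
  invisible(x)
}

#' @export
as.data.frame.labeled_dataset <- function(x, ..., response = "class") {
  out <- as.data.frame(x$x)
  out[[response]] <- x$y
  out
}

.check_dataset <- function(dataset) {
  if (!inherits(dataset, "labeled_dataset")) {
    stop("expected a 'labeled_dataset' (see labeled_dataset())")
  }
  dataset
}
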