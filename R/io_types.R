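#' Labeled feature epochs for one subject
#'
#' Container for one subject's calibration data: a numeric feature matrix with
#' one row per epoch and an integer class label per row. Labels are 1-based
#' (`1..n_classes`), matching the usual coding of ordered task-difficulty
#' scenarios. Feature values are expected (but not required) to lie in
#' `[0, 1]` after per-subject min-max normalization
#' (see [minmax_normalize()]).
#'
#' @param subject_id Single character string identifying the subject.
#' @param X Numeric matrix, `n` epochs x `F` features; all values finite.
#' @param y Integer vector of length `n` with class labels in `1..n_classes`.
#' @param feature_names Character vector of length `F`; defaults to
#'   `colnames(X)` or `f1..fF`.
#' @param n_classes Number of classes `K`; defaults to `max(y)`.
#'
#' @return An object of class `feature_dataset`: a list with elements
#'   `subject_id`, `X`, `y`, `feature_names`, `n_classes`.
#' @examples
#' ds <- feature_dataset("s1", matrix(runif(12), 6, 2), rep(1:3, each = 2))
#' ds
#' @export
feature_dataset <- function(subject_id, X, y,
                            feature_names = NULL, n_classes = NULL) {
  if (!is.character(subject_id) || length(subject_id) != 1L || is.na(subject_id))
    stop("`subject_id` must be a single string", call. = FALSE)
  if (is.data.frame(X)) X <- as.matrix(X)
  if (!is.matrix(X) || !is.numeric(X))
    stop("`X` must be a numeric matrix", call. = FALSE)
  storage.mode(X) <- "double"
  if (any(!is.finite(X)))
    stop("validation error: `X` contains non-finite values", call. = FALSE)
  if (length(y) != nrow(X))
    stop("validation error: length(y) != nrow(X)", call. = FALSE)
  if (any(is.na(y)) || any(y != as.integer(y)) || any(y < 1L))
    stop("validation error: labels must be positive integers", call. = FALSE)
  y <- as.integer(y)
  if (is.null(n_classes)) n_classes <- max(y)
  n_classes <- as.integer(n_classes)
  if (any(y > n_classes))
    stop("validation error: label outside 1..", n_classes, call. = FALSE)
  if (is.null(feature_names)) {
    feature_names <- colnames(X)
    if (is.null(feature_names)) feature_names <- paste0("f", seq_len(ncol(X)))
  }
  if (length(feature_names) != ncol(X))
    stop("validation error: feature_names length != ncol(X)", call. = FALSE)
  colnames(X) <- feature_names
  structure(
    list(subject_id = subject_id, X = X, y = y,
         feature_names = feature_names, n_classes = n_classes),
    class = "feature_dataset"
  )
}

#' @export
print.feature_dataset <- function(x, ...) {
  cat(sprintf("<feature_dataset> subject '%s': %d epochs x %d features, K = %d\n",
              x$subject_id, nrow(x$X), ncol(x$X), x$n_classes))
  cat("  class counts:", paste(tabulate(x$y, x$n_classes), collapse = "/"), "\n")
  invisible(x)
}

#' Pool of subjects sharing one feature schema
#'
#' A non-empty list of [feature_dataset()] objects with distinct subject ids,
#' identical feature names and the same number of classes. This is the
#' "subject database" that auxiliary training data are drawn from.
#'
#' @param datasets List of `feature_dataset` objects.
#' @return An object of class `subject_pool` (a named list of datasets).
#' @export
subject_pool <- function(datasets) {
  if (!is.list(datasets) || length(datasets) == 0L)
    stop("validation error: pool must be a non-empty list", call. = FALSE)
  ok <- vapply(datasets, inherits, logical(1), "feature_dataset")
  if (!all(ok))
    stop("validation error: all pool elements must be feature_dataset", call. = FALSE)
  ids <- vapply(datasets, `[[`, character(1), "subject_id")
  if (anyDuplicated(ids))
    stop("validation error: duplicate subject_id in pool", call. = FALSE)
  fn <- datasets[[1L]]$feature_names
  K <- datasets[[1L]]$n_classes
  for (ds in datasets) {
    if (!identical(ds$feature_names, fn))
      stop("validation error: feature names differ across pool subjects", call. = FALSE)
    if (ds$n_classes != K)
      stop("validation error: n_classes differs across pool subjects", call. = FALSE)
  }
  names(datasets) <- ids
  structure(datasets, class = "subject_pool",
            feature_names = fn, n_classes = K)
}

#' @export
print.subject_pool <- function(x, ...) {
  cat(sprintf("<subject_pool> %d subjects, %d features, K = %d\n",
              length(x), length(attr(x, "feature_names")), attr(x, "n_classes")))
  invisible(x)
}

#' Calibration-session configuration
#'
#' Bundles the knobs of the online calibration loop. Defaults follow the
#' standard short-calibration protocol: start from one sample per class
#' (`m0 = K`), add `l` samples per iteration, stop at 30 primary samples or
#' when the internal cross-validation accuracy reaches `lambda` (with the
#' default `lambda = 1` the loop normally runs to `max_m`).
#'
#' @param n_classes Number of classes `K`.
#' @param classifier `"knn"` or `"svm"`.
#' @param m0 Initial number of primary samples; must be a multiple of `K`
#'   so every class is represented. Default `K`.
#' @param l Samples requested per iteration (typically 1, 2 or 3).
#' @param max_m Maximum number of primary samples (default 30).
#' @param lambda Minimum satisfactory internal-CV accuracy in `(0, 1]`
#'   (default 1).
#' @param use_tl Use transfer learning for hyperparameter selection?
#' @param use_acs Use active class selection for requesting classes?
#' @param seed Optional integer seed set at the start of a calibration run.
#' @param grid Optional hyperparameter grid (data.frame); when `NULL` the
#'   per-iteration default of [default_param_grid()] is used.
#' @return An object of class `calibration_config`.
#' @export
calibration_config <- function(n_classes, classifier = c("knn", "svm"),
                               m0 = NULL, l = 1L, max_m = 30L, lambda = 1,
                               use_tl = FALSE, use_acs = FALSE,
                               seed = NULL, grid = NULL) {
  classifier <- match.arg(classifier)
  n_classes <- as.integer(n_classes)
  if (n_classes < 2L) stop("n_classes must be >= 2", call. = FALSE)
  if (is.null(m0)) m0 <- n_classes
  m0 <- as.integer(m0); l <- as.integer(l); max_m <- as.integer(max_m)
  if (m0 < n_classes) stop("m0 must be >= n_classes", call. = FALSE)
  if (m0 %% n_classes != 0L)
    stop("m0 must be a multiple of n_classes (round-robin initialization)",
         call. = FALSE)
  if (l < 1L) stop("l must be >= 1", call. = FALSE)
  if (max_m < m0) stop("max_m must be >= m0", call. = FALSE)
  if (!is.numeric(lambda) || lambda <= 0 || lambda > 1)
    stop("lambda must be in (0, 1]", call. = FALSE)
  structure(
    list(n_classes = n_classes, classifier = classifier, m0 = m0, l = l,
         max_m = max_m, lambda = lambda, use_tl = isTRUE(use_tl),
         use_acs = isTRUE(use_acs),
         seed = if (is.null(seed)) NULL else as.integer(seed), grid = grid),
    class = "calibration_config"
  )
}

#' Read a CSV feature table into a subject pool
#'
#' The interchange format is a comma-separated UTF-8 table with mandatory
#' header `subject,label,f1,...,fF` ("." decimal separator): one row per
#' epoch, grouped into one [feature_dataset()] per distinct subject id.
#'
#' @param path Path to a CSV file.
#' @param n_classes Optional `K`; labels outside `1..K` are a validation
#'   error. Default: inferred as the maximum label in the file.
#' @return A [subject_pool()].
#' @seealso [write_feature_table()]
#' @export
read_feature_table <- function(path, n_classes = NULL) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3L || !identical(names(df)[1:2], c("subject", "label")))
    stop("format error: expected header 'subject,label,<features...>'",
         call. = FALSE)
  feat_cols <- names(df)[-(1:2)]
  Xall <- as.matrix(df[feat_cols])
  if (!is.numeric(Xall))
    stop("validation error: non-numeric feature values", call. = FALSE)
  if (is.null(n_classes)) {
    if (any(!is.finite(df$label)))
      stop("validation error: non-finite labels", call. = FALSE)
    n_classes <- max(df$label)
  }
  subjects <- unique(df$subject)
  datasets <- lapply(subjects, function(s) {
    rows <- df$subject == s
    feature_dataset(as.character(s), Xall[rows, , drop = FALSE],
                    df$label[rows], feature_names = feat_cols,
                    n_classes = n_classes)
  })
  subject_pool(datasets)
}

#' Write a subject pool as a CSV feature table
#'
#' Inverse of [read_feature_table()]; numeric values are written with 17
#' significant digits so that a read/write round trip reproduces the feature
#' matrix and labels bit-exactly.
#'
#' @param pool A [subject_pool()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_feature_table <- function(pool, path) {
  if (!inherits(pool, "subject_pool")) pool <- subject_pool(pool)
  blocks <- lapply(pool, function(ds) {
    Xc <- apply(ds$X, 2L, function(col) sprintf("%.17g", col))
    if (!is.matrix(Xc)) Xc <- matrix(Xc, nrow = nrow(ds$X))
    data.frame(subject = ds$subject_id, label = ds$y, Xc,
               check.names = FALSE, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, blocks)
  names(df) <- c("subject", "label", attr(pool, "feature_names"))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
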