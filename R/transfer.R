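#' Leave-one-out cross-validation accuracy on the primary samples
#'
#' Each primary sample is held out in turn, the classifier is fitted on the
#' remaining samples and the held-out sample is scored. A fold whose training
#' part has lost a class entirely is still scored (the classifier simply
#' cannot predict that class). This is the internal-CV accuracy `acc_p`
#' driving hyperparameter selection.
#'
#' @param primary A [feature_dataset()] with `n >= 2`.
#' @param params ClassifierParams: `list(k = ...)` for kNN or
#'   `list(C = ..., gamma = ...)` for the RBF SVM.
#' @param classifier `"knn"` or `"svm"`.
#' @return Accuracy in `[0, 1]`.
#' @export
loocv_accuracy <- function(primary, params, classifier = c("knn", "svm")) {
  classifier <- match.arg(classifier)
  check_loocv_args(primary, params, classifier)
  pred <- loocv_pred_one(primary, params, classifier)
  mean(pred == primary$y)
}

#' Per-class leave-one-out accuracies
#'
#' Same folds as [loocv_accuracy()], but the held-out accuracy is reported
#' separately per class: `a_c` = correct held-out predictions among class-`c`
#' samples divided by the class-`c` count. Classes with no sample get `NA`
#' (callers such as the active-class-selection rule treat that as accuracy
#' zero, i.e. maximal need for samples). The count-weighted mean of the
#' defined `a_c` equals the overall accuracy.
#'
#' @inheritParams loocv_accuracy
#' @return Numeric vector of length `K`.
#' @export
per_class_loocv_accuracy <- function(primary, params, classifier = c("knn", "svm")) {
  classifier <- match.arg(classifier)
  check_loocv_args(primary, params, classifier)
  pred <- loocv_pred_one(primary, params, classifier)
  per_class_from_pred(pred, primary$y, primary$n_classes)
}

#' Accuracy of a primary-trained classifier on auxiliary samples
#'
#' Trains on *all* primary samples and classifies the auxiliary dataset; the
#' returned fraction correct is the tie-breaking score `acc_a` of the
#' transfer-learning selection rule (auxiliary data are used only for
#' validation, never as training points).
#'
#' @inheritParams loocv_accuracy
#' @param aux A non-empty [feature_dataset()] from another subject.
#' @return Accuracy in `[0, 1]`.
#' @export
auxiliary_accuracy <- function(primary, aux, params, classifier = c("knn", "svm")) {
  classifier <- match.arg(classifier)
  stopifnot(inherits(primary, "feature_dataset"), inherits(aux, "feature_dataset"))
  if (nrow(aux$X) == 0L) stop("auxiliary dataset is empty", call. = FALSE)
  pred <- fit_predict(classifier, primary$X, primary$y, params, aux$X,
                      primary$n_classes)
  mean(pred == aux$y)
}

#' Transfer-learning hyperparameter selection
#'
#' Scores every grid point by its primary leave-one-out accuracy `acc_p`;
#' because the primary set is small, many grid points tie, and ties are broken
#' by the accuracy `acc_a` of the primary-trained classifier on the auxiliary
#' data. Any remaining tie resolves to the earliest grid row (smallest `k`
#' for kNN; smallest `(C, gamma)` for the SVM). With `aux = NULL` the
#' auxiliary score is identically 0 and the procedure reduces to the
#' baseline's primary-only internal-CV selection.
#'
#' @inheritParams loocv_accuracy
#' @param aux A [feature_dataset()] of auxiliary samples, or `NULL` for the
#'   baseline (no transfer) mode.
#' @param grid Data.frame of candidate parameters (one row per candidate),
#'   e.g. from [default_param_grid()].
#' @return An object of class `tl_score`: list with `params`, `acc_p`,
#'   `acc_a`, the selected grid `index`, and `loocv_pred` (the held-out
#'   predictions under the selected parameters, reusable for per-class
#'   accuracies).
#' @export
tl_select_params <- function(primary, aux, grid, classifier = c("knn", "svm")) {
  classifier <- match.arg(classifier)
  stopifnot(inherits(primary, "feature_dataset"))
  if (!is.data.frame(grid) || nrow(grid) == 0L)
    stop("grid must be a non-empty data.frame", call. = FALSE)
  n <- nrow(primary$X)
  K <- primary$n_classes

  if (classifier == "knn") {
    ks <- pmin(grid$k, n - 1L)
    P <- knn_loocv_predictions(primary$X, primary$y, ks, K)
    acc_p <- colMeans(P == primary$y)
  } else {
    P <- vapply(seq_len(nrow(grid)), function(i) {
      loocv_predictions(classifier, primary$X, primary$y,
                        grid_params(grid, i), K)
    }, integer(n))
    if (!is.matrix(P)) P <- matrix(P, nrow = n)
    acc_p <- colMeans(P == primary$y)
  }

  tied <- which(acc_p == max(acc_p))
  if (length(tied) > 1L && !is.null(aux)) {
    if (classifier == "knn") {
      acc_a_tied <- knn_aux_accuracy_multi(primary$X, primary$y, aux$X, aux$y,
                                           grid$k[tied], K)
    } else {
      acc_a_tied <- vapply(tied, function(i) {
        auxiliary_accuracy(primary, aux, grid_params(grid, i), classifier)
      }, numeric(1))
    }
    best <- tied[which.max(acc_a_tied)]   # first max: earliest grid row
    acc_a <- acc_a_tied[which.max(acc_a_tied)]
  } else {
    best <- tied[1L]
    acc_a <- if (is.null(aux)) 0
    else if (classifier == "knn")
      knn_aux_accuracy_multi(primary$X, primary$y, aux$X, aux$y,
                             grid$k[best], K)
    else auxiliary_accuracy(primary, aux, grid_params(grid, best), classifier)
  }

  structure(list(params = grid_params(grid, best),
                 acc_p = unname(acc_p[best]), acc_a = unname(acc_a),
                 index = best, loocv_pred = P[, best]),
            class = "tl_score")
}

# ---- internal helpers -------------------------------------------------------

check_loocv_args <- function(primary, params, classifier) {
  stopifnot(inherits(primary, "feature_dataset"))
  n <- nrow(primary$X)
  if (n < 2L) stop("LOOCV needs at least 2 primary samples", call. = FALSE)
  if (classifier == "knn") {
    if (is.null(params$k) || params$k < 1L) stop("k must be >= 1", call. = FALSE)
    if (params$k > n - 1L)
      stop("k exceeds the leave-one-out training size (n - 1)", call. = FALSE)
  } else {
    if (is.null(params$C) || params$C <= 0 ||
        is.null(params$gamma) || params$gamma <= 0)
      stop("C and gamma must be positive", call. = FALSE)
  }
  invisible(TRUE)
}

loocv_pred_one <- function(primary, params, classifier) {
  if (classifier == "knn") {
    drop(knn_loocv_predictions(primary$X, primary$y, params$k,
                               primary$n_classes))
  } else {
    loocv_predictions(classifier, primary$X, primary$y, params,
                      primary$n_classes)
  }
}

per_class_from_pred <- function(pred, y, K) {
  a <- rep(NA_real_, K)
  for (c in seq_len(K)) {
    idx <- y == c
    if (any(idx)) a[c] <- mean(pred[idx] == c)
  }
  a
}
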