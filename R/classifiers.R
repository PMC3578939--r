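# Internal classifier kernel: deterministic Euclidean kNN plus an RBF SVM
# (one-vs-one, via libsvm through e1071). The kNN vote tie rule is part of the
# package contract: among classes tied for the most votes, the class of the
# nearest neighbour belonging to a tied class wins, which is deterministic and
# distance-respecting. Neighbour ordering uses stable sorting, so equal
# distances resolve by row order.

# Squared Euclidean distances between rows of A and rows of B.
pdist2 <- function(A, B) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  d2
}

# Predict classes from a test-by-train distance matrix for one k.
knn_predict_dist <- function(D, y_train, k, n_classes) {
  drop(knn_vote_cpp(D, as.integer(y_train), as.integer(min(k, ncol(D))),
                    as.integer(n_classes)))
}

# Leave-one-out kNN predictions for every k in `ks` at once.
# Returns an n x length(ks) integer matrix of predicted labels.
knn_loocv_predictions <- function(X, y, ks, n_classes) {
  n <- nrow(X)
  D <- pdist2(X, X)
  diag(D) <- Inf   # the held-out point is never its own neighbour
  P <- knn_vote_cpp(D, as.integer(y), as.integer(pmin(ks, n - 1L)),
                    as.integer(n_classes))
  if (!is.matrix(P)) P <- matrix(P, nrow = n)
  P
}

# Accuracy on (aux_X, aux_y) of primary-trained kNN, for several k at once:
# the test-by-train distance matrix and per-row neighbour orderings are
# computed once and reused across all k.
knn_aux_accuracy_multi <- function(X_train, y_train, aux_X, aux_y, ks, n_classes) {
  D <- pdist2(aux_X, X_train)
  P <- knn_vote_cpp(D, as.integer(y_train), as.integer(pmin(ks, ncol(D))),
                    as.integer(n_classes))
  if (!is.matrix(P)) P <- matrix(P, nrow = nrow(D))
  colMeans(P == aux_y)
}

# Fit on (X_train, y_train) and predict X_test; degenerate single-class
# training data predicts that class for everything (an RBF SVM cannot even be
# fitted then, and a kNN vote is unanimous).
fit_predict <- function(classifier, X_train, y_train, params, X_test, n_classes) {
  present <- unique(y_train)
  if (length(present) == 1L)
    return(rep.int(present, nrow(X_test)))
  if (classifier == "knn") {
    knn_predict_dist(pdist2(X_test, X_train), y_train, params$k, n_classes)
  } else {
    fit <- e1071::svm(x = X_train,
                      y = factor(y_train, levels = seq_len(n_classes)),
                      type = "C-classification", kernel = "radial",
                      cost = params$C, gamma = params$gamma, scale = FALSE)
    as.integer(as.character(stats::predict(fit, X_test)))
  }
}

# Leave-one-out predictions for an arbitrary classifier (slow generic path;
# the kNN selection machinery uses knn_loocv_predictions instead).
loocv_predictions <- function(classifier, X, y, params, n_classes) {
  n <- nrow(X)
  vapply(seq_len(n), function(i) {
    fit_predict(classifier, X[-i, , drop = FALSE], y[-i], params,
                X[i, , drop = FALSE], n_classes)
  }, integer(1))
}

#' Default hyperparameter grid
#'
#' For kNN: odd neighbour counts `k` in `1, 3, ..., min(15, m - 1)`, so that
#' leave-one-out folds of an `m`-sample primary set always have at least `k`
#' training points and most voting ties are avoided. For the RBF SVM: the
#' conventional coarse logarithmic grid `C` in `2^-5, 2^-3, ..., 2^15` crossed
#' with `gamma` in `2^-15, 2^-13, ..., 2^3`, ordered by `C` then `gamma` so
#' that tie-breaking toward the first grid row prefers the smallest
#' `(C, gamma)`.
#'
#' @param classifier `"knn"` or `"svm"`.
#' @param m Current number of primary training samples (caps the kNN `k`).
#' @return A data.frame with column `k` (kNN) or columns `C`, `gamma` (SVM).
#' @export
default_param_grid <- function(classifier = c("knn", "svm"), m) {
  classifier <- match.arg(classifier)
  if (classifier == "knn") {
    kmax <- max(1L, min(15L, as.integer(m) - 1L))
    data.frame(k = seq(1L, kmax, by = 2L))
  } else {
    g <- expand.grid(gamma = 2^seq(-15L, 3L, by = 2L),
                     C = 2^seq(-5L, 15L, by = 2L))
    data.frame(C = g$C, gamma = g$gamma)
  }
}

# Row i of a grid data.frame as a ClassifierParams list.
grid_params <- function(grid, i) as.list(grid[i, , drop = FALSE])
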