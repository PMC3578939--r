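# Independent brute-force oracles. These re-implement the scored quantities
# with plain loops and explicit arithmetic, sharing no code with the package
# internals, so that agreement is evidence of correctness rather than of
# shared bugs. The kNN oracle implements the documented deterministic vote
# contract (ties toward the nearest tied class).

oracle_knn_one <- function(X_train, y_train, x, k, K) {
  d <- sqrt(colSums((t(X_train) - x)^2))
  ord <- order(d)
  nb <- y_train[ord[seq_len(min(k, length(y_train)))]]
  counts <- sapply(seq_len(K), function(c) sum(nb == c))
  winners <- which(counts == max(counts))
  if (length(winners) == 1L) return(winners)
  for (cls in nb) if (cls %in% winners) return(cls)
}

oracle_loocv_pred <- function(ds, params, classifier, K = ds$n_classes) {
  n <- nrow(ds$X)
  sapply(seq_len(n), function(i) {
    Xtr <- ds$X[-i, , drop = FALSE]; ytr <- ds$y[-i]
    if (length(unique(ytr)) == 1L) return(unique(ytr))
    if (classifier == "knn") {
      oracle_knn_one(Xtr, ytr, ds$X[i, ], params$k, K)
    } else {
      fit <- e1071::svm(x = Xtr, y = factor(ytr, levels = seq_len(K)),
                        type = "C-classification", kernel = "radial",
                        cost = params$C, gamma = params$gamma, scale = FALSE)
      as.integer(as.character(predict(fit, ds$X[i, , drop = FALSE])))
    }
  })
}

oracle_loocv_accuracy <- function(ds, params, classifier) {
  mean(oracle_loocv_pred(ds, params, classifier) == ds$y)
}

oracle_per_class_accuracy <- function(ds, params, classifier) {
  pred <- oracle_loocv_pred(ds, params, classifier)
  sapply(seq_len(ds$n_classes), function(c) {
    if (!any(ds$y == c)) return(NA_real_)
    mean(pred[ds$y == c] == c)
  })
}

oracle_auxiliary_accuracy <- function(primary, aux, params, classifier) {
  K <- primary$n_classes
  pred <- if (classifier == "knn") {
    sapply(seq_len(nrow(aux$X)), function(j)
      oracle_knn_one(primary$X, primary$y, aux$X[j, ], params$k, K))
  } else {
    fit <- e1071::svm(x = primary$X, y = factor(primary$y, levels = seq_len(K)),
                      type = "C-classification", kernel = "radial",
                      cost = params$C, gamma = params$gamma, scale = FALSE)
    as.integer(as.character(predict(fit, aux$X)))
  }
  mean(pred == aux$y)
}

# Exhaustive double-key arg-max: score every grid row fully, then pick the
# best (acc_p, then acc_a, then earliest row).
oracle_tl_select <- function(primary, aux, grid, classifier) {
  scores <- t(sapply(seq_len(nrow(grid)), function(i) {
    params <- as.list(grid[i, , drop = FALSE])
    acc_p <- oracle_loocv_accuracy(primary, params, classifier)
    acc_a <- if (is.null(aux)) 0
             else oracle_auxiliary_accuracy(primary, aux, params, classifier)
    c(acc_p = acc_p, acc_a = acc_a)
  }))
  best <- 1L
  for (i in seq_len(nrow(grid))[-1L]) {
    if (scores[i, 1L] > scores[best, 1L] ||
        (scores[i, 1L] == scores[best, 1L] && scores[i, 2L] > scores[best, 2L]))
      best <- i
  }
  list(index = best, acc_p = unname(scores[best, 1L]),
       acc_a = unname(scores[best, 2L]), scores = scores)
}
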