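#' Label-source abstraction for online sample requests
#'
#' A label source stands in for online stimulus presentation: `request(c)`
#' returns one new labeled feature vector of the requested class `c` (e.g. by
#' showing the user a stimulus of the corresponding difficulty level and
#' extracting the features of the evoked response). Synthetic sources are
#' built with [make_label_source()].
#'
#' @param request Function taking a class index and returning a numeric
#'   feature vector of length `F`.
#' @param n_classes Number of classes `K`.
#' @param feature_names Character vector of feature names (length `F`).
#' @return An object of class `label_source`.
#' @export
label_source <- function(request, n_classes, feature_names) {
  stopifnot(is.function(request))
  structure(list(request = request, n_classes = as.integer(n_classes),
                 feature_names = feature_names),
            class = "label_source")
}

#' Initialize a calibration run
#'
#' Requests the first `m0` primary samples round-robin over the `K` classes
#' in randomized order (for `m0 = K`, exactly one sample per class; for
#' `m0 = qK`, `q` randomized blocks of all classes), so that every class is
#' represented before the first hyperparameter selection. The class of the
#' final request becomes `last_class` for the no-consecutive-repeat rule.
#'
#' @param source A [label_source()].
#' @param cfg A [calibration_config()].
#' @return An object of class `calibration_state`: list with the growing
#'   `primary` [feature_dataset()], `last_class`, `params`, `acc_cv`,
#'   `per_class_acc` and the append-only `iteration_log`.
#' @export
initialize_calibration <- function(source, cfg) {
  stopifnot(inherits(source, "label_source"), inherits(cfg, "calibration_config"))
  K <- cfg$n_classes
  classes <- unlist(lapply(seq_len(cfg$m0 %/% K), function(b) sample.int(K)))
  rows <- lapply(classes, function(c) source$request(c))
  F_ <- length(rows[[1L]])
  X <- do.call(rbind, rows)
  colnames(X) <- source$feature_names
  primary <- feature_dataset("primary", X, classes,
                             feature_names = source$feature_names,
                             n_classes = K)
  structure(list(primary = primary, last_class = classes[length(classes)],
                 params = NULL, acc_cv = NA_real_, per_class_acc = rep(NA_real_, K),
                 iteration_log = list()),
            class = "calibration_state")
}

#' Run one online calibration session
#'
#' The four calibration strategies share one loop; flags in `cfg` switch the
#' two ingredients on and off:
#'
#' * **baseline** (`use_tl = FALSE, use_acs = FALSE`): hyperparameters by
#'   primary-only leave-one-out selection; the class of each new sample drawn
#'   uniformly at random (with replacement).
#' * **TL** (`use_tl = TRUE`): each iteration re-selects the most similar
#'   pool subject from the current primary class means and breaks
#'   selection ties with the auxiliary validation accuracy
#'   ([tl_select_params()]).
#' * **ACS** (`use_acs = TRUE`): the class of each new sample is drawn with
#'   probability proportional to inverse per-class accuracy, never repeating
#'   the previously requested class ([acs_probabilities()]); within an
#'   iteration the `l` draws apply the rule sequentially, and the constraint
#'   carries across iteration boundaries.
#' * **TL+ACS**: both.
#'
#' Each iteration: select parameters on the current `m` primary samples,
#' record per-class held-out accuracies, stop if the internal-CV accuracy has
#' reached `lambda` or no further sample may be added (`m + l > max_m`),
#' otherwise request `l` new samples and append them. With the default
#' `lambda = 1` the loop normally runs until `max_m` primary samples. The
#' per-class accuracies driving ACS are computed with the parameters selected
#' in the same iteration.
#'
#' @param source A [label_source()] for the new subject.
#' @param pool A [subject_pool()] of auxiliary subjects (required when
#'   `cfg$use_tl`), else `NULL`.
#' @param cfg A [calibration_config()]. When `cfg$seed` is set, the RNG is
#'   seeded at entry, making the whole trajectory reproducible.
#' @param test Optional held-out [feature_dataset()]; when given, the test
#'   accuracy under the current selection is recorded at every iteration
#'   (yielding a per-`m` learning curve for this run).
#' @return The final `calibration_state`. `iteration_log` is a data.frame
#'   with one row per parameter selection: `m`, selected parameters, `acc_p`,
#'   `acc_a`, per-class accuracies `a_1..a_K`, the requested classes of that
#'   iteration (empty on the terminal row) and, if `test` was given,
#'   `acc_test`. `n_iterations` counts the sample-generating iterations.
#' @export
run_calibration <- function(source, pool = NULL, cfg, test = NULL) {
  stopifnot(inherits(cfg, "calibration_config"))
  if (cfg$use_tl && (is.null(pool) || length(pool) == 0L))
    stop("transfer learning requires a non-empty auxiliary pool", call. = FALSE)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  K <- cfg$n_classes
  state <- initialize_calibration(source, cfg)
  state$config <- cfg
  log <- list()
  pool_profiles <- if (cfg$use_tl) lapply(pool, class_mean_profile) else NULL

  repeat {
    m <- nrow(state$primary$X)
    grid <- if (is.null(cfg$grid)) default_param_grid(cfg$classifier, m) else cfg$grid
    aux <- if (cfg$use_tl)
      select_auxiliary(state$primary, pool, .profiles = pool_profiles) else NULL
    sel <- tl_select_params(state$primary, aux, grid, cfg$classifier)
    a_c <- per_class_from_pred(sel$loocv_pred, state$primary$y, K)

    state$params <- sel$params
    state$acc_cv <- sel$acc_p
    state$per_class_acc <- a_c

    entry <- list(m = m, acc_p = sel$acc_p, acc_a = sel$acc_a,
                  params = sel$params, a_c = a_c, requested = integer(0))
    if (!is.null(test)) entry$acc_test <- evaluate_classifier(state, test)

    done <- sel$acc_p >= cfg$lambda || m + cfg$l > cfg$max_m
    if (!done) {
      req <- integer(cfg$l)
      for (j in seq_len(cfg$l)) {
        if (cfg$use_acs) {
          probs <- acs_probabilities(ifelse(is.na(a_c), 0, a_c),
                                     last_class = state$last_class)
          cls <- sample_next_class(probs)
        } else {
          cls <- sample.int(K, 1L)
        }
        x <- source$request(cls)
        state$primary$X <- rbind(state$primary$X, x)
        state$primary$y <- c(state$primary$y, cls)
        state$last_class <- cls
        req[j] <- cls
      }
      rownames(state$primary$X) <- NULL
      entry$requested <- req
    }
    log[[length(log) + 1L]] <- entry
    if (done) break
  }

  state$iteration_log <- iteration_log_frame(log, K, !is.null(test))
  state$n_iterations <- sum(vapply(log, function(e) length(e$requested) > 0L,
                                   logical(1)))
  state$config <- cfg
  state
}

iteration_log_frame <- function(log, K, has_test) {
  df <- data.frame(
    m = vapply(log, `[[`, integer(1), "m"),
    acc_p = vapply(log, `[[`, numeric(1), "acc_p"),
    acc_a = vapply(log, `[[`, numeric(1), "acc_a")
  )
  pn <- names(log[[1L]]$params)
  for (p in pn)
    df[[p]] <- vapply(log, function(e) as.numeric(e$params[[p]]), numeric(1))
  ac <- t(vapply(log, `[[`, numeric(K), "a_c"))
  colnames(ac) <- paste0("a_", seq_len(K))
  df <- cbind(df, ac)
  if (has_test)
    df$acc_test <- vapply(log, `[[`, numeric(1), "acc_test")
  df$requested <- I(lapply(log, `[[`, "requested"))
  df
}

#' Evaluate the calibrated classifier on held-out data
#'
#' Trains the classifier with the currently selected parameters on all
#' primary samples and reports the fraction of test samples classified
#' correctly (Euclidean-distance neighbours for kNN).
#'
#' @param state A `calibration_state` (from [run_calibration()]).
#' @param test A non-empty [feature_dataset()] disjoint from the primary set.
#' @return Accuracy in `[0, 1]`.
#' @export
evaluate_classifier <- function(state, test) {
  stopifnot(inherits(state, "calibration_state"), inherits(test, "feature_dataset"))
  if (nrow(test$X) == 0L) stop("test set is empty", call. = FALSE)
  if (is.null(state$params)) stop("no parameters selected yet", call. = FALSE)
  pred <- fit_predict(state$config$classifier %||% "knn",
                      state$primary$X, state$primary$y, state$params,
                      test$X, state$primary$n_classes)
  mean(pred == test$y)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.calibration_state <- function(x, ...) {
  cat(sprintf("<calibration_state> m = %d, acc_cv = %.3f\n",
              nrow(x$primary$X), x$acc_cv))
  cat("  params:", paste(names(x$params), unlist(x$params), sep = "=",
                         collapse = ", "), "\n")
  invisible(x)
}
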