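#' Specification of a synthetic multi-subject pool
#'
#' Describes a Gaussian class-conditional generator for multi-subject
#' physiological feature data with the structure the calibration methods
#' assume: subjects fall into clusters of mutually similar individuals,
#' between-subject distribution shifts are larger than the within-subject
#' class separation, and every subject's features are min-max normalized to
#' `[0, 1]`. Defaults emulate a study of 18 subjects with 3 task-difficulty
#' classes, 50 epochs per class and 29 features.
#'
#' The generative hierarchy is: cluster centre (sd `subject_shift` per
#' feature) -> cluster-level class means (offset sd `class_separation`) ->
#' subject offset shared across classes (sd `within_cluster_shift`) -> epoch
#' noise (sd `noise_sd`, optionally t-distributed for heavier tails). The
#' default `class_separation` was calibrated once by simulation so that a
#' baseline kNN classifier trained on 30 primary samples reaches roughly
#' 0.70-0.80 test accuracy, the regime where calibration-shortening methods
#' are interesting.
#'
#' @param n_subjects,n_classes,per_class,n_features Pool dimensions.
#' @param n_clusters Number of clusters of mutually similar subjects.
#' @param class_separation Scale of class-mean offsets (raw feature units).
#' @param subject_shift Scale of between-cluster (between-subject-group)
#'   shifts; larger than `class_separation` by default.
#' @param within_cluster_shift Scale of subject-specific offsets within a
#'   cluster; small relative to `subject_shift`.
#' @param noise_sd Epoch-level noise standard deviation.
#' @param heavy_tails If `TRUE`, epoch noise is drawn from a scaled
#'   t-distribution (df 4) instead of a Gaussian.
#' @param seed Optional integer seed used by [generate_pool()].
#' @return An object of class `pool_spec`.
#' @export
pool_spec <- function(n_subjects = 18L, n_classes = 3L, per_class = 50L,
                      n_features = 29L, n_clusters = 4L,
                      class_separation = 0.55, subject_shift = 2,
                      within_cluster_shift = 0.25, noise_sd = 1,
                      heavy_tails = FALSE, seed = NULL) {
  n_subjects <- as.integer(n_subjects); n_classes <- as.integer(n_classes)
  per_class <- as.integer(per_class); n_features <- as.integer(n_features)
  n_clusters <- as.integer(n_clusters)
  if (n_clusters > n_subjects) stop("n_clusters must be <= n_subjects", call. = FALSE)
  if (per_class < 1L) stop("per_class must be >= 1", call. = FALSE)
  if (min(class_separation, subject_shift, within_cluster_shift, noise_sd) < 0)
    stop("all scales must be >= 0", call. = FALSE)
  structure(list(n_subjects = n_subjects, n_classes = n_classes,
                 per_class = per_class, n_features = n_features,
                 n_clusters = n_clusters, class_separation = class_separation,
                 subject_shift = subject_shift,
                 within_cluster_shift = within_cluster_shift,
                 noise_sd = noise_sd, heavy_tails = isTRUE(heavy_tails),
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "pool_spec")
}

draw_noise <- function(n, sd, heavy) {
  if (heavy) sd * stats::rt(n, df = 4) / sqrt(2) else stats::rnorm(n, 0, sd)
}

# Subject-level generative models (class means in raw feature space).
draw_subject_models <- function(spec) {
  K <- spec$n_classes; F_ <- spec$n_features
  cluster_of <- sort(rep_len(seq_len(spec$n_clusters), spec$n_subjects))
  cluster_class_means <- lapply(seq_len(spec$n_clusters), function(g) {
    centre <- stats::rnorm(F_, 0, spec$subject_shift)
    t(vapply(seq_len(K), function(c)
      centre + stats::rnorm(F_, 0, spec$class_separation), numeric(F_)))
  })
  lapply(seq_len(spec$n_subjects), function(s) {
    g <- cluster_of[s]
    offset <- stats::rnorm(F_, 0, spec$within_cluster_shift)
    list(subject_id = sprintf("S%02d", s), cluster = g,
         class_means = sweep(cluster_class_means[[g]], 2L, -offset),
         noise_sd = spec$noise_sd, heavy_tails = spec$heavy_tails,
         n_classes = K,
         feature_names = paste0("f", seq_len(F_)))
  })
}

draw_subject_epochs <- function(model, per_class) {
  K <- model$n_classes; F_ <- ncol(model$class_means)
  y <- rep(seq_len(K), each = per_class)
  X <- model$class_means[y, , drop = FALSE] +
    matrix(draw_noise(length(y) * F_, model$noise_sd, model$heavy_tails),
           length(y), F_)
  feature_dataset(model$subject_id, X, y,
                  feature_names = model$feature_names, n_classes = K)
}

#' Generate a synthetic multi-subject pool
#'
#' Draws one [feature_dataset()] per subject from the hierarchy described in
#' [pool_spec()] and min-max normalizes every subject's features to `[0, 1]`.
#' The per-subject generative models are attached as `attr(pool, "models")`
#' so that fresh samples from the same subjects can be requested later via
#' [make_label_source()].
#'
#' @param spec A [pool_spec()].
#' @return A [subject_pool()] with a `models` attribute.
#' @export
generate_pool <- function(spec = pool_spec()) {
  stopifnot(inherits(spec, "pool_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  models <- draw_subject_models(spec)
  datasets <- lapply(models, function(mod)
    minmax_normalize(draw_subject_epochs(mod, spec$per_class)))
  pool <- subject_pool(datasets)
  attr(pool, "models") <- stats::setNames(
    models, vapply(models, `[[`, character(1), "subject_id"))
  pool
}

#' Build an online label source (and held-out test set) for one subject
#'
#' For a synthetic subject model, draws `n_request_per_class + n_test_per_class`
#' fresh epochs per class, min-max normalizes them jointly (emulating the
#' per-subject normalization applied to a full recording session), and splits
#' them into per-class request streams and a disjoint test set. Each
#' `request(c)` consumes the next unseen sample of class `c`; exhausting a
#' class's budget is an error.
#'
#' For a [feature_dataset()] (real recorded data), rows are permuted per
#' class and split the same way: up to `n_request_per_class` rows per class
#' serve requests, the remainder is the test set.
#'
#' @param x A subject model from `attr(pool, "models")`, or a
#'   [feature_dataset()].
#' @param n_request_per_class Per-class request budget; must cover the
#'   calibration maximum (worst case `max_m - 1` from one class).
#' @param n_test_per_class Held-out test epochs per class (synthetic models
#'   only; for datasets the remainder is used).
#' @param seed Optional seed for the draws/permutation.
#' @return List with elements `source` (a [label_source()]) and `test`
#'   (a [feature_dataset()]).
#' @export
make_label_source <- function(x, n_request_per_class = 30L,
                              n_test_per_class = 50L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (inherits(x, "feature_dataset")) {
    K <- x$n_classes
    take <- lapply(seq_len(K), function(c) {
      idx <- which(x$y == c)
      idx[sample.int(length(idx))]
    })
    req_idx <- lapply(take, function(idx)
      idx[seq_len(min(n_request_per_class, max(0L, length(idx) - 1L)))])
    test_idx <- sort(unlist(mapply(function(all, req) setdiff(all, req),
                                   take, req_idx, SIMPLIFY = FALSE)))
    streams <- lapply(req_idx, function(idx) x$X[idx, , drop = FALSE])
    test <- feature_dataset(x$subject_id, x$X[test_idx, , drop = FALSE],
                            x$y[test_idx], feature_names = x$feature_names,
                            n_classes = K)
    fn <- x$feature_names
  } else {
    K <- x$n_classes
    total <- n_request_per_class + n_test_per_class
    full <- minmax_normalize(draw_subject_epochs(x, total))
    streams <- vector("list", K)
    test_rows <- integer(0)
    for (c in seq_len(K)) {
      idx <- which(full$y == c)
      streams[[c]] <- full$X[idx[seq_len(n_request_per_class)], , drop = FALSE]
      test_rows <- c(test_rows, idx[n_request_per_class + seq_len(n_test_per_class)])
    }
    test <- feature_dataset(x$subject_id, full$X[test_rows, , drop = FALSE],
                            full$y[test_rows], feature_names = x$feature_names,
                            n_classes = K)
    fn <- x$feature_names
  }
  used <- integer(K)
  env <- environment()
  request <- function(class) {
    class <- as.integer(class)
    if (class < 1L || class > K) stop("requested class out of range", call. = FALSE)
    if (used[class] >= nrow(streams[[class]]))
      stop("label source budget exhausted for class ", class, call. = FALSE)
    env$used[class] <- used[class] + 1L
    streams[[class]][env$used[class], ]
  }
  list(source = label_source(request, K, fn), test = test)
}
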