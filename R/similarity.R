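#' Per-class mean feature vectors of one subject
#'
#' Summarises a subject by the arithmetic mean feature vector of each class.
#' These profiles are the basis of the subject-similarity heuristic used to
#' pick auxiliary training data: subjects whose class means are close are
#' expected to respond similarly.
#'
#' @param ds A [feature_dataset()].
#' @return An object of class `class_mean_profile`: list with `subject_id`,
#'   `means` (`K x F` matrix, `NA` rows for absent classes) and `counts`
#'   (epochs per class).
#' @export
class_mean_profile <- function(ds) {
  stopifnot(inherits(ds, "feature_dataset"))
  K <- ds$n_classes
  F_ <- ncol(ds$X)
  means <- matrix(NA_real_, K, F_, dimnames = list(NULL, ds$feature_names))
  counts <- tabulate(ds$y, K)
  for (c in seq_len(K)) {
    if (counts[c] > 0L)
      means[c, ] <- colMeans(ds$X[ds$y == c, , drop = FALSE])
  }
  structure(list(subject_id = ds$subject_id, means = means, counts = counts),
            class = "class_mean_profile")
}

#' Mean squared difference between two subjects' class-mean profiles
#'
#' The inter-subject distance is the mean, over classes observed in *both*
#' profiles and over features, of the squared difference of the class-mean
#' feature vectors. Averaging (rather than summing) over classes and features
#' makes the value scale-free in `K` and `F`; the arg-min over subjects is
#' unchanged either way.
#'
#' @param p,q `class_mean_profile` objects with the same number of features.
#' @return A single non-negative number; zero iff the shared-class means
#'   coincide.
#' @export
subject_distance <- function(p, q) {
  stopifnot(inherits(p, "class_mean_profile"), inherits(q, "class_mean_profile"))
  if (ncol(p$means) != ncol(q$means))
    stop("profiles have different numbers of features", call. = FALSE)
  shared <- which(p$counts > 0L & q$counts > 0L)
  if (length(shared) == 0L)
    stop("no class observed in both profiles", call. = FALSE)
  mean((p$means[shared, , drop = FALSE] - q$means[shared, , drop = FALSE])^2)
}

#' Select the most similar pool subject as auxiliary data
#'
#' Computes the new subject's class-mean profile from the current primary
#' samples, compares it with every pool subject's profile by
#' [subject_distance()] (restricted to classes the primary set has observed),
#' and returns the full dataset of the closest subject. A pool entry with the
#' same subject id as the primary data is excluded. Distance ties break
#' toward the lexicographically smallest subject id, so the choice is
#' deterministic.
#'
#' @param primary A [feature_dataset()] with at least one sample.
#' @param pool A [subject_pool()].
#' @param n_best Number of subjects to return merged as one dataset
#'   (default 1, the standard single-donor rule).
#' @param .profiles Optional precomputed list of pool profiles (named by
#'   subject id), used by the calibration loop to avoid recomputing the
#'   static pool means every iteration.
#' @return A [feature_dataset()] (for `n_best > 1`, row-bound donors with the
#'   id of the closest).
#' @export
select_auxiliary <- function(primary, pool, n_best = 1L, .profiles = NULL) {
  stopifnot(inherits(primary, "feature_dataset"))
  if (!inherits(pool, "subject_pool")) pool <- subject_pool(pool)
  cand <- pool[names(pool) != primary$subject_id]
  if (length(cand) == 0L)
    stop("pool contains no subject other than the primary one", call. = FALSE)
  pp <- class_mean_profile(primary)
  if (is.null(.profiles)) .profiles <- lapply(cand, class_mean_profile)
  d <- vapply(names(cand), function(id) subject_distance(pp, .profiles[[id]]),
              numeric(1))
  ord <- order(d, names(cand), method = "radix")
  picked <- cand[ord[seq_len(min(n_best, length(cand)))]]
  if (length(picked) == 1L) return(picked[[1L]])
  feature_dataset(picked[[1L]]$subject_id,
                  do.call(rbind, lapply(picked, `[[`, "X")),
                  unlist(lapply(picked, `[[`, "y"), use.names = FALSE),
                  feature_names = primary$feature_names,
                  n_classes = primary$n_classes)
}
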