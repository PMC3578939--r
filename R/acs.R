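#' Inverse-accuracy class-request probabilities
#'
#' The probability of requesting the next online training sample from class
#' `c` is proportional to the inverse of that class's current leave-one-out
#' accuracy `a_c`, under the assumption that poor class accuracy comes from
#' having observed too few samples of that class. The improved rule adds a
#' constraint that no two consecutive requests may come from the same class:
#' when `last_class` is given, that class gets probability 0 and the inverse
#' weights are renormalised over the remaining classes.
#'
#' Accuracies are floored at `eps` before inversion, so a class at accuracy 0
#' (including classes never observed, which callers encode as 0) is strongly
#' but not infinitely preferred.
#'
#' @param a Numeric vector of per-class accuracies in `[0, 1]`; `NA` entries
#'   (classes with no sample) are treated as 0.
#' @param last_class Index of the previously requested class, or `NULL` for
#'   the unconstrained rule.
#' @param eps Accuracy floor (default 0.01).
#' @return An object of class `class_probabilities`: list with the
#'   probability vector `p` (summing to 1, `p[last_class] == 0`) and
#'   `excluded`.
#' @examples
#' acs_probabilities(c(0.5, 0.25, 0.25))                  # (0.2, 0.4, 0.4)
#' acs_probabilities(c(0.5, 0.25, 0.25), last_class = 2)  # (1/3, 0, 2/3)
#' @export
acs_probabilities <- function(a, last_class = NULL, eps = 0.01) {
  if (!is.numeric(a) || length(a) < 1L)
    stop("`a` must be a numeric vector", call. = FALSE)
  a[is.na(a)] <- 0
  if (any(a < 0 | a > 1))
    stop("accuracies must be in [0, 1]", call. = FALSE)
  K <- length(a)
  if (!is.null(last_class)) {
    last_class <- as.integer(last_class)
    if (K < 2L)
      stop("exclusion of the last class requires K >= 2", call. = FALSE)
    if (last_class < 1L || last_class > K)
      stop("last_class out of range", call. = FALSE)
  }
  w <- 1 / pmax(a, eps)
  if (!is.null(last_class)) w[last_class] <- 0
  structure(list(p = w / sum(w), excluded = last_class),
            class = "class_probabilities")
}

#' Draw the class of the next training-sample request
#'
#' One draw from the categorical distribution of a
#' [acs_probabilities()] object; the excluded (previous) class can never be
#' drawn. Uses R's global random number generator, so runs are reproducible
#' under `set.seed()`.
#'
#' @param probs A `class_probabilities` object.
#' @return A class index in `1..K`.
#' @export
sample_next_class <- function(probs) {
  stopifnot(inherits(probs, "class_probabilities"))
  sample.int(length(probs$p), 1L, prob = probs$p)
}
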