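# Benchmarking harness: leave-one-subject-out learning curves over repeated
# calibration runs, samples-saved percentages relative to the baseline, and
# paired t-tests with Holm-corrected significance.

# Deterministic 31-bit seed derived from a stream of integers.
mix_seed <- function(...) {
  v <- as.double(c(...))
  s <- 0
  for (x in v) s <- (s * 69069 + x + 1) %% 2147483647
  as.integer(s)
}

method_flags <- function(method) {
  switch(method,
         baseline = c(FALSE, FALSE),
         tl = c(TRUE, FALSE),
         acs = c(FALSE, TRUE),
         tl_acs = c(TRUE, TRUE),
         stop("unknown method: ", method, call. = FALSE))
}

#' Repeated leave-one-subject-out learning curves
#'
#' Benchmarks calibration strategies on a subject pool: each subject in turn
#' plays the new user while the remaining subjects form the auxiliary
#' database. For every repeat a fresh label source and held-out test set are
#' drawn (from the subject's generative model if the pool carries one, else
#' by splitting the subject's recorded epochs), the calibration loop is run,
#' and the test accuracy is recorded after every iteration. All methods share
#' the same per-repeat seeds — identical initial samples and identical
#' per-class sample streams — so method contrasts are paired by construction.
#'
#' @param pool A [subject_pool()] (optionally with generative `models`
#'   attribute, as produced by [generate_pool()]).
#' @param methods Character subset of `baseline`, `tl`, `acs`, `tl_acs`.
#' @param classifier `"knn"` or `"svm"`.
#' @param l Samples generated per iteration.
#' @param n_repeats Repeats per subject (random initial samples and random
#'   request outcomes differ across repeats).
#' @param m0,max_m,lambda Calibration protocol, as in [calibration_config()].
#' @param seed Global seed; per-subject-per-repeat seeds are derived from it.
#' @param n_test_per_class Held-out test epochs per class for synthetic
#'   sources.
#' @return A named list of `learning_curve` objects, one per method: list
#'   with `method`, `classifier`, `l`, `m` (the per-iteration sample counts
#'   `m0, m0 + l, ...`), `mean` and `sd` accuracy across subjects (of
#'   per-subject repeat means), `subject_mean` (m x subject matrix) and
#'   `n_repeats`.
#' @export
learning_curves <- function(pool, methods = c("baseline", "tl", "acs", "tl_acs"),
                            classifier = c("knn", "svm"), l = 1L,
                            n_repeats = 10L, m0 = NULL, max_m = 30L,
                            lambda = 1, seed = 1L, n_test_per_class = 50L) {
  classifier <- match.arg(classifier)
  stopifnot(inherits(pool, "subject_pool"), n_repeats >= 1L)
  methods <- match.arg(methods, c("baseline", "tl", "acs", "tl_acs"),
                       several.ok = TRUE)
  K <- attr(pool, "n_classes")
  if (is.null(m0)) m0 <- K
  models <- attr(pool, "models")
  subjects <- names(pool)
  m_grid <- seq(m0, max_m, by = l)
  n_m <- length(m_grid)

  acc <- array(NA_real_,
               c(n_m, length(subjects), n_repeats, length(methods)),
               dimnames = list(NULL, subjects, NULL, methods))
  for (si in seq_along(subjects)) {
    s <- subjects[si]
    aux_pool <- subject_pool(pool[setdiff(subjects, s)])
    gen <- if (!is.null(models)) models[[s]] else pool[[s]]
    for (r in seq_len(n_repeats)) {
      run_seed <- mix_seed(seed, utf8ToInt(s), r)  # id-based: order-invariant
      for (mi in seq_along(methods)) {
        flags <- method_flags(methods[mi])
        src <- make_label_source(gen, n_request_per_class = max_m,
                                 n_test_per_class = n_test_per_class,
                                 seed = run_seed)
        cfg <- calibration_config(K, classifier, m0 = m0, l = l,
                                  max_m = max_m, lambda = lambda,
                                  use_tl = flags[1L], use_acs = flags[2L],
                                  seed = run_seed)
        st <- run_calibration(src$source, aux_pool, cfg, test = src$test)
        log <- st$iteration_log
        vals <- rep(NA_real_, n_m)
        vals[match(log$m, m_grid)] <- log$acc_test
        # A run that reached lambda early keeps its final classifier: carry
        # the terminal accuracy forward over the remaining sample counts.
        for (i in seq_len(n_m)[-1L])
          if (is.na(vals[i])) vals[i] <- vals[i - 1L]
        acc[, si, r, mi] <- vals
      }
    }
  }

  curves <- lapply(seq_along(methods), function(mi) {
    subj_mean <- apply(acc[, , , mi, drop = FALSE], c(1L, 2L), mean)
    structure(list(method = methods[mi], classifier = classifier, l = l,
                   m = m_grid, mean = rowMeans(subj_mean),
                   sd = apply(subj_mean, 1L, stats::sd),
                   subject_mean = subj_mean, n_repeats = n_repeats),
              class = "learning_curve")
  })
  stats::setNames(curves, methods)
}

#' @export
print.learning_curve <- function(x, ...) {
  cat(sprintf("<learning_curve> %s / %s, l = %d, %d repeats; m in [%d, %d]\n",
              x$method, x$classifier, x$l, x$n_repeats, min(x$m), max(x$m)))
  cat(sprintf("  accuracy %.3f -> %.3f\n", x$mean[1L], x$mean[length(x$mean)]))
  invisible(x)
}

# Smallest (interpolated) m at which `curve` reaches accuracy `target`.
invert_curve <- function(m, acc, target) {
  j <- which(acc >= target)[1L]
  if (is.na(j)) return(NA_real_)
  if (j == 1L) return(m[1L])
  m[j - 1L] + (target - acc[j - 1L]) / (acc[j] - acc[j - 1L]) * (m[j] - m[j - 1L])
}

#' Primary training samples saved relative to the baseline
#'
#' For each sample count `m` of the improved method's curve, finds `n_b`,
#' the (linearly interpolated) smallest baseline sample count whose mean
#' accuracy matches the improved method's accuracy at `m`, and reports the
#' percentage saved, `(n_b - m) / n_b * 100`. Where even the baseline's
#' largest `m` does not reach the improved accuracy, the value is undefined
#' (`NA`). Savings are floored at zero: where the baseline reaches the target
#' accuracy with fewer samples than the improved method (e.g. at a dip of a
#' non-monotone curve, or comparing a curve against itself), the saving is
#' reported as 0 rather than a negative percentage.
#'
#' @param improved,baseline `learning_curve` objects on the same `m` grid.
#' @return An object of class `savings_curve`: list with `m`, `percent`
#'   (`NA` where undefined) and `n_b`.
#' @export
samples_saved <- function(improved, baseline) {
  stopifnot(inherits(improved, "learning_curve"),
            inherits(baseline, "learning_curve"))
  if (!identical(improved$m, baseline$m))
    stop("curves are on different m grids", call. = FALSE)
  n_b <- vapply(seq_along(improved$m), function(i) {
    invert_curve(baseline$m, baseline$mean, improved$mean[i])
  }, numeric(1))
  percent <- ifelse(is.na(n_b), NA_real_,
                    pmax(0, (n_b - improved$m) / n_b * 100))
  structure(list(m = improved$m, percent = percent, n_b = n_b,
                 method = improved$method),
            class = "savings_curve")
}

#' Paired t-test between two per-m accuracy curves
#'
#' Classical two-sided paired t-test over the per-`m` mean-accuracy pairs of
#' two methods; with `P` curve points the degrees of freedom are `P - 1`
#' (e.g. 26 when 27 sample counts are compared). Zero-variance differences
#' are an error rather than a silent `p = 0`.
#'
#' @param a,b Numeric vectors of equal length (per-`m` mean accuracies).
#' @return List with `t`, `df`, `p`.
#' @export
paired_t_test <- function(a, b) {
  if (length(a) != length(b) || length(a) < 2L)
    stop("need two equal-length vectors of length >= 2", call. = FALSE)
  d <- a - b
  if (stats::sd(d) == 0)
    stop("zero-variance differences: paired t-test undefined", call. = FALSE)
  ht <- stats::t.test(a, b, paired = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Holm-modified Bonferroni correction
#'
#' Step-down multiple-testing procedure: sort the p-values ascending, reject
#' the `i`-th smallest while it is at most `alpha / (n - i + 1)`, and stop at
#' the first failure. Rejections are mapped back to the input order. The
#' rejection set always contains the classical Bonferroni rejections and is
#' contained in the uncorrected `alpha`-level rejections.
#'
#' @param pvals Numeric vector of p-values in `[0, 1]` (may be empty).
#' @param alpha Family-wise error level (default 0.05).
#' @return Logical vector of rejection flags, same order as `pvals`.
#' @export
holm_bonferroni <- function(pvals, alpha = 0.05) {
  if (length(pvals) == 0L) return(logical(0))
  if (any(pvals < 0 | pvals > 1)) stop("p-values must be in [0, 1]", call. = FALSE)
  stats::p.adjust(pvals, method = "holm") <= alpha
}

#' Compare two learning curves (paired t, subject diagnostics)
#'
#' Convenience wrapper pairing two curves on a common range of sample counts
#' (by default from `m0 + l` upward, i.e. the iterations that actually
#' generated samples) and running [paired_t_test()] on the pool-averaged
#' accuracies; per-subject mean differences are attached as a secondary
#' diagnostic.
#'
#' @param a,b `learning_curve` objects on the same grid.
#' @param m_min Smallest `m` included (default: second grid point).
#' @return List with `t`, `df`, `p`, `mean_diff`, `m_used` and
#'   `subject_diff`.
#' @export
compare_curves <- function(a, b, m_min = NULL) {
  stopifnot(identical(a$m, b$m))
  if (is.null(m_min)) m_min <- a$m[2L]
  keep <- a$m >= m_min
  tt <- paired_t_test(a$mean[keep], b$mean[keep])
  tt$mean_diff <- mean(a$mean[keep] - b$mean[keep])
  tt$m_used <- a$m[keep]
  tt$subject_diff <- colMeans(a$subject_mean[keep, , drop = FALSE] -
                                b$subject_mean[keep, , drop = FALSE])
  tt
}
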