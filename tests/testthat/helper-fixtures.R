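# Small programmatic fixtures shared across the suite.

make_ds <- function(X, y, id = "s1", K = NULL) {
  if (!is.matrix(X)) X <- matrix(X, ncol = 1L)
  feature_dataset(id, X, y, n_classes = K)
}

# Random dataset with every class represented at least once.
random_ds <- function(n, F_ = 3L, K = 3L, id = "s1") {
  y <- c(seq_len(K), sample.int(K, n - K, replace = TRUE))
  make_ds(matrix(runif(n * F_), n, F_), y, id = id, K = K)
}

# Two far-apart point clusters per class: trivially separable.
separable_ds <- function(n_per_class = 4L, K = 2L, id = "s1") {
  y <- rep(seq_len(K), each = n_per_class)
  X <- cbind(10 * y + stats::rnorm(length(y), 0, 0.1),
             stats::rnorm(length(y), 0, 0.1))
  make_ds(X, y, id = id, K = K)
}

# A label source serving rows of a fixed matrix per class, plus its test set.
fixed_source <- function(class_rows, feature_names = NULL) {
  K <- length(class_rows)
  if (is.null(feature_names))
    feature_names <- paste0("f", seq_len(ncol(class_rows[[1L]])))
  used <- integer(K)
  env <- environment()
  label_source(function(class) {
    env$used[class] <- env$used[class] + 1L
    class_rows[[class]][env$used[class], ]
  }, K, feature_names)
}

# Tiny synthetic pool for fast integration tests.
small_pool <- function(n_subjects = 4L, seed = 99L, F_ = 5L, ...) {
  generate_pool(pool_spec(n_subjects = n_subjects, n_clusters = 2L,
                          per_class = 20L, n_features = F_,
                          seed = seed, ...))
}

# Synthetic multichannel recording channels for feature-extraction tests.
all_channels <- function(n, rate) {
  t <- seq(0, (n - 1) / rate, by = 1 / rate)
  ch <- c(stats::setNames(lapply(1:7, function(i) sin(2 * pi * 10 * t + i) +
                                   0.1 * stats::rnorm(n)),
                          c("Fp1", "Fp2", "Fz", "Cz", "Pz", "O1", "O2")),
          list(EOG = 0.05 * stats::rnorm(n), EDA = 0.4 + 0.01 * t,
               RSP = sin(2 * pi * t / 4)))
  ecg <- rep(0, n)
  for (pk in seq(0.2, (n - 1) / rate, by = 0.8)) {
    idx <- which(abs(t - pk) <= 0.03)
    ecg[idx] <- pmax(ecg[idx], 1 - abs(t[idx] - pk) / 0.03)
  }
  c(ch, list(ECG = ecg))
}

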