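test_that("epoching cuts 3-second stimulus-locked windows", {
  rate <- 512
  n <- 6 * rate
  rec <- raw_recording(rate, all_channels(n, rate),
                       data.frame(time = 2.0, label = 1L))
  eps <- epoch_signals(rec)
  expect_length(eps, 1L)
  expect_length(eps[[1L]]$channels$Fp1, 1536L)   # 3 s at 512 Hz

  # an event without 1 s of pre-stimulus context is skipped with a warning
  rec2 <- raw_recording(rate, all_channels(n, rate),
                        data.frame(time = c(0.5, 2.0), label = c(1L, 2L)))
  expect_warning(eps2 <- epoch_signals(rec2), "skipped")
  expect_length(eps2, 1L)
  expect_equal(eps2[[1L]]$label, 2L)

  # 150 clean events -> 150 epochs, ordered by time
  rate <- 32
  n <- 460 * rate
  times <- seq(2, by = 3, length.out = 150)
  rec3 <- raw_recording(rate, all_channels(n, rate),
                        data.frame(time = sample(times), label = rep(1:3, 50)))
  eps3 <- epoch_signals(rec3)
  expect_length(eps3, 150L)
  expect_equal(vapply(eps3, `[[`, numeric(1), "time"), times)
})

test_that("EOG regression removes the projected artifact", {
  set.seed(8)
  eog <- stats::rnorm(256)
  expect_equal(remove_eog(2 * eog, eog), rep(0, 256))

  # orthogonal (uncorrelated) channel passes through unchanged
  x <- stats::rnorm(256)
  x_orth <- x - (stats::cov(x, eog) / stats::var(eog)) * eog
  expect_equal(remove_eog(x_orth, eog), x_orth)

  # least-squares property: the residual is uncorrelated with the EOG
  for (i in 1:10) {
    ch <- stats::rnorm(128) + runif(1, -2, 2) * eog[1:128]
    res <- remove_eog(ch, eog[1:128])
    expect_lt(abs(stats::cov(res, eog[1:128])), 1e-10)
  }

  # zero-variance EOG leaves the input unchanged
  expect_equal(remove_eog(x, rep(1, 256)), x)
  expect_error(remove_eog(x, eog[1:10]), "lengths differ")
})

test_that("band power concentrates where the signal lives", {
  rate <- 128
  t <- seq(0, 3, by = 1 / rate)
  s <- sin(2 * pi * 10 * t)
  p <- sapply(c("theta", "alpha", "beta"), function(b) band_power(s, b, rate))
  expect_gt(p["alpha"], 10 * p["theta"])
  expect_gt(p["alpha"], 10 * p["beta"])

  expect_equal(band_power(rep(0, 256), "alpha", rate), 0)

  # flat-spectrum oracle: band powers proportional to bandwidth within 20%
  set.seed(4)
  x <- stats::rnorm(200 * rate)
  p <- sapply(c("theta", "alpha", "beta"), function(b) band_power(x, b, rate))
  expect_lt(abs(p["theta"] / p["alpha"] / (3.5 / 6) - 1), 0.2)
  expect_lt(abs(p["beta"] / p["alpha"] - 1), 0.2)

  # offset invariance after detrending; non-negativity
  expect_equal(band_power(s + 5, "alpha", rate), p2 <- band_power(s, "alpha", rate))
  expect_gte(p2, 0)
  expect_error(band_power(s, c(10, 100), rate), "Nyquist")
  expect_error(band_power(s[1:50], "alpha", rate), "shorter")
})

test_that("peripheral features summarise EDA, RSP and ECG", {
  rate <- 500
  n <- 3 * rate
  ch <- all_channels(n, rate)
  t <- seq(0, (n - 1) / rate, by = 1 / rate)
  ep <- list(channels = c(ch[c("ECG")], list(EDA = rep(0.4, n),
                                             RSP = sin(2 * pi * t))),
             rate = rate, label = 1L)
  pf <- peripheral_features(ep)
  expect_equal(unname(pf[c("EDA_min", "EDA_max", "EDA_mean")]), rep(0.4, 3))
  expect_equal(unname(pf["RSP_min"]), -1, tolerance = 1e-3)
  expect_equal(unname(pf["RSP_max"]), 1, tolerance = 1e-3)
  expect_equal(unname(pf["RSP_mean"]), 0, tolerance = 1e-2)
  # hand-placed R waves 0.8 s apart
  expect_equal(unname(pf["ECG_beats"]), 4)
  expect_equal(unname(pf["ECG_ibi"]), 0.8)

  # unreadable ECG: flagged sentinel, not a crash
  ep$channels$ECG <- rep(0, n)
  expect_warning(pf2 <- peripheral_features(ep), "R peaks")
  expect_equal(unname(pf2["ECG_ibi"]), 3)
  expect_true(isTRUE(attr(pf2, "ibi_flagged")))
  expect_error(peripheral_features(list(channels = list(EDA = 1:5), rate = 5)),
               "lacks")
})

test_that("the assembled vector follows the frozen 29-feature schema", {
  rate <- 64
  n <- 3 * rate
  set.seed(12)
  ep <- list(channels = all_channels(n, rate), rate = rate, label = 2L)
  v <- assemble_feature_vector(ep)
  expect_length(v, 29L)
  expect_identical(names(v), feature_schema())
  expect_identical(feature_schema()[1:8],
                   c("EDA_min", "EDA_max", "EDA_mean", "RSP_min", "RSP_max",
                     "RSP_mean", "ECG_beats", "ECG_ibi"))
  expect_identical(feature_schema()[9:11], c("Fp1_theta", "Fp1_alpha", "Fp1_beta"))

  # determinism: identical epochs give identical vectors
  expect_identical(v, assemble_feature_vector(ep))

  # the EEG block equals direct band-power recomputation (raw channels)
  v_raw <- assemble_feature_vector(ep, eog_correct = FALSE, filter_eeg = FALSE)
  direct <- unlist(lapply(c("Fp1", "Fp2", "Fz", "Cz", "Pz", "O1", "O2"),
                          function(site) sapply(c("theta", "alpha", "beta"),
                                                function(b) band_power(ep$channels[[site]], b, rate))))
  expect_equal(unname(v_raw[9:29]), unname(direct))
  expect_error(assemble_feature_vector(list(channels = list(), rate = rate)),
               "lacks")
})

test_that("the extraction pipeline yields a valid normalized dataset", {
  rate <- 64
  set.seed(3)
  n <- 40 * rate
  times <- seq(2, by = 3.5, length.out = 10)
  rec <- raw_recording(rate, all_channels(n, rate),
                       data.frame(time = times, label = rep(1:2, 5)))
  ds <- extract_features(rec, "subjA")
  expect_s3_class(ds, "feature_dataset")
  expect_equal(dim(ds$X), c(10L, 29L))
  expect_identical(ds$feature_names, feature_schema())
  norm <- minmax_normalize(ds)
  expect_true(all(norm$X >= 0 & norm$X <= 1))
})

test_that("min-max normalization is an idempotent affine map to [0, 1]", {
  ds <- make_ds(cbind(c(2, 4, 6), c(7, 7, 7)), c(1L, 2L, 2L))
  norm <- minmax_normalize(ds)
  expect_equal(unname(norm$X[, 1L]), c(0, 0.5, 1))
  expect_equal(unname(norm$X[, 2L]), c(0, 0, 0))   # constant column -> 0

  set.seed(6)
  ds2 <- random_ds(20L, F_ = 6L)
  n1 <- minmax_normalize(ds2)
  expect_equal(unname(apply(n1$X, 2, min)), rep(0, 6))
  expect_equal(unname(apply(n1$X, 2, max)), rep(1, 6))
  expect_equal(minmax_normalize(n1), n1)
  expect_error(minmax_normalize(make_ds(matrix(1, 1, 1), 1L)), "at least 2")
})
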