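test_that("leave-one-out accuracy matches hand-worked cases", {
  set.seed(2)
  ds <- separable_ds()
  expect_equal(loocv_accuracy(ds, list(k = 1), "knn"), 1.0)

  # four points on a line, labels (1,1,2,2): with k = 3 every held-out
  # point's neighbours are majority-opposite 2:1, so every fold fails
  line <- make_ds(matrix(c(0, 0.1, 1, 1.1), 4, 1), c(1L, 1L, 2L, 2L))
  expect_equal(loocv_accuracy(line, list(k = 3), "knn"), 0.0)
  expect_equal(loocv_accuracy(line, list(k = 1), "knn"), 1.0)

  expect_error(loocv_accuracy(line, list(k = 4), "knn"), "n - 1")
  expect_error(loocv_accuracy(make_ds(matrix(1, 1, 1), 1L),
                              list(k = 1), "knn"), "at least 2")
})

test_that("LOOCV accuracy equals the brute-force oracle on random instances", {
  set.seed(31)
  for (i in 1:50) {
    n <- sample(4:12, 1L)
    ds <- random_ds(n, F_ = sample(2:5, 1L))
    k <- sample(seq(1L, n - 1L, by = 2L), 1L)
    expect_equal(loocv_accuracy(ds, list(k = k), "knn"),
                 oracle_loocv_accuracy(ds, list(k = k), "knn"))
  }
  # RBF SVM path against a direct train-and-score loop
  for (i in 1:5) {
    ds <- random_ds(8L, F_ = 3L)
    params <- list(C = 2^sample(-2:6, 1L), gamma = 2^sample(-6:1, 1L))
    expect_equal(loocv_accuracy(ds, params, "svm"),
                 oracle_loocv_accuracy(ds, params, "svm"))
  }
})

test_that("per-class accuracies partition the overall accuracy", {
  set.seed(17)
  ds <- separable_ds(n_per_class = 3L, K = 3L)
  expect_equal(per_class_loocv_accuracy(ds, list(k = 1), "knn"), rep(1, 3))

  for (i in 1:30) {
    n <- sample(5:12, 1L)
    ds <- random_ds(n)
    k <- sample(c(1L, 3L), 1L)
    a_c <- per_class_loocv_accuracy(ds, list(k = k), "knn")
    expect_equal(a_c, oracle_per_class_accuracy(ds, list(k = k), "knn"))
    counts <- tabulate(ds$y, 3L)
    expect_equal(sum(a_c * counts, na.rm = TRUE) / n,
                 loocv_accuracy(ds, list(k = k), "knn"))
  }

  # a class absent from the dataset is reported as NA
  ds2 <- make_ds(matrix(runif(8), 4, 2), c(1L, 1L, 2L, 2L), K = 3L)
  expect_true(is.na(per_class_loocv_accuracy(ds2, list(k = 1), "knn")[3L]))
})

test_that("auxiliary accuracy scores a primary-trained classifier", {
  set.seed(23)
  ds <- separable_ds()
  expect_equal(auxiliary_accuracy(ds, ds, list(k = 1), "knn"), 1.0)

  # adversarially permuted labels on a separable problem: nothing is right
  wrong <- ds; wrong$y <- 3L - wrong$y
  expect_lte(auxiliary_accuracy(ds, wrong, list(k = 1), "knn"), 0.5)

  for (i in 1:30) {
    primary <- random_ds(sample(4:10, 1L), F_ = 4L)
    aux <- random_ds(sample(5:12, 1L), F_ = 4L, id = "aux")
    k <- sample(c(1L, 3L), 1L)
    expect_equal(auxiliary_accuracy(primary, aux, list(k = k), "knn"),
                 oracle_auxiliary_accuracy(primary, aux, list(k = k), "knn"))
  }
  expect_error(auxiliary_accuracy(ds, make_ds(matrix(0, 0, 2), integer(0), K = 2L),
                                  list(k = 1), "knn"), "empty")
})

test_that("parameter selection maximises acc_p, then acc_a, then grid order", {
  set.seed(5)
  ds <- random_ds(6L)
  single <- data.frame(k = 3L)
  expect_equal(tl_select_params(ds, NULL, single, "knn")$params$k, 3L)

  # frozen instance where k = 1 and k = 3 tie on primary LOOCV but the
  # auxiliary validation data favour k = 3
  set.seed(7)
  n <- 6L
  y <- c(1L, 2L, 3L, sample(3, n - 3L, replace = TRUE))
  primary <- make_ds(matrix(runif(n * 2), n, 2), y, K = 3L)
  ya <- rep(1:3, each = 12L)
  aux <- make_ds(matrix(runif(72), 36, 2) * 0.2 +
                   matrix(c(0.2, 0.5, 0.8)[ya], 36, 2), ya, id = "aux", K = 3L)
  grid <- data.frame(k = c(1L, 3L))
  p1 <- loocv_accuracy(primary, list(k = 1), "knn")
  p3 <- loocv_accuracy(primary, list(k = 3), "knn")
  expect_equal(p1, p3)   # the planted tie
  expect_gt(auxiliary_accuracy(primary, aux, list(k = 3), "knn"),
            auxiliary_accuracy(primary, aux, list(k = 1), "knn"))
  sel <- tl_select_params(primary, aux, grid, "knn")
  expect_equal(sel$params$k, 3L)
  # without auxiliary data the tie falls through to the smallest k
  expect_equal(tl_select_params(primary, NULL, grid, "knn")$params$k, 1L)
})

test_that("selection equals the exhaustive double-key arg-max oracle", {
  set.seed(41)
  for (i in 1:100) {
    n <- sample(4:12, 1L)
    primary <- random_ds(n, F_ = sample(2:5, 1L))
    aux <- if (i %% 4 == 0) NULL else random_ds(sample(6:12, 1L), F_ = ncol(primary$X), id = "aux")
    ks <- seq(1L, n - 1L, by = 2L)
    grid <- data.frame(k = ks[seq_len(min(length(ks), 10L))])
    sel <- tl_select_params(primary, aux, grid, "knn")
    orc <- oracle_tl_select(primary, aux, grid, "knn")
    expect_equal(sel$index, orc$index)
    expect_equal(sel$acc_p, orc$acc_p)
    expect_equal(sel$acc_a, orc$acc_a)
    # contract: selected params always lie in the grid
    expect_true(sel$params$k %in% grid$k)
    # monotone tie rule: no tied grid point has strictly larger acc_a
    tied <- which(orc$scores[, 1L] == orc$acc_p)
    expect_true(all(orc$scores[tied, 2L] <= orc$acc_a))
  }
})

test_that("SVM selection agrees with the oracle on small grids", {
  set.seed(59)
  grid <- expand.grid(gamma = 2^c(-4, 0), C = 2^c(0, 4))
  grid <- data.frame(C = grid$C, gamma = grid$gamma)
  for (i in 1:8) {
    primary <- random_ds(7L, F_ = 3L)
    aux <- random_ds(9L, F_ = 3L, id = "aux")
    sel <- tl_select_params(primary, aux, grid, "svm")
    orc <- oracle_tl_select(primary, aux, grid, "svm")
    expect_equal(sel$index, orc$index)
    expect_equal(sel$acc_p, orc$acc_p)
  }
})

test_that("default grids respect the sample-size cap and ordering", {
  expect_equal(default_param_grid("knn", 4)$k, c(1L, 3L))
  expect_equal(default_param_grid("knn", 30)$k, seq(1L, 15L, by = 2L))
  expect_equal(default_param_grid("knn", 2)$k, 1L)
  g <- default_param_grid("svm", 10)
  expect_equal(nrow(g), 11L * 10L)
  expect_true(!is.unsorted(g$C))                  # C slowest, ascending
  expect_equal(g$gamma[1:2], 2^c(-15, -13))       # gamma ascending within C
})
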