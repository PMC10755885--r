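test_that("windowing produces exact non-overlapping chunks", {
  x <- seq_len(4097)
  chunks <- window_segment(x, 178)
  expect_length(chunks, 23)
  expect_equal(chunks[[1]], 1:178)
  expect_equal(unlist(chunks), x[1:(23 * 178)])  # prefix round-trip

  expect_equal(window_segment(1:178, 178), list(1:178))

  two <- window_segment(1:356, 178)
  expect_length(two, 2)
  expect_equal(two[[2]], 179:356)

  expect_warning(short <- window_segment(1:50, 178), "no chunks")
  expect_length(short, 0)
})

test_that("dataset assembly counts, labels and order are exact", {
  ds <- tiny_ds()  # 5 subsets x 4 segments x 4097 samples
  expect_equal(nrow(ds$X), 5 * 4 * 23)
  expect_equal(ncol(ds$X), 178)
  expect_equal(as.vector(table(ds$y)), rep(4 * 23, 5))
  expect_equal(sort(unique(ds$y)), 0:4)
  # A -> 0 ... E -> 4 in subset order
  expect_equal(unique(ds$subset[ds$y == 0]), "A")
  expect_equal(unique(ds$subset[ds$y == 4]), "E")

  small <- build_windowed_dataset(list(list(rnorm(178), rnorm(178))))
  expect_equal(nrow(small$X), 2)

  expect_error(
    build_windowed_dataset(list(A = list(rnorm(100)))),
    "segment 1 of subset A")
})

test_that("chunk conservation holds across segment lengths", {
  set.seed(3)
  lens <- sample(150:900, 12)
  segs <- lapply(lens, rnorm)
  ds <- build_windowed_dataset(list(S = segs), chunk_len = 100)
  expect_equal(nrow(ds$X), sum(floor(lens / 100)))
})

test_that("stratified split is exhaustive, disjoint and proportionate", {
  ds <- tiny_ds()
  sp <- split_dataset(ds, 0.8, seed = 4)
  expect_equal(nrow(sp$train$X) + nrow(sp$test$X), nrow(ds$X))
  per_class <- 4 * 23
  expect_equal(as.vector(table(sp$train$y)), rep(round(0.8 * per_class), 5))
  # stratification: train proportions match global within one row per class
  expect_true(all(abs(table(sp$train$y) / length(sp$train$y) - 0.2) <
                    1 / length(sp$train$y)))

  all_rows <- rbind(sp$train$X, sp$test$X)
  expect_equal(nrow(unique(cbind(all_rows[, 1:4]))), nrow(ds$X))

  full <- split_dataset(ds, 1.0, seed = 1)
  expect_equal(nrow(full$test$X), 0)

  s1 <- split_dataset(ds, 0.8, seed = 1)
  s2 <- split_dataset(ds, 0.8, seed = 2)
  expect_false(identical(s1$train$segment, s2$train$segment))
  expect_equal(table(s1$train$y), table(s2$train$y))
})

test_that("segment-level split keeps whole segments on one side", {
  ds <- tiny_ds()
  sp <- split_dataset(ds, 0.75, seed = 6, by_segment = TRUE)
  expect_length(intersect(unique(sp$train$segment),
                          unique(sp$test$segment)), 0)
  expect_equal(length(unique(sp$train$segment)), 5 * 3)  # 3 of 4 per class
})

test_that("k-fold indices are stratified, disjoint and exhaustive", {
  y <- rep(0:1, c(46, 69))
  folds <- kfold_indices(y, k = 10, seed = 3)
  expect_length(folds, 10)
  expect_equal(sort(unlist(folds)), seq_along(y))
  expect_equal(sum(vapply(folds, length, integer(1))), length(y))
  for (f in folds) {
    per_class <- table(factor(y[f], levels = 0:1))
    expect_true(all(per_class >= floor(c(46, 69) / 10)))
    expect_true(all(per_class <= ceiling(c(46, 69) / 10)))
  }
  expect_identical(kfold_indices(y, 10, seed = 3),
                   kfold_indices(y, 10, seed = 3))
  # leave-one-out on a tiny fixture
  loo <- kfold_indices(rep(0L, 5), k = 5, seed = 1)
  expect_true(all(vapply(loo, length, integer(1)) == 1))
  expect_error(kfold_indices(y, k = 1), "k must be")
  expect_error(kfold_indices(rep(0L, 3), k = 5), "fewer rows")
})

test_that("group expressions select and relabel sub-experiments", {
  ds <- tiny_ds()
  per_subset <- 4 * 23
  ae <- subset_selector(ds, "A vs E")
  expect_equal(nrow(ae$X), 2 * per_subset)
  expect_equal(sort(unique(ae$y)), 0:1)
  expect_equal(unique(ae$subset[ae$y == 1]), "E")

  imb <- subset_selector(ds, "AB vs CDE")
  expect_equal(sum(imb$y == 0), 2 * per_subset)
  expect_equal(sum(imb$y == 1), 3 * per_subset)

  three <- subset_selector(ds, "A vs CD vs E")
  expect_equal(sort(unique(three$y)), 0:2)

  expect_error(subset_selector(ds, "A vs A"), "disjoint")
  expect_error(subset_selector(ds, "A"), "at least two")
})

test_that("windowed datasets round-trip through their delimited form", {
  ds <- build_windowed_dataset(list(A = list(rnorm(356)),
                                    B = list(rnorm(356))),
                               chunk_len = 178)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_windowed_dataset(ds, path)
  back <- read_windowed_dataset(path)
  expect_equal(back$X, ds$X, tolerance = 1e-12, ignore_attr = TRUE)
  expect_identical(back$y, ds$y)
  expect_identical(back$chunk_len, ds$chunk_len)
})
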