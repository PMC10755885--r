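test_that("the optimized vector reproduces the published architecture", {
  spec <- table2_spec()
  expect_length(spec$layers, 26)
  expect_equal(spec$filters, c(50L, 40L, 35L, 30L, 25L, 20L))
  kinds <- vapply(spec$layers, `[[`, character(1), "kind")
  expect_equal(kinds[1:4], c("conv", "batch_norm", "dropout", "max_pool"))
  expect_equal(kinds[25:26], c("flatten", "dense"))
  sh <- spec$shapes
  expect_equal(sh$out_len[sh$kind == "conv"][1], 178)  # same padding
  expect_equal(sh$out_len[4], 89)    # first pool: ceil(178/2)
  expect_equal(sh$out_len[12], 23)   # third pool: ceil(45/2), not floor
  expect_equal(sh$out_len[16], 12)   # ceil(23/2)
  expect_equal(sh$out_len[25], 60)   # flatten 3 x 20
  expect_equal(sh$out_len[26], 5)    # dense softmax head
})

test_that("layer count and block structure follow 4b + 2", {
  for (b in c(1L, 2L, 4L, 6L)) {
    spec <- build_model_spec(hp_vector(), n_blocks = b)
    expect_length(spec$layers, 4 * b + 2)
  }
  one <- build_model_spec(hp_vector(n_kernels = 40), n_blocks = 1)
  expect_equal(vapply(one$layers, `[[`, character(1), "kind"),
               c("conv", "batch_norm", "dropout", "max_pool",
                 "flatten", "dense"))
})

test_that("the filter schedule decrements and clamps at one", {
  spec <- build_model_spec(hp_vector(n_kernels = 40), n_blocks = 6)
  expect_equal(spec$filters, c(40L, 30L, 25L, 20L, 15L, 10L))
  deep <- build_model_spec(hp_vector(n_kernels = 40), n_blocks = 10)
  expect_true(all(deep$filters >= 1))
})

test_that("sequence length is non-increasing and stays positive", {
  set.seed(12)
  for (i in 1:20) {
    hp <- decode_position(runif(6, c(40, 1, 0, 0, -5, 2),
                                c(100, 20, 2, 0.6, 0, 20)))
    sh <- infer_shapes(build_model_spec(hp))$shapes
    lens <- sh$out_len[sh$kind %in% c("conv", "batch_norm", "dropout",
                                      "max_pool")]
    expect_true(all(diff(lens) <= 0))
    expect_true(all(lens >= 1))
  }
})

test_that("instantiated models emit normalized probabilities, seeded", {
  spec <- build_model_spec(hp_vector(), n_blocks = 2, input_len = 64,
                           n_classes = 3)
  m1 <- instantiate(spec, seed = 21)
  X <- matrix(0, nrow = 4, ncol = 64)
  p <- predict(m1, X)
  expect_equal(dim(p), c(4, 3))
  expect_equal(rowSums(p), rep(1, 4), tolerance = 1e-6)

  m2 <- instantiate(spec, seed = 21)
  expect_identical(predict(m1, X), predict(m2, X))
  m3 <- instantiate(spec, seed = 22)
  X2 <- matrix(rnorm(4 * 64), 4)
  expect_false(identical(predict(m1, X2), predict(m3, X2)))
})

test_that("native shape inference matches the engine's reported shapes", {
  spec <- table2_spec()
  eng <- model_shapes(instantiate(spec, seed = 1))
  sh <- spec$shapes
  expect_equal(unname(eng[, "length"]), sh$out_len)
  tensor <- !sh$kind %in% c("flatten", "dense")
  expect_equal(unname(eng[tensor, "channels"]), sh$out_ch[tensor])
})

test_that("model specs serialize to a readable layer table", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_model_spec(table2_spec(), path)
  tab <- read.table(path, header = TRUE, sep = "\t")
  expect_equal(nrow(tab), 26)
  expect_match(tab$parameter[1], "filters=50 kernel=10 activation=relu")
})
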