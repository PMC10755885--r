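test_that("positions decode to valid hyperparameters", {
  hp <- decode_position(c(50.4, 9.6, 0.3, 0.2, -3.0, 2.2))
  expect_identical(hp$n_kernels, 50L)
  expect_identical(hp$kernel_size, 10L)
  expect_identical(hp$activation, 0L)
  expect_equal(hp$dropout, 0.2)
  expect_equal(hp$learning_rate, 1e-3)
  expect_identical(hp$pool_size, 2L)

  corner <- decode_position(c(40, 1, 0, 0, -5, 2))
  expect_identical(corner$n_kernels, 40L)
  expect_identical(corner$kernel_size, 1L)
  expect_equal(corner$learning_rate, 1e-5)
  expect_identical(corner$pool_size, 2L)

  clipped <- decode_position(c(200, 30, 9, 2, 5, 40))
  expect_identical(clipped$n_kernels, 100L)
  expect_identical(clipped$kernel_size, 20L)
  expect_identical(clipped$activation, 2L)
  expect_equal(clipped$dropout, 0.6)
  expect_lt(clipped$learning_rate, 1)
  expect_identical(clipped$pool_size, 20L)

  expect_error(decode_position(1:5), "length 6")
})

test_that("decoding is idempotent under re-encoding", {
  set.seed(42)
  for (i in 1:200) {
    pos <- runif(6, -50, 250)  # mostly far out of bounds
    hp <- decode_position(pos)
    hp2 <- decode_position(encode_hp(hp))
    expect_identical(hp2, hp)
  }
})

test_that("decoded vectors always satisfy the constraint box", {
  set.seed(7)
  sp <- hp_space()
  n <- 10000
  pos <- matrix(runif(6 * n, -1e3, 1e3), ncol = 6)
  ok <- vapply(seq_len(n), function(i) {
    hp <- decode_position(pos[i, ])
    hp$n_kernels >= 40 && hp$n_kernels <= 100 &&
      hp$kernel_size >= 1 && hp$kernel_size <= 20 &&
      hp$activation %in% 0:2 &&
      hp$dropout >= 0 && hp$dropout <= 0.6 &&
      hp$learning_rate >= 1e-5 && hp$learning_rate < 1 &&
      hp$pool_size >= 2 && hp$pool_size <= 20
  }, logical(1))
  expect_true(all(ok))
  expect_identical(sp$name[5], "log10_eta")
})

test_that("half-away-from-zero rounding is used at .5 grid points", {
  hp <- decode_position(c(50.5, 9.5, 0.5, 0.2, -3, 2.5))
  expect_identical(hp$n_kernels, 51L)
  expect_identical(hp$kernel_size, 10L)
  expect_identical(hp$activation, 1L)
  expect_identical(hp$pool_size, 3L)
  hp2 <- decode_position(c(50.5, 9.5, 1.5, 0.2, -3, 2.5))
  expect_identical(hp2$activation, 2L)
})

test_that("activation codes map to named activations", {
  expect_identical(activation_name(0), "relu")
  expect_identical(activation_name(1), "sigmoid")
  expect_identical(activation_name(2), "tanh")
  expect_error(activation_name(3), "0")
  expect_error(activation_name(-1), "0")
})

test_that("report rows render the compact dropout index", {
  row <- report_row(table2_hp())
  expect_equal(unlist(row[c("delta", "s", "a", "d_index", "m")]),
               c(delta = 50, s = 10, a = 0, d_index = 2, m = 2))
  expect_identical(report_row(hp_vector(dropout = 0))$d_index, 0L)
  expect_identical(report_row(hp_vector(dropout = 0.6))$d_index, 6L)
})

test_that("direct construction validates the constraint box", {
  expect_error(hp_vector(n_kernels = 30), "n_kernels")
  expect_error(hp_vector(learning_rate = 1), "learning_rate")
  expect_error(hp_vector(pool_size = 1), "pool_size")
})
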