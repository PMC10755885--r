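test_that("population initialization is seeded, reproducible and in bounds", {
  cfg <- mfo_config(bounds = list(c(0, 1), c(0, 1)), n_moths = 3, seed = 11)
  p1 <- init_population(cfg)
  p2 <- init_population(cfg)
  expect_identical(p1$positions, p2$positions)
  expect_true(all(p1$positions >= 0 & p1$positions <= 1))

  tight <- init_population(mfo_config(list(c(5, 5.0001)), n_moths = 50,
                                      seed = 1))
  expect_true(all(tight$positions >= 5 & tight$positions <= 5.0001))

  eq8 <- init_population(mfo_config(hp_bounds(), n_moths = 20, seed = 2))
  expect_equal(dim(eq8$positions), c(20, 6))
  expect_true(all(eq8$positions[, 1] >= 40 & eq8$positions[, 1] <= 100))

  expect_error(mfo_config(list(c(1, 0))), "lower < upper")
  expect_error(mfo_config(list(c(2, 2))), "lower < upper")
})

test_that("flame count follows the adaptive reduction rule", {
  expect_identical(flame_count(30, 30, 20), 1L)
  expect_identical(flame_count(1, 30, 20), 19L)   # round(20 - 19/30)
  expect_identical(flame_count(10, 30, 20), 14L)  # round(13.667)
  counts <- vapply(1:30, flame_count, integer(1), t_max = 30, n_max = 20)
  expect_true(all(diff(counts) <= 0))
  expect_true(all(counts >= 1))
  expect_lte(counts[1], 20)
  expect_error(flame_count(31, 30, 20), "1..t_max")
})

test_that("spiral update matches its closed form", {
  expect_equal(spiral_update(c(3, -2), c(3, -2), b = 1, t = 0.37),
               c(3, -2))  # zero distance: fixed point
  expect_equal(spiral_update(1, 0, b = 1, t = 0), 1)
  expect_equal(spiral_update(1, 0, b = 1, t = -1), exp(-1) * cos(-2 * pi),
               tolerance = 1e-12)
  expect_error(spiral_update(c(1, 2), 0, b = 1, t = 0), "dimension")
})

test_that("flame update keeps the best of the pooled records", {
  pos <- matrix(rnorm(10), 5, 2)
  fit <- c(5, 3, 1, 4, 2)
  first <- update_flames(pos, fit, flame_no = 5)
  expect_equal(first$fitness, sort(fit))
  expect_equal(first$positions[1, ], pos[3, ])

  # elitism: a better previous flame survives worse moths
  kept <- update_flames(pos, fit + 10, prev_positions = matrix(c(9, 9), 1),
                        prev_fitness = 0.1, flame_no = 3)
  expect_equal(kept$fitness[1], 0.1)

  # brute-force oracle over pooled moths + flames
  for (s in 1:5) {
    set.seed(s)
    m_fit <- runif(5); f_fit <- runif(5)
    m_pos <- matrix(runif(10), 5); f_pos <- matrix(runif(10), 5)
    got <- update_flames(m_pos, m_fit, f_pos, f_fit, flame_no = 3)
    expect_equal(got$fitness, sort(c(m_fit, f_fit))[1:3])
  }
  expect_error(update_flames(pos, fit, flame_no = 0), "flame_no")
})

test_that("run_mfo handles degenerate objectives and stays in bounds", {
  cfg <- mfo_config(list(c(-1, 1)), n_moths = 4, max_iter = 3, seed = 5)
  res <- run_mfo(function(x) 7, cfg)
  expect_equal(res$best_fitness, 7)
  expect_equal(res$trace$best_fitness, rep(7, 3))

  one <- run_mfo(function(x) sum(x^2),
                 mfo_config(list(c(-2, 2)), n_moths = 1, max_iter = 1,
                            seed = 9))
  init <- init_population(mfo_config(list(c(-2, 2)), n_moths = 1,
                                     max_iter = 1, seed = 9))
  expect_equal(one$best_fitness, sum(init$positions[1, ]^2))

  # a partially non-finite objective never poisons the flame set
  spiky <- function(x) if (x[1] > 0) NaN else sum(x^2)
  res2 <- run_mfo(spiky, mfo_config(list(c(-1, 1)), n_moths = 6,
                                    max_iter = 10, seed = 3))
  expect_true(is.finite(res2$best_fitness))

  sphere <- function(x) sum(x^2)
  cfg2 <- mfo_config(list(c(-5, 5), c(-5, 5)), n_moths = 10, max_iter = 25,
                     seed = 17)
  r1 <- run_mfo(sphere, cfg2)
  r2 <- run_mfo(sphere, cfg2)
  expect_identical(r1$trace, r2$trace)  # bit-identical seeded runs
  expect_true(all(diff(r1$trace$best_fitness) <= 0))  # elitism
  expect_true(all(r1$trace$x1 >= -5 & r1$trace$x1 <= 5))
  expect_true(all(r1$trace$x2 >= -5 & r1$trace$x2 <= 5))
})

test_that("trace table round-trips through its delimited form", {
  res <- run_mfo(function(x) sum(x^2),
                 mfo_config(list(c(-1, 1)), n_moths = 3, max_iter = 4,
                            seed = 2))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_mfo_trace(res, path)
  back <- read.table(path, header = TRUE, sep = "\t")
  expect_equal(back$best_fitness, res$trace$best_fitness)
  expect_equal(nrow(back), 4)
})
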