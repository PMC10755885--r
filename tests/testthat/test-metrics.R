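test_that("confusion matrices count exactly", {
  cm <- confusion_matrix(c(0L, 0L, 1L), c(0L, 1L, 1L), K = 2)
  expect_equal(unname(cm), rbind(c(1, 1), c(0, 1)))

  y <- c(0L, 1L, 2L, 2L, 1L)
  expect_true(all(diag(confusion_matrix(y, y)) == c(1, 2, 2)))

  set.seed(2)
  truth <- sample(0:3, 57, replace = TRUE)
  pred <- sample(0:3, 57, replace = TRUE)
  expect_equal(sum(confusion_matrix(truth, pred, 4)), 57)

  expect_error(confusion_matrix(c(0, 5), c(0, 1), K = 2), "0..K-1")
  expect_error(confusion_matrix(0:1, 0L), "equal length")
})

test_that("binary scores follow the TP/TN/FP/FN formulas on the 0-100 scale", {
  # TP = TN = 9, FP = FN = 1 (class 1 positive)
  cm <- rbind(c(9, 1), c(1, 9))
  r <- basic_scores(cm)
  expect_equal(r$accuracy, 90)
  expect_equal(r$precision, 90)
  expect_equal(r$recall, 90)
  expect_equal(r$f1, 90)

  perfect <- diag(c(10, 20, 30, 40, 50))
  rp <- basic_scores(perfect)
  expect_equal(c(rp$accuracy, rp$precision, rp$recall, rp$f1),
               rep(100, 4))

  # class never predicted: defined precision 0 with a warning
  cm0 <- rbind(c(5, 0), c(5, 0))
  expect_warning(r0 <- basic_scores(cm0), "never predicted")
  expect_equal(r0$per_class$precision[2], 0)
  expect_error(basic_scores(matrix(0, 2, 2)), "empty")
})

test_that("multi-class averaging is weighted by support", {
  cm <- rbind(c(8, 2, 0), c(1, 6, 3), c(0, 0, 10))
  r <- basic_scores(cm)
  expect_equal(r$accuracy, 100 * 24 / 30)  # trace identity
  prec <- c(8 / 9, 6 / 8, 10 / 13)
  rec <- c(8 / 10, 6 / 10, 10 / 10)
  w <- c(10, 10, 10) / 30
  expect_equal(r$precision, 100 * sum(w * prec))
  expect_equal(r$recall, 100 * sum(w * rec))
  m <- basic_scores(cm, averaging = "macro")
  expect_equal(m$precision, 100 * mean(prec))
  # balanced binary: weighted and macro coincide
  bal <- rbind(c(40, 10), c(5, 45))
  expect_equal(basic_scores(bal, "weighted")$recall,
               basic_scores(bal, "macro")$recall)
})

test_that("Cohen's kappa matches hand computations and an external oracle", {
  expect_equal(cohen_kappa(diag(c(3, 4, 5))), 1)

  # outer-product (statistically independent) matrix: chance agreement
  marg_r <- c(30, 70); marg_c <- c(40, 60)
  indep <- outer(marg_r, marg_c) / 100
  expect_equal(cohen_kappa(indep), 0)

  cm <- rbind(c(45, 5), c(15, 35))
  expect_equal(cohen_kappa(cm), 0.6)  # p_o = 0.8, p_e = 0.5

  skip_if_not_installed("e1071")
  set.seed(9)
  for (i in 1:10) {
    K <- sample(2:5, 1)
    cm <- matrix(rpois(K * K, 8), K, K)
    expect_equal(cohen_kappa(cm),
                 e1071::classAgreement(cm)$kappa, tolerance = 1e-12)
  }
})

test_that("scores are invariant under consistent class relabeling", {
  set.seed(4)
  truth <- sample(0:4, 300, replace = TRUE)
  pred <- ifelse(runif(300) < 0.7, truth, sample(0:4, 300, replace = TRUE))
  r <- evaluation_report(truth, pred, K = 5)
  perm <- sample(0:4)
  r2 <- evaluation_report(perm[truth + 1], perm[pred + 1], K = 5)
  expect_equal(r2$accuracy, r$accuracy)
  expect_equal(r2$kappa, r$kappa)
  expect_equal(r2$f1, r$f1)
  expect_equal(r$accuracy, 100 * sum(diag(r$confusion)) / 300)
})

test_that("report tables use the publication column layout", {
  r <- evaluation_report(c(0L, 1L, 1L, 0L), c(0L, 1L, 0L, 0L), K = 2)
  tab <- report_table(list("A vs E" = r), group = "Normal vs. ictal")
  expect_named(tab, c("Group", "Class", "Accuracy", "Precision", "Recall",
                      "F1.score", "Kappa"))
  expect_equal(tab$Class, "A vs E")
  expect_equal(tab$Accuracy, 75)
})
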