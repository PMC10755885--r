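#' Confusion matrix from true and predicted labels
#'
#' @param truth,pred Integer label vectors (0-based) of equal length.
#' @param K Number of classes (defaults to one more than the largest
#'   label seen).
#' @return A `K x K` integer matrix; rows are true classes, columns
#'   predicted classes.
#' @export
#' @examples
#' confusion_matrix(c(0, 0, 1), c(0, 1, 1), K = 2)
confusion_matrix <- function(truth, pred, K = NULL) {
  if (length(truth) != length(pred)) {
    stop("truth and pred must have equal length", call. = FALSE)
  }
  if (is.null(K)) K <- max(truth, pred) + 1L
  if (any(truth < 0 | truth >= K) || any(pred < 0 | pred >= K)) {
    stop("labels must lie in 0..K-1", call. = FALSE)
  }
  cm <- matrix(0L, K, K)
  for (i in seq_along(truth)) {
    cm[truth[i] + 1L, pred[i] + 1L] <- cm[truth[i] + 1L, pred[i] + 1L] + 1L
  }
  dimnames(cm) <- list(true = 0:(K - 1), predicted = 0:(K - 1))
  cm
}

# per-class one-vs-rest counts
ovr_counts <- function(cm) {
  total <- sum(cm)
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  tn <- total - tp - fp - fn
  list(tp = tp, tn = tn, fp = fp, fn = fn, support = rowSums(cm))
}

#' Accuracy, precision, recall and F1 from a confusion matrix
#'
#' For two classes the standard TP/TN/FP/FN formulas are applied
#' directly (class 1 taken as positive).  For more classes, per-class
#' one-vs-rest counts are computed and averaged, weighted by class
#' support by default (`averaging = "macro"` gives the unweighted
#' mean).  All scores are on the 0-100 scale.  A class that is never
#' predicted has precision 0 for that class (with a warning).
#'
#' @param cm A confusion matrix from [confusion_matrix()].
#' @param averaging `"weighted"` (default) or `"macro"`.
#' @return An object of class `evaluation_report`: `accuracy`,
#'   `precision`, `recall`, `f1` (0-100), `per_class` data frame,
#'   `averaging`, and the matrix itself.
#' @export
#' @examples
#' basic_scores(matrix(c(9, 1, 1, 9), 2, byrow = TRUE))
basic_scores <- function(cm, averaging = c("weighted", "macro")) {
  averaging <- match.arg(averaging)
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix", call. = FALSE)
  K <- nrow(cm)
  ct <- ovr_counts(cm)
  pred_counts <- colSums(cm)
  if (any(pred_counts == 0 & ct$support > 0)) {
    warning("some class is never predicted; its precision is set to 0")
  }
  prec_c <- ifelse(ct$tp + ct$fp > 0, ct$tp / (ct$tp + ct$fp), 0)
  rec_c <- ifelse(ct$tp + ct$fn > 0, ct$tp / (ct$tp + ct$fn), 0)
  f1_c <- ifelse(prec_c + rec_c > 0,
                 2 * prec_c * rec_c / (prec_c + rec_c), 0)
  per_class <- data.frame(class = 0:(K - 1), support = ct$support,
                          precision = 100 * prec_c, recall = 100 * rec_c,
                          f1 = 100 * f1_c)
  if (K == 2) {
    # literal binary formulas, class 1 positive
    tp <- cm[2, 2]; tn <- cm[1, 1]; fp <- cm[1, 2]; fn <- cm[2, 1]
    accuracy <- 100 * (tp + tn) / total
    precision <- if (tp + fp > 0) 100 * tp / (tp + fp) else 0
    recall <- if (tp + fn > 0) 100 * tp / (tp + fn) else 0
    f1 <- if (precision + recall > 0) {
      2 * recall * precision / (recall + precision)
    } else 0
  } else {
    w <- if (averaging == "weighted") ct$support / total else rep(1 / K, K)
    accuracy <- 100 * sum(diag(cm)) / total
    precision <- 100 * sum(w * prec_c)
    recall <- 100 * sum(w * rec_c)
    f1 <- 100 * sum(w * f1_c)
  }
  structure(list(accuracy = accuracy, precision = precision,
                 recall = recall, f1 = f1, kappa = NA_real_,
                 per_class = per_class, averaging = averaging,
                 confusion = cm),
            class = "evaluation_report")
}

#' Cohen's kappa from a confusion matrix
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)`, with observed
#' agreement `p_o = trace / total` and chance agreement `p_e` from the
#' product of row and column marginals.  When `p_e = 1` (all mass in a
#' single cell) the value is 1 for perfect agreement and undefined
#' otherwise.
#'
#' @param cm A confusion matrix.
#' @return A scalar in `[-1, 1]`.
#' @export
#' @examples
#' cohen_kappa(matrix(c(45, 5, 15, 35), 2, byrow = TRUE))  # 0.6
cohen_kappa <- function(cm) {
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix", call. = FALSE)
  p_o <- sum(diag(cm)) / total
  p_e <- sum(rowSums(cm) * colSums(cm)) / total^2
  if (abs(1 - p_e) < 1e-15) {
    if (p_o >= 1 - 1e-15) return(1)
    stop("kappa undefined: chance agreement is 1 without perfect agreement",
         call. = FALSE)
  }
  (p_o - p_e) / (1 - p_e)
}

#' Full evaluation report from labels
#'
#' Convenience wrapper building the confusion matrix, the basic scores
#' and Cohen's kappa in one call.
#'
#' @inheritParams confusion_matrix
#' @inheritParams basic_scores
#' @return An `evaluation_report` with `kappa` filled in.
#' @export
evaluation_report <- function(truth, pred, K = NULL,
                              averaging = c("weighted", "macro")) {
  cm <- confusion_matrix(truth, pred, K)
  rep <- basic_scores(cm, averaging)
  rep$kappa <- cohen_kappa(cm)
  rep
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("Accuracy %.2f  Precision %.2f  Recall %.2f  F1 %.2f",
              x$accuracy, x$precision, x$recall, x$f1))
  if (!is.na(x$kappa)) cat(sprintf("  kappa %.4f", x$kappa))
  cat(sprintf("  (%s averaging, n = %d)\n", x$averaging, sum(x$confusion)))
  invisible(x)
}

#' Render evaluation reports as a publication-style table
#'
#' @param reports A named list of `evaluation_report`s (names become the
#'   `Class` column, e.g. `"A vs E"`).
#' @param group Optional `Group` column value(s).
#' @return A data frame with columns `Group`, `Class`, `Accuracy`,
#'   `Precision`, `Recall`, `F1.score`, `Kappa`.
#' @export
report_table <- function(reports, group = "") {
  stopifnot(is.list(reports))
  rows <- lapply(seq_along(reports), function(i) {
    r <- reports[[i]]
    data.frame(Group = if (length(group) > 1) group[i] else group,
               Class = names(reports)[i],
               Accuracy = r$accuracy, Precision = r$precision,
               Recall = r$recall, F1.score = r$f1, Kappa = r$kappa,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
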