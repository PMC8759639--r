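#' Binary classification metric bundle
#'
#' Computes the confusion matrix, accuracy, Matthews correlation
#' coefficient, ROC curve with trapezoidal AUC, and precision-recall
#' curve with step-wise average precision from labels, continuous
#' decision scores and hard predictions.
#'
#' Conventions: class 1 is the "positive" class; scores are oriented so
#' larger values favour class 1; ROC thresholds sweep the distinct score
#' values in decreasing order, and tied scores are handled by averaged
#' ranks, so the trapezoidal AUC equals the Mann-Whitney rank statistic
#' `U / (n1 * n0)` exactly.  MCC is 0 by convention when any confusion
#' marginal is zero.
#'
#' @param labels integer 0/1 true labels (both classes present).
#' @param scores numeric decision scores (e.g. signed distance to the
#'   decision boundary).
#' @param predictions integer 0/1 hard predictions; defaults to
#'   `scores > 0`.
#' @return list of class `metric_bundle`: `confusion` (2 x 2 matrix,
#'   rows = truth 0/1, cols = predicted 0/1), `accuracy`, `mcc`, `auc`,
#'   `ap`, `roc` (data.frame fpr/tpr/threshold), `pr` (data.frame
#'   recall/precision/threshold).
#' @export
evaluate_metrics <- function(labels, scores,
                             predictions = as.integer(scores > 0)) {
  labels <- as.integer(labels)
  predictions <- as.integer(predictions)
  if (length(labels) != length(scores) ||
      length(labels) != length(predictions))
    stop("labels, scores and predictions must have equal length")
  if (length(unique(labels)) < 2L)
    stop("both classes must be present in `labels`")

  conf <- confusion_matrix(labels, predictions)
  acc <- sum(diag(conf)) / sum(conf)
  roc <- roc_curve(labels, scores)
  pr <- pr_curve(labels, scores)
  structure(list(confusion = conf, accuracy = acc,
                 mcc = mcc_from_confusion(conf),
                 auc = trapezoid_auc(roc$fpr, roc$tpr),
                 ap = step_ap(pr$recall, pr$precision),
                 roc = roc, pr = pr),
            class = "metric_bundle")
}

#' Confusion matrix of binary predictions
#' @param labels,predictions integer 0/1 vectors.
#' @return 2 x 2 integer matrix, rows = truth (0, 1), cols = predicted.
#' @export
confusion_matrix <- function(labels, predictions) {
  conf <- table(factor(labels, levels = c(0L, 1L)),
                factor(predictions, levels = c(0L, 1L)))
  m <- matrix(as.integer(conf), 2L, 2L,
              dimnames = list(truth = c("0", "1"),
                              predicted = c("0", "1")))
  m
}

#' Matthews correlation coefficient from a confusion matrix
#'
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, with the
#' value defined as 0 whenever a marginal (hence the denominator) is
#' zero.
#' @param conf 2 x 2 confusion matrix as from [confusion_matrix()].
#' @return scalar in `[-1, 1]`.
#' @export
mcc_from_confusion <- function(conf) {
  tn <- conf[1L, 1L]; fp <- conf[1L, 2L]
  fn <- conf[2L, 1L]; tp <- conf[2L, 2L]
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / den
}

# ROC by sweeping distinct scores in decreasing order
roc_curve <- function(labels, scores) {
  th <- sort(unique(scores), decreasing = TRUE)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  tpr <- vapply(th, function(t) sum(scores >= t & labels == 1L) / n1,
                numeric(1L))
  fpr <- vapply(th, function(t) sum(scores >= t & labels == 0L) / n0,
                numeric(1L))
  data.frame(fpr = c(0, fpr), tpr = c(0, tpr),
             threshold = c(Inf, th))
}

pr_curve <- function(labels, scores) {
  th <- sort(unique(scores), decreasing = TRUE)
  n1 <- sum(labels == 1L)
  rec <- numeric(length(th)); prec <- numeric(length(th))
  for (i in seq_along(th)) {
    sel <- scores >= th[i]
    rec[i] <- sum(sel & labels == 1L) / n1
    prec[i] <- sum(sel & labels == 1L) / sum(sel)
  }
  data.frame(recall = c(0, rec), precision = c(1, prec),
             threshold = c(Inf, th))
}

trapezoid_auc <- function(x, y) {
  o <- order(x, y)
  sum(diff(x[o]) * (utils::head(y[o], -1L) + utils::tail(y[o], -1L)) / 2)
}

# step-wise average precision: sum over thresholds of
# (recall_i - recall_{i-1}) * precision_i
step_ap <- function(recall, precision) {
  sum(diff(recall) * precision[-1L])
}

#' Compare two cross-validation accuracy distributions
#'
#' Two-sided Mann-Whitney U test on the fold-level accuracies of two
#' cross-validation reports (or raw accuracy vectors).  The fold is the
#' sampling unit: one accuracy per left-out subject for LOSO, one per
#' subject x fold for the per-subject k-fold scheme.
#'
#' @param report_a,report_b `cv_report` objects (see [run_loso()]) or
#'   numeric vectors of fold accuracies (length >= 3 each).
#' @return list: `u` (Mann-Whitney U for the first sample), `p`
#'   (two-sided p-value), `direction` (`"a > b"`, `"b > a"` or `"tie"`,
#'   by median), `n_a`, `n_b`.  All-tied inputs give `p = 1` with a
#'   warning.
#' @export
compare_accuracy_distributions <- function(report_a, report_b) {
  acc <- function(r) if (inherits(r, "cv_report")) r$fold_accuracies
                     else as.numeric(r)
  a <- acc(report_a); b <- acc(report_b)
  if (length(a) < 3L || length(b) < 3L)
    stop("need at least 3 fold accuracies per report")
  if (length(unique(c(a, b))) == 1L) {
    warning("all accuracies tied across both reports; p set to 1")
    return(list(u = length(a) * length(b) / 2, p = 1,
                direction = "tie", n_a = length(a), n_b = length(b)))
  }
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE,
                                            correct = TRUE))
  dir <- if (stats::median(a) > stats::median(b)) "a > b"
         else if (stats::median(b) > stats::median(a)) "b > a" else "tie"
  list(u = unname(wt$statistic), p = wt$p.value, direction = dir,
       n_a = length(a), n_b = length(b))
}
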