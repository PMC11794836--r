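#' Two-class confusion matrix
#'
#' @param labels_true,labels_pred Equal-length vectors (logical,
#'   character, or factor).
#' @param positive Value of the positive class (default `TRUE`, i.e.
#'   "abnormal" in this package's pipelines).
#' @return Object of class `confusion_matrix` with counts `TP`, `TN`,
#'   `FP`, `FN` and `total`.
#' @export
confusion <- function(labels_true, labels_pred, positive = TRUE) {
  if (length(labels_true) != length(labels_pred)) {
    stop("label vectors must have equal length", call. = FALSE)
  }
  tp <- sum(labels_true == positive & labels_pred == positive)
  tn <- sum(labels_true != positive & labels_pred != positive)
  fp <- sum(labels_true != positive & labels_pred == positive)
  fn <- sum(labels_true == positive & labels_pred != positive)
  structure(list(TP = tp, TN = tn, FP = fp, FN = fn, total = tp + tn + fp + fn,
                 positive = positive),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$TP, x$FP, x$FN, x$TN), 2, 2,
              dimnames = list(truth = c("positive", "negative"),
                              predicted = c("positive", "negative")))
  print(m)
  invisible(x)
}

#' Classification metrics from a confusion matrix
#'
#' Accuracy `(TP + TN) / total`, precision `TP / (TP + FP)`, recall
#' `TP / (TP + FN)`, and their harmonic-mean F1. Any division by zero
#' yields 0 with the corresponding flag set in `degenerate`.
#'
#' @param cm A `confusion_matrix`.
#' @return List of class `class_metrics` with `accuracy`, `precision`,
#'   `recall`, `f1` (all in `[0, 1]`) and `degenerate` flags.
#' @export
cls_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  if (cm$total == 0) stop("empty confusion matrix", call. = FALSE)
  div <- function(num, den) if (den == 0) c(0, TRUE) else c(num / den, FALSE)
  pr <- div(cm$TP, cm$TP + cm$FP)
  rc <- div(cm$TP, cm$TP + cm$FN)
  f1 <- if (pr[1] + rc[1] == 0) c(0, TRUE)
        else c(2 * pr[1] * rc[1] / (pr[1] + rc[1]), FALSE)
  structure(list(accuracy = (cm$TP + cm$TN) / cm$total,
                 precision = pr[1], recall = rc[1], f1 = f1[1],
                 degenerate = c(precision = as.logical(pr[2]),
                                recall = as.logical(rc[2]),
                                f1 = as.logical(f1[2]))),
            class = "class_metrics")
}

#' @export
print.class_metrics <- function(x, ...) {
  cat(sprintf("accuracy %.2f%%  precision %.2f%%  recall %.2f%%  F1 %.2f%%\n",
              100 * x$accuracy, 100 * x$precision, 100 * x$recall, 100 * x$f1))
  invisible(x)
}

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps the decision threshold over the unique scores (equal scores
#' grouped, so ties contribute a single ROC point) and integrates the
#' area under the curve with the trapezoidal rule — numerically
#' identical to the Mann-Whitney pairwise estimator with ties counted
#' one half.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels Binary labels (logical or 0/1); both classes required.
#' @return List of class `roc_result`: `points` (data frame `threshold`,
#'   `fpr`, `tpr`, starting at (0,0) and ending at (1,1)) and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) stop("length mismatch", call. = FALSE)
  if (!any(labels) || all(labels)) {
    stop("both classes must be present for a ROC curve", call. = FALSE)
  }
  np <- sum(labels)
  nn <- sum(!labels)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  grp <- cumsum(!duplicated(s))
  tp <- tapply(l, grp, sum)
  fp <- tapply(!l, grp, sum)
  thr <- s[!duplicated(s)]
  ctp <- cumsum(tp)
  cfp <- cumsum(fp)
  points <- data.frame(threshold = c(Inf, thr),
                       fpr = c(0, cfp / nn), tpr = c(0, ctp / np))
  auc <- sum(diff(points$fpr) * (head(points$tpr, -1) + tail(points$tpr, -1)) / 2)
  structure(list(points = points, auc = auc), class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat("<roc_result> AUC", signif(x$auc, 4), "over", nrow(x$points), "points\n")
  invisible(x)
}

#' @export
plot.roc_result <- function(x, ...) {
  graphics::plot(x$points$fpr, x$points$tpr, type = "l",
                 xlab = "False positive rate", ylab = "True positive rate", ...)
  graphics::abline(0, 1, lty = 3, col = "grey50")
  invisible(x)
}

#' Full evaluation report
#'
#' Per-class precision/recall/F1 (each class taken in turn as positive),
#' overall accuracy, and — when scores are supplied — the ROC curve and
#' AUC for the positive (abnormal) class.
#'
#' @param labels_true,labels_pred Binary label vectors (logical:
#'   `TRUE` = abnormal).
#' @param scores Optional abnormality scores for the ROC/AUC.
#' @return Object of class `evaluation_report`.
#' @export
evaluation_report <- function(labels_true, labels_pred, scores = NULL) {
  labels_true <- as.logical(labels_true)
  labels_pred <- as.logical(labels_pred)
  cm_abn <- confusion(labels_true, labels_pred, positive = TRUE)
  cm_norm <- confusion(labels_true, labels_pred, positive = FALSE)
  roc <- if (!is.null(scores)) roc_auc(scores, labels_true) else NULL
  structure(list(confusion = cm_abn,
                 per_class = list(normal = cls_metrics(cm_norm),
                                  abnormal = cls_metrics(cm_abn)),
                 accuracy = cls_metrics(cm_abn)$accuracy,
                 roc = roc, auc = if (is.null(roc)) NA_real_ else roc$auc),
            class = "evaluation_report")
}

# Two-decimal half-up percentage formatting used in report tables.
pct2 <- function(x) sprintf("%.2f", floor(100 * x * 100 + 0.5) / 100)

#' @export
print.evaluation_report <- function(x, ...) {
  cat("Evaluation (positive class: abnormal)\n")
  print(x$confusion)
  tab <- rbind(
    Accuracy = c(pct2(x$accuracy), pct2(x$accuracy)),
    Precision = c(pct2(x$per_class$normal$precision), pct2(x$per_class$abnormal$precision)),
    Recall = c(pct2(x$per_class$normal$recall), pct2(x$per_class$abnormal$recall)),
    `F1 score` = c(pct2(x$per_class$normal$f1), pct2(x$per_class$abnormal$f1))
  )
  colnames(tab) <- c("Normal %", "Abnormal %")
  print(tab, quote = FALSE)
  if (!is.null(x$roc)) cat("AUC:", signif(x$auc, 4), "\n")
  invisible(x)
}

#' Write an evaluation report to disk
#'
#' Writes `report.json` (all metrics), `confusion.csv`, and — when a ROC
#' is present — `roc.csv` (threshold, FPR, TPR).
#'
#' @param report An `evaluation_report`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the files written.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "evaluation_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jf <- file.path(dir, "report.json")
  obj <- list(
    accuracy = report$accuracy,
    confusion = report$confusion[c("TP", "TN", "FP", "FN")],
    per_class = lapply(report$per_class, function(m) {
      m[c("accuracy", "precision", "recall", "f1")]
    }),
    auc = report$auc
  )
  jsonlite::write_json(obj, jf, auto_unbox = TRUE, digits = NA, na = "null")
  cf <- file.path(dir, "confusion.csv")
  write.csv(data.frame(TP = report$confusion$TP, TN = report$confusion$TN,
                       FP = report$confusion$FP, FN = report$confusion$FN),
            cf, row.names = FALSE)
  files <- c(jf, cf)
  if (!is.null(report$roc)) {
    rf <- file.path(dir, "roc.csv")
    write.csv(report$roc$points, rf, row.names = FALSE)
    files <- c(files, rf)
  }
  invisible(files)
}
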