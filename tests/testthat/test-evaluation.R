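test_that("confusion matrix counts follow the positive-class convention", {
  truth <- c(TRUE, TRUE, FALSE, FALSE, FALSE)
  perfect <- confusion(truth, truth)
  expect_equal(perfect$TP + perfect$TN, 5)
  expect_equal(perfect$FP + perfect$FN, 0)
  allpos <- confusion(truth, rep(TRUE, 5))
  expect_equal(allpos$FN, 0)
  expect_error(confusion(truth, truth[-1]), "equal length")
})

test_that("metrics reproduce the clinical test outcome from its printed counts", {
  # 428 abnormal: 408 caught, 20 missed; 4619 normal: 4607 kept, 12 flagged
  truth <- c(rep(TRUE, 428), rep(FALSE, 4619))
  pred <- c(rep(TRUE, 408), rep(FALSE, 20), rep(FALSE, 4607), rep(TRUE, 12))
  cm <- confusion(truth, pred, positive = TRUE)
  expect_equal(cm$TP, 408)
  expect_equal(cm$FN, 20)
  expect_equal(cm$TN, 4607)
  expect_equal(cm$FP, 12)
  m_abn <- cls_metrics(cm)
  m_norm <- cls_metrics(confusion(truth, pred, positive = FALSE))
  expect_equal(round(100 * m_abn$accuracy, 2), 99.37)
  expect_equal(round(100 * m_norm$precision, 2), 99.57)
  expect_equal(round(100 * m_norm$f1, 2), 99.65)
  # exact arithmetic gives 96.226; the printed table says 96.22 — agree to
  # one unit in the last printed digit
  expect_lte(abs(100 * m_abn$f1 - 96.22), 0.01)
  # accuracy does not depend on which class is positive
  expect_equal(m_abn$accuracy, m_norm$accuracy)
})

test_that("degenerate metric denominators return 0 with flags", {
  cm <- confusion(c(FALSE, FALSE), c(FALSE, FALSE))
  m <- cls_metrics(cm)
  expect_equal(m$precision, 0)
  expect_equal(m$recall, 0)
  expect_equal(m$f1, 0)
  expect_true(all(m$degenerate))
  one <- cls_metrics(confusion(TRUE, TRUE))
  expect_equal(c(one$precision, one$recall, one$f1), c(1, 1, 1))
})

test_that("F1 sits between precision and recall", {
  set.seed(11)
  for (i in 1:25) {
    truth <- sample(c(TRUE, FALSE), 40, replace = TRUE)
    pred <- sample(c(TRUE, FALSE), 40, replace = TRUE)
    m <- cls_metrics(confusion(truth, pred))
    if (m$precision > 0 && m$recall > 0) {
      expect_gte(m$f1, min(m$precision, m$recall) - 1e-12)
      expect_lte(m$f1, max(m$precision, m$recall) + 1e-12)
    }
  }
})

test_that("ROC sweep is monotone, anchored, and AUC matches the pairwise estimator", {
  sep <- roc_auc(c(0.9, 0.8, 0.2, 0.1), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(sep$auc, 1.0)
  flat <- roc_auc(rep(0.5, 10), c(rep(TRUE, 4), rep(FALSE, 6)))
  expect_equal(flat$auc, 0.5)
  expect_error(roc_auc(1:3, c(TRUE, TRUE, TRUE)), "both classes")

  set.seed(21)
  for (i in 1:40) {
    n <- sample(5:30, 1)
    # coarse scores force ties across and within classes
    scores <- sample(seq(0, 1, by = 0.25), n, replace = TRUE)
    labels <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(labels) || all(labels)) next
    r <- roc_auc(scores, labels)
    expect_equal(r$auc, auc_pairwise(scores, labels), tolerance = 1e-12)
    expect_equal(r$points$fpr[1], 0)
    expect_equal(r$points$tpr[1], 0)
    expect_equal(r$points$fpr[nrow(r$points)], 1)
    expect_equal(r$points$tpr[nrow(r$points)], 1)
    expect_true(all(diff(r$points$fpr) >= 0))
    expect_true(all(diff(r$points$tpr) >= 0))
  }
})

test_that("evaluation reports round-trip to JSON and CSV", {
  dir <- withr::local_tempdir()
  truth <- c(rep(TRUE, 6), rep(FALSE, 14))
  scores <- c(runif(6, 0.5, 1), runif(14, 0, 0.6))
  rep <- evaluation_report(truth, scores > 0.5, scores)
  files <- write_report(rep, dir)
  expect_true(all(file.exists(files)))
  j <- jsonlite::read_json(file.path(dir, "report.json"))
  expect_equal(j$accuracy, rep$accuracy)
  expect_equal(j$auc, rep$auc)
  roc <- read.csv(file.path(dir, "roc.csv"))
  expect_equal(nrow(roc), nrow(rep$roc$points))
})
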