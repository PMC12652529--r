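test_that("confusion matrices count truth/prediction pairs exactly", {
  cm <- brdu_confusion(c("T", "T", "B"), c("T", "B", "B"))
  expect_equal(cm["T", "T"], 1L)
  expect_equal(cm["T", "B"], 1L)
  expect_equal(cm["B", "B"], 1L)
  expect_equal(sum(cm), 3L)

  truth <- rep(CLASSES, 3)
  cm2 <- brdu_confusion(truth, truth)
  expect_equal(unname(diag(unclass(cm2))), rep(3L, 5))
  expect_equal(sum(cm2) - sum(diag(unclass(cm2))), 0L)

  expect_error(brdu_confusion("T", c("T", "B")), "equal length")
  expect_error(brdu_confusion(c("T", "X"), c("T", "B")), "unknown class")
})

test_that("confusion matches a brute-force pair tally on a random fixture", {
  set.seed(31)
  truth <- sample(CLASSES, 500, replace = TRUE)
  calls <- sample(CLASSES, 500, replace = TRUE)
  cm <- brdu_confusion(truth, calls)
  for (i in CLASSES) for (j in CLASSES) {
    n <- 0L
    for (k in 1:500) if (truth[k] == i && calls[k] == j) n <- n + 1L
    expect_equal(unname(cm[i, j]), n)
  }
  expect_equal(sum(cm), 500L)
})

test_that("binary metrics apply the defining formulas and flag undefined cases", {
  m <- binary_metrics(TP = 1, TN = 1, FP = 0, FN = 0)
  expect_equal(unname(m), c(1, 1, 1, 1))
  m2 <- binary_metrics(TP = 90, TN = 95, FP = 5, FN = 10)
  expect_equal(m2[["sensitivity"]], 0.90)
  expect_equal(m2[["specificity"]], 0.95)
  expect_equal(m2[["accuracy"]], 0.925)
  expect_equal(m2[["precision"]], 90 / 95)
  m3 <- binary_metrics(TP = 0, TN = 10, FP = 0, FN = 5)
  expect_true(is.na(m3[["precision"]]))
  expect_false(is.na(m3[["accuracy"]]))
  expect_error(binary_metrics(TP = -1, TN = 0, FP = 0, FN = 0), "non-negative")
})

test_that("binary collapse of the confusion matrix equals direct counting", {
  set.seed(12)
  truth <- sample(CLASSES, 400, replace = TRUE, prob = c(1, 3, 1, 1, 3))
  calls <- sample(CLASSES, 400, replace = TRUE, prob = c(1, 3, 1, 1, 3))
  cnt <- collapse_binary(brdu_confusion(truth, calls), positive = "B")
  expect_equal(cnt$TP, sum(truth == "B" & calls == "B"))
  expect_equal(cnt$FN, sum(truth == "B" & calls != "B"))
  expect_equal(cnt$FP, sum(truth != "B" & calls == "B"))
  expect_equal(cnt$TN, sum(truth != "B" & calls != "B"))
})

test_that("multiclass summaries aggregate per-class metrics correctly", {
  truth <- rep(CLASSES, each = 4)
  cm <- brdu_confusion(truth, truth)
  expect_equal(unname(multiclass_summary(cm)), c(1, 1, 1))

  # single-class truth: weighted recall is that class's recall
  cm1 <- brdu_confusion(rep("T", 6), c("T", "T", "T", "T", "B", "A"))
  s1 <- multiclass_summary(cm1)
  expect_equal(s1[["recall"]], 4 / 6)
  expect_equal(s1[["accuracy"]], 4 / 6)

  # random fixture against an independent per-class computation
  set.seed(9)
  truth <- sample(CLASSES, 500, replace = TRUE)
  calls <- sample(CLASSES, 500, replace = TRUE)
  cm2 <- brdu_confusion(truth, calls)
  prec <- rec <- wts <- numeric(5)
  for (k in seq_along(CLASSES)) {
    cl <- CLASSES[k]
    pred_k <- sum(calls == cl)
    supp_k <- sum(truth == cl)
    prec[k] <- if (pred_k > 0) sum(truth == cl & calls == cl) / pred_k else 0
    rec[k] <- if (supp_k > 0) sum(truth == cl & calls == cl) / supp_k else 0
    wts[k] <- supp_k / 500
  }
  s2 <- multiclass_summary(cm2, "weighted")
  expect_equal(s2[["precision"]], sum(wts * prec))
  expect_equal(s2[["recall"]], sum(wts * rec))
  expect_equal(s2[["accuracy"]], mean(truth == calls))
  s3 <- multiclass_summary(cm2, "macro")
  expect_equal(s3[["recall"]], mean(rec))

  # accuracy is invariant under a relabeling of the class universe
  perm <- c(T = "A", A = "T", B = "C", C = "B", G = "G")
  cmp <- brdu_confusion(unname(perm[truth]), unname(perm[calls]))
  expect_equal(multiclass_summary(cmp)[["accuracy"]], s2[["accuracy"]])
})

test_that("auprc equals exhaustive threshold enumeration on a toy set", {
  scores <- c(0.9, 0.8, 0.7, 0.6, 0.55, 0.1)
  truth <- c(TRUE, FALSE, TRUE, TRUE, FALSE, FALSE)
  # brute force: step through every distinct threshold, sum precision * dRecall
  brute <- function(scores, truth) {
    th <- sort(unique(scores), decreasing = TRUE)
    prev_rec <- 0
    area <- 0
    for (s in th) {
      keep <- scores >= s
      prec <- sum(truth[keep]) / sum(keep)
      rec <- sum(truth[keep]) / sum(truth)
      area <- area + (rec - prev_rec) * prec
      prev_rec <- rec
    }
    area
  }
  expect_lt(abs(auprc(scores, truth) - brute(scores, truth)), 1e-12)

  set.seed(5)
  for (i in 1:10) {
    s <- round(runif(40), 2)  # duplicated scores exercise tie handling
    t <- runif(40) < 0.4
    if (!any(t) || all(t)) next
    expect_lt(abs(auprc(s, t) - brute(s, t)), 1e-12)
  }
})

test_that("auprc has the known limiting behaviors", {
  expect_equal(auprc(c(0.9, 0.8, 0.3, 0.1), c(TRUE, TRUE, FALSE, FALSE)), 1)
  set.seed(44)
  t <- runif(20000) < 0.3
  s <- runif(20000)
  expect_lt(abs(auprc(s, t) - 0.3), 0.02)  # random scores: AP ~ prevalence
  # invariance under strictly monotone score transforms
  s2 <- runif(500); t2 <- runif(500) < 0.5
  expect_equal(auprc(s2, t2), auprc(exp(3 * s2) + 1, t2))
  expect_error(auprc(c(0.1, 0.2), c(TRUE, TRUE)), "one positive and one negative")
})

test_that("evaluate_calls assembles a consistent metric set", {
  set.seed(2)
  n <- 300
  truth <- sample(CLASSES, n, replace = TRUE)
  calls <- data.frame(call = ifelse(runif(n) < 0.8, truth,
                                    sample(CLASSES, n, replace = TRUE)),
                      p_BrdU = runif(n))
  res <- evaluate_calls(calls, truth)
  expect_equal(sum(res$confusion), n)
  expect_equal(res$n, n)
  expect_equal(res$multiclass[["accuracy"]], mean(truth == calls$call))
  expect_equal(binary_metrics(res$binary_counts), res$binary)
})
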