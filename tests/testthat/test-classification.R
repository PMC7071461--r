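test_that("random splits pick 7 subjects per class without leakage", {
  ids <- list(CNT = sprintf("CNT%02d", 1:10),
              PNES = sprintf("PNES%02d", 1:10))
  plan <- makeRandomSplit(ids, trainPerClass = 7, seed = 4)
  expect_length(plan$train, 14)
  expect_length(plan$test, 6)
  expect_length(intersect(plan$train, plan$test), 0)
  expect_equal(sum(startsWith(plan$train, "CNT")), 7)
  # 1,680 training epochs at 120 epochs/subject
  expect_equal(length(plan$train) * 120, 1680)
  expect_equal(length(plan$test) * 120, 720)
  plan2 <- makeRandomSplit(ids, trainPerClass = 7, seed = 4)
  expect_identical(plan, plan2)
  expect_error(makeRandomSplit(list(CNT = ids$CNT[1:5], PNES = ids$PNES),
                               trainPerClass = 7), "more than")
})

test_that("LOO plans hold out each subject exactly once", {
  ids <- sprintf("S%02d", 1:20)
  plans <- makeLooSplits(ids)
  expect_length(plans, 20)
  held <- vapply(plans, function(p) p$test, "")
  expect_setequal(held, ids)
  for (p in plans) {
    expect_length(intersect(p$train, p$test), 0)
    expect_setequal(c(p$train, p$test), ids)
  }
  expect_error(makeLooSplits("S1"), ">= 2")
})

test_that("every split generated across schemes and seeds is leakage-free", {
  ids <- list(CNT = sprintf("CNT%02d", 1:10),
              PNES = sprintf("PNES%02d", 1:10))
  for (seed in 1:25) {
    p <- makeRandomSplit(ids, trainPerClass = 7, seed = seed)
    expect_length(intersect(p$train, p$test), 0)
    expect_setequal(c(p$train, p$test), unlist(ids))
  }
  for (p in makeLooSplits(unlist(ids)))
    expect_length(intersect(p$train, p$test), 0)
})

test_that("standardization is train-fitted, degenerate-safe and idempotent", {
  tr <- cbind(a = c(3, 5, 7), b = c(1, 1, 1))
  te <- cbind(a = c(7, 5), b = c(9, 1))
  s <- standardizeFeatures(tr, te)
  expect_equal(unname(s$test[1, "a"]), 1)  # (7-5)/sd(3,5,7) = 2/2
  expect_equal(unname(s$train[, "b"]), c(0, 0, 0))
  expect_equal(unname(s$test[, "b"]), c(0, 0))
  s2 <- standardizeFeatures(s$train, s$test)
  expect_equal(s2$train, s$train, tolerance = 1e-12)
  expect_error(standardizeFeatures(tr, te[, c("b", "a")]), "schema")
  # train column mean 5, sd 2 -> value 7 maps to 1
  tr2 <- cbind(x = c(3, 7))  # mean 5, sd (sample) 2.828; population def uses sd()
  mu <- mean(tr2[, 1]); sdv <- sd(tr2[, 1])
  s3 <- standardizeFeatures(tr2, cbind(x = mu + sdv))
  expect_equal(unname(s3$test[1, 1]), 1)
})

test_that("all three classifiers separate well-separated Gaussian clouds", {
  ft <- toyFeatureTable(sep = 10)
  X <- featureMatrix(ft)
  cd <- SummarizedExperiment::colData(ft)
  trIdx <- cd$subject_id %in% c("CNT01", "CNT02", "PNES01", "PNES02")
  for (kind in c("SVM", "LDA", "NB")) {
    ps <- trainAndScore(X[trIdx, ], X[!trIdx, ],
                        as.character(cd$class_label[trIdx]),
                        classifierSpec(kind))
    cm <- confusionMetrics(as.character(cd$class_label[!trIdx]), ps$labels)
    expect_equal(cm$accuracy, 1.0)
  }
  expect_error(trainAndScore(X[trIdx, ], X[!trIdx, ],
                             rep("CNT", sum(trIdx)), classifierSpec("LDA")),
               "both classes")
})

test_that("duplicating training rows leaves LDA and NB predictions unchanged", {
  ft <- toyFeatureTable(sep = 1.5, seed = 9)
  X <- featureMatrix(ft)
  cd <- SummarizedExperiment::colData(ft)
  trIdx <- which(cd$subject_id %in% c("CNT01", "CNT02", "PNES01", "PNES02"))
  teIdx <- setdiff(seq_len(nrow(X)), trIdx)
  y <- as.character(cd$class_label[trIdx])
  # class means are duplication-invariant exactly; the n-1 variance
  # estimators shift slightly, so posteriors agree only approximately
  for (kind in c("LDA", "NB")) {
    a <- trainAndScore(X[trIdx, ], X[teIdx, ], y, classifierSpec(kind))
    b <- trainAndScore(X[c(trIdx, trIdx), ], X[teIdx, ],
                       c(y, y), classifierSpec(kind))
    expect_identical(a$labels, b$labels)
    expect_lt(max(abs(a$scores - b$scores)), 0.05)
  }
})

test_that("confusion metrics satisfy the printed formula identities", {
  cm <- confusionMetrics(c(rep("PNES", 10), rep("CNT", 10)),
                         c(rep("PNES", 9), "CNT", rep("CNT", 9), "PNES"))
  expect_equal(unname(cm$counts), c(9, 9, 1, 1))
  expect_equal(cm$accuracy, 0.9)
  perfect <- confusionMetrics(c("PNES", "CNT"), c("PNES", "CNT"))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$perClass$precision, c(1, 1))
  expect_equal(perfect$perClass$f1, c(1, 1))
  expect_error(confusionMetrics(character(0), character(0)), "nonempty")
  # property: random confusion tables vs the direct formulas
  set.seed(30)
  for (i in 1:200) {
    n <- sample(4:60, 1)
    truth <- sample(c("CNT", "PNES"), n, replace = TRUE)
    pred <- sample(c("CNT", "PNES"), n, replace = TRUE)
    cm <- confusionMetrics(truth, pred)
    TP <- cm$counts[["TP"]]; TN <- cm$counts[["TN"]]
    FP <- cm$counts[["FP"]]; FN <- cm$counts[["FN"]]
    expect_equal(sum(cm$counts), n)
    expect_equal(cm$accuracy, (TP + TN) / (TP + FP + TN + FN))
    P <- if (TP + FP > 0) TP / (TP + FP) else NA_real_
    R <- if (TP + FN > 0) TP / (TP + FN) else NA_real_
    expect_equal(cm$perClass$precision[2], P)
    expect_equal(cm$perClass$recall[2], R)
    if (!is.na(P) && !is.na(R) && P + R > 0)
      expect_equal(cm$perClass$f1[2], 2 * P * R / (P + R))
  }
})

test_that("AUC equals the rank-statistic oracle, including ties", {
  labels <- c(rep("PNES", 3), rep("CNT", 3))
  expect_equal(rocAuc(c(1, 1, 1, 0, 0, 0), labels)$auc, 1.0)
  set.seed(31)
  for (i in 1:100) {
    n <- sample(6:80, 1)
    truth <- c("PNES", "CNT",
               sample(c("CNT", "PNES"), n - 2, replace = TRUE))
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # heavy ties
    expect_equal(rocAuc(scores, truth)$auc, rankAuc(scores, truth),
                 tolerance = 1e-12)
  }
  # label-independent scores give chance AUC at large n
  set.seed(32)
  truth <- sample(c("CNT", "PNES"), 2000, replace = TRUE)
  expect_equal(rocAuc(rnorm(2000), truth)$auc, 0.5, tolerance = 0.05)
  expect_error(rocAuc(1:3, rep("PNES", 3)), "both classes")
})

test_that("our ROC/AUC agrees with pROC on random scores", {
  skip_if_not_installed("pROC")
  set.seed(33)
  for (i in 1:10) {
    truth <- c("PNES", "CNT", sample(c("CNT", "PNES"), 48, replace = TRUE))
    scores <- round(rnorm(50), 1)
    ours <- rocAuc(scores, truth)$auc
    theirs <- as.numeric(pROC::auc(pROC::roc(
      response = truth, predictor = scores, levels = c("CNT", "PNES"),
      direction = "<", quiet = TRUE)))
    expect_equal(ours, theirs, tolerance = 1e-12)
  }
})

test_that("ROC vertical averaging interpolates on a common FPR grid", {
  r1 <- data.frame(fpr = c(0, 0, 1), tpr = c(0, 1, 1))   # perfect
  r2 <- data.frame(fpr = c(0, 1, 1), tpr = c(0, 0, 1))   # worst
  avg <- averageRoc(list(r1, r2), grid = c(0, 0.5, 1))
  expect_equal(avg$tpr, c(0.5, 0.5, 1))
})

test_that("the evaluation grid covers classifiers x schemes without leakage", {
  ft <- smallFeatureTable(nPerClass = 3, nChannels = 3, nEpochs = 6)
  rep <- suppressWarnings(
    evaluateCohort(ft, seed = 2, trainPerClass = 2))
  res <- evalResults(rep)
  # 3 classifiers x (1 RS + 6 LOO) = 21 rows
  expect_equal(nrow(res), 21)
  expect_setequal(unique(res$classifier), c("SVM", "LDA", "NB"))
  expect_equal(sum(res$scheme == "loo"), 18)
  # summary is recomputable from the per-split rows
  s <- evalSummary(rep)
  loo <- res[res$scheme == "loo" & res$classifier == "SVM", ]
  expect_equal(s$accuracy_mean[s$scheme == "loo" & s$classifier == "SVM"],
               mean(loo$accuracy), tolerance = 1e-12)
  expect_equal(s$accuracy_sd[s$scheme == "loo" & s$classifier == "SVM"],
               sd(loo$accuracy), tolerance = 1e-12)
  # all confusion counts add to the test epoch count
  expect_equal(res$TP + res$TN + res$FP + res$FN, res$n_test)
  # shuffling epoch order within subjects leaves LOO means unchanged
  perm <- order(SummarizedExperiment::colData(ft)$subject_id,
                rev(seq_len(ncol(ft))))
  rep2 <- suppressWarnings(
    evaluateCohort(ft[, perm], seed = 2, trainPerClass = 2))
  s2 <- evalSummary(rep2)
  expect_equal(s2$accuracy_mean[s2$scheme == "loo"],
               s$accuracy_mean[s$scheme == "loo"], tolerance = 1e-12)
})
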