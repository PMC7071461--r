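#' Classifier specification
#'
#' The three classifiers of the pipeline. SVM uses the radial basis
#' kernel exp(-gamma * ||x - x_k||^2) with \code{gamma = 0.01} and cost
#' \code{C = 1} by default (\code{coef0} and \code{degree} are inert for
#' the RBF kernel and kept only for provenance); LDA and Gaussian naive
#' Bayes use library defaults.
#'
#' @param kind "SVM", "LDA" or "NB".
#' @param gamma RBF kernel width parameter (> 0).
#' @param cost SVM misclassification cost C (> 0).
#' @param coef0,degree recorded but unused with the RBF kernel.
#' @return list of class \code{ClassifierSpec}.
#' @export
classifierSpec <- function(kind = c("SVM", "LDA", "NB"), gamma = 0.01,
                           cost = 1, coef0 = 0, degree = 3) {
  kind <- match.arg(kind)
  if (gamma <= 0 || cost <= 0) stop("gamma and cost must be > 0")
  structure(list(kind = kind, gamma = gamma, cost = cost,
                 coef0 = coef0, degree = degree),
            class = "ClassifierSpec")
}

#' Subject-level 70/30 random split
#'
#' Draws \code{trainPerClass} training subjects per class uniformly
#' without replacement; the remainder form the test set. Splitting
#' always operates on whole subjects so that no subject contributes
#' epochs to both sides.
#'
#' @param subjectsByClass named list mapping class label to its subject
#'   ids.
#' @param trainPerClass training subjects per class (default 7).
#' @param seed integer seed; the plan is deterministic given it.
#' @return list of class \code{SplitPlan} with elements \code{scheme},
#'   \code{train}, \code{test}, \code{seed}.
#' @export
makeRandomSplit <- function(subjectsByClass, trainPerClass = 7, seed = 1) {
  train <- character(0); test <- character(0)
  rs <- local({ set.seed(as.integer(seed)); lapply(subjectsByClass, function(ids) {
    if (length(ids) <= trainPerClass)
      stop("each class needs more than trainPerClass subjects")
    tr <- sample(ids, trainPerClass)
    list(train = tr, test = setdiff(ids, tr))
  })})
  for (cl in rs) { train <- c(train, cl$train); test <- c(test, cl$test) }
  structure(list(scheme = "random_split", train = train, test = test,
                 seed = as.integer(seed)),
            class = "SplitPlan")
}

#' Leave-one-subject-out split plans
#'
#' One plan per subject: that subject's epochs are the test set, all
#' remaining subjects train.
#'
#' @param subjectIds character vector of all subject ids (>= 2).
#' @return list of \code{SplitPlan}s, one per subject.
#' @export
makeLooSplits <- function(subjectIds) {
  subjectIds <- unique(subjectIds)
  if (length(subjectIds) < 2L) stop("leave-one-out needs >= 2 subjects")
  lapply(subjectIds, function(sid) {
    structure(list(scheme = "loo", train = setdiff(subjectIds, sid),
                   test = sid, seed = NA_integer_),
              class = "SplitPlan")
  })
}

assertNoLeakage <- function(plan) {
  if (length(intersect(plan$train, plan$test)) > 0L)
    stop("subject-level leakage: train and test subject sets overlap")
  invisible(TRUE)
}

#' Train-fitted z-scoring of feature columns
#'
#' Centers and scales every column by the training mean and SD and
#' applies the same transform to the test matrix. Columns constant in
#' training map to all zeros on both sides.
#'
#' @param trainX,testX numeric matrices with identical columns.
#' @return list with elements \code{train}, \code{test}, \code{center},
#'   \code{scale}.
#' @export
standardizeFeatures <- function(trainX, testX) {
  if (!identical(colnames(trainX), colnames(testX)))
    stop("train and test feature schemas differ")
  mu <- colMeans(trainX)
  sdv <- apply(trainX, 2, sd)
  zero <- sdv == 0
  sdv[zero] <- 1
  tr <- sweep(sweep(trainX, 2, mu), 2, sdv, "/")
  te <- sweep(sweep(testX, 2, mu), 2, sdv, "/")
  tr[, zero] <- 0; te[, zero] <- 0
  list(train = tr, test = te, center = mu,
       scale = ifelse(zero, 0, sdv))
}

#' Train a classifier and score test epochs
#'
#' Fits the requested classifier on the training matrix and returns a
#' hard label plus a continuous PNES-oriented score (decision value or
#' positive-class posterior; larger means more PNES-like) per test
#' epoch. Feature columns constant in training are dropped before
#' fitting (they carry no information and break LDA / naive Bayes).
#'
#' All three classifiers are fitted calibration-neutral: balanced class
#' weights for the SVM, uniform priors for LDA, and prior-corrected
#' posteriors for naive Bayes. Subject-level leave-one-out necessarily
#' trains on slightly imbalanced classes (the held-out subject's class
#' is one short), and with weak class signal an unweighted fit drifts
#' toward the majority class — which is always the wrong one for the
#' held-out subject. Balancing removes that bias and is inert for
#' balanced training sets such as the 7+7 random split.
#'
#' @param trainX,testX numeric feature matrices (epochs x features).
#' @param trainY character labels ("CNT"/"PNES") for the training rows;
#'   both classes must be present.
#' @param spec a \code{\link{classifierSpec}}.
#' @return list with \code{labels} (character) and \code{scores}
#'   (numeric) for the test rows.
#' @export
trainAndScore <- function(trainX, testX, trainY, spec = classifierSpec("SVM")) {
  lv <- c("CNT", "PNES")
  y <- factor(trainY, levels = lv)
  tab <- table(y)
  if (any(tab == 0L)) stop("training set must contain both classes")
  keep <- apply(trainX, 2, function(v) sd(v) > 0)
  trainX <- trainX[, keep, drop = FALSE]
  testX <- testX[, keep, drop = FALSE]
  if (ncol(trainX) == 0L) stop("no informative features in training set")
  if (spec$kind == "SVM") {
    cw <- sum(tab) / (2 * tab)
    fit <- e1071::svm(x = trainX, y = y, kernel = "radial",
                      gamma = spec$gamma, cost = spec$cost, scale = FALSE,
                      class.weights = stats::setNames(as.numeric(cw), lv))
    pr <- predict(fit, testX, decision.values = TRUE)
    dv <- drop(attr(pr, "decision.values"))
    # decision values are oriented "first/second" of the colname pair
    orient <- colnames(attr(pr, "decision.values"))[1]
    scores <- if (startsWith(orient, "PNES")) dv else -dv
    labels <- as.character(pr)
  } else if (spec$kind == "LDA") {
    fit <- withCallingHandlers(
      MASS::lda(trainX, grouping = y, prior = c(0.5, 0.5)),
      warning = function(w) {
        # correlated PSD moments routinely trip the collinearity warning
        if (grepl("collinear", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
    pr <- predict(fit, testX)
    scores <- pr$posterior[, "PNES"]
    labels <- as.character(pr$class)
  } else {
    fit <- e1071::naiveBayes(trainX, y)
    post <- predict(fit, testX, type = "raw")
    # rescale away the empirical class prior -> uniform-prior posterior
    post <- sweep(post, 2, as.numeric(tab) / sum(tab), "/")
    post <- post / rowSums(post)
    scores <- post[, "PNES"]
    labels <- lv[max.col(post, ties.method = "first")]
  }
  list(labels = labels, scores = as.numeric(scores))
}
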