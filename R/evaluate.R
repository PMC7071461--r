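splitFeatureTable <- function(ft, plan) {
  assertNoLeakage(plan)
  cd <- SummarizedExperiment::colData(ft)
  trIdx <- which(cd$subject_id %in% plan$train)
  teIdx <- which(cd$subject_id %in% plan$test)
  if (length(trIdx) == 0L || length(teIdx) == 0L)
    stop("split produced an empty train or test partition")
  X <- featureMatrix(ft)
  list(trainX = X[trIdx, , drop = FALSE],
       testX = X[teIdx, , drop = FALSE],
       trainY = as.character(cd$class_label[trIdx]),
       testY = as.character(cd$class_label[teIdx]))
}

evaluateOneSplit <- function(ft, plan, specs, scale = TRUE) {
  d <- splitFeatureTable(ft, plan)
  if (scale) {
    sc <- standardizeFeatures(d$trainX, d$testX)
    d$trainX <- sc$train; d$testX <- sc$test
  }
  rows <- list(); rocs <- list()
  for (spec in specs) {
    ps <- trainAndScore(d$trainX, d$testX, d$trainY, spec)
    cm <- confusionMetrics(d$testY, ps$labels)
    # single-class test sets (typical under leave-one-subject-out) have
    # no defined ROC; record NA and let the summary skip it
    ra <- if (length(unique(d$testY)) > 1L) rocAuc(ps$scores, d$testY)
          else list(roc = NULL, auc = NA_real_)
    pn <- cm$perClass[cm$perClass$class == "PNES", ]
    rows[[spec$kind]] <- data.frame(
      classifier = spec$kind, scheme = plan$scheme,
      test_subjects = paste(plan$test, collapse = "+"),
      n_test = length(d$testY),
      TP = cm$counts[["TP"]], TN = cm$counts[["TN"]],
      FP = cm$counts[["FP"]], FN = cm$counts[["FN"]],
      accuracy = cm$accuracy, precision = pn$precision,
      recall = pn$recall, f1 = pn$f1, auc = ra$auc,
      stringsAsFactors = FALSE)
    if (!is.null(ra$roc)) rocs[[spec$kind]] <- ra$roc
  }
  list(rows = do.call(rbind, rows), rocs = rocs)
}

summarizeResults <- function(results) {
  metrics <- c("accuracy", "precision", "recall", "f1", "auc")
  key <- interaction(results$classifier, results$scheme, drop = TRUE)
  out <- lapply(split(results, key), function(g) {
    row <- data.frame(classifier = g$classifier[1], scheme = g$scheme[1],
                      n_splits = nrow(g), stringsAsFactors = FALSE)
    for (m in metrics) {
      row[[paste0(m, "_mean")]] <- mean(g[[m]], na.rm = TRUE)
      row[[paste0(m, "_sd")]] <- if (nrow(g) > 1)
        sd(g[[m]], na.rm = TRUE) else 0
    }
    row
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$scheme, out$classifier), , drop = FALSE]
}

#' Evaluate classifiers over validation schemes
#'
#' Runs the full classifier x scheme grid on a feature table:
#' subject-level random split (one or more seeded repetitions of the
#' 7-train / remainder-test draw per class) and leave-one-subject-out.
#' Every split is checked for subject-level leakage before training.
#' Per-split confusion counts, PNES-positive metrics, and ROC/AUC are
#' collected, with mean and SD summaries per classifier x scheme.
#'
#' LOO splits where the single held-out subject leaves only one class
#' in the test set have undefined AUC/one-class precision components;
#' those entries are NA and excluded from the corresponding means.
#'
#' @param ft an \linkS4class{EEGFeatureTable} with >= 2 subjects per
#'   class.
#' @param classifiers character subset of c("SVM", "LDA", "NB") or a
#'   list of \code{\link{classifierSpec}}s.
#' @param schemes character subset of c("random_split", "loo").
#' @param seed base seed for the random-split draws.
#' @param nRandomSplits number of repeated random splits (seeded
#'   seed, seed+1, ...; default 1).
#' @param trainPerClass training subjects per class in the random split.
#' @param scale standardize features with train-fitted z-scores
#'   (default TRUE).
#' @return an \linkS4class{EvalReport}.
#' @export
evaluateCohort <- function(ft, classifiers = c("SVM", "LDA", "NB"),
                           schemes = c("random_split", "loo"), seed = 1,
                           nRandomSplits = 1, trainPerClass = 7,
                           scale = TRUE) {
  if (is.character(classifiers))
    classifiers <- lapply(classifiers, classifierSpec)
  cd <- SummarizedExperiment::colData(ft)
  subjTab <- unique(data.frame(subject_id = cd$subject_id,
                               class_label = cd$class_label,
                               stringsAsFactors = FALSE))
  counts <- table(subjTab$class_label)
  if (length(counts) < 2L || any(counts < 2L))
    stop("need at least two subjects in each of two classes")
  subjectsByClass <- split(subjTab$subject_id, subjTab$class_label)
  plans <- list()
  if ("random_split" %in% schemes) {
    for (r in seq_len(nRandomSplits))
      plans <- c(plans, list(makeRandomSplit(subjectsByClass,
                                             trainPerClass = trainPerClass,
                                             seed = seed + r - 1L)))
  }
  if ("loo" %in% schemes)
    plans <- c(plans, makeLooSplits(subjTab$subject_id))
  allRows <- list(); allRocs <- list()
  for (i in seq_along(plans)) {
    ev <- evaluateOneSplit(ft, plans[[i]], classifiers, scale = scale)
    ev$rows$split <- i
    allRows[[i]] <- ev$rows
    for (k in names(ev$rocs))
      allRocs[[paste(k, plans[[i]]$scheme, i, sep = ".")]] <- ev$rocs[[k]]
  }
  results <- do.call(rbind, allRows)
  rownames(results) <- NULL
  new("EvalReport", results = results, roc = allRocs,
      summary = summarizeResults(results))
}

#' Write an EvalReport to JSON and CSV
#'
#' @param report an \linkS4class{EvalReport}.
#' @param dir output directory.
#' @param prefix file name stem.
#' @return character vector of the files written, invisibly.
#' @export
writeEvalReport <- function(report, dir, prefix = "eval") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fJson <- file.path(dir, paste0(prefix, "_summary.json"))
  fCsv <- file.path(dir, paste0(prefix, "_splits.csv"))
  jsonlite::write_json(list(summary = evalSummary(report)),
                       fJson, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA, na = "null")
  data.table::fwrite(evalResults(report), fCsv)
  rocFiles <- character(0)
  for (k in names(evalRoc(report))) {
    fr <- file.path(dir, paste0(prefix, "_roc_", k, ".csv"))
    data.table::fwrite(evalRoc(report)[[k]], fr)
    rocFiles <- c(rocFiles, fr)
  }
  invisible(c(fJson, fCsv, rocFiles))
}
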