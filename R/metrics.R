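#' Confusion counts and classification metrics
#'
#' PNES is the positive class for the headline counts:
#' TP = PNES predicted PNES, TN = CNT predicted CNT. Metrics follow the
#' standard identities accuracy = (TP+TN)/(TP+FP+TN+FN),
#' precision = TP/(TP+FP), recall = TP/(TP+FN),
#' F1 = 2*precision*recall/(precision+recall); per-class precision /
#' recall / F1 treat each class in turn as positive. Undefined ratios
#' (zero denominators) are returned as NA.
#'
#' @param truth,predicted character vectors in \{"CNT", "PNES"\} of
#'   equal positive length.
#' @return list with \code{counts} (named TP/TN/FP/FN),
#'   \code{accuracy}, \code{perClass} (data.frame class / precision /
#'   recall / f1) and \code{macro} (unweighted mean over the classes).
#' @export
#' @examples
#' confusionMetrics(c("PNES", "CNT"), c("PNES", "PNES"))
confusionMetrics <- function(truth, predicted) {
  if (length(truth) == 0L || length(truth) != length(predicted))
    stop("truth and predicted must be nonempty and of equal length")
  lv <- c("CNT", "PNES")
  if (!all(truth %in% lv) || !all(predicted %in% lv))
    stop("labels must be CNT or PNES")
  TP <- sum(truth == "PNES" & predicted == "PNES")
  TN <- sum(truth == "CNT" & predicted == "CNT")
  FP <- sum(truth == "CNT" & predicted == "PNES")
  FN <- sum(truth == "PNES" & predicted == "CNT")
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  prc <- function(tp, fp) ratio(tp, tp + fp)
  rcl <- function(tp, fn) ratio(tp, tp + fn)
  f1of <- function(p, r) {
    if (is.na(p) || is.na(r) || p + r == 0) return(NA_real_)
    2 * p * r / (p + r)
  }
  pP <- prc(TP, FP); rP <- rcl(TP, FN)
  pC <- prc(TN, FN); rC <- rcl(TN, FP)
  perClass <- data.frame(
    class = c("CNT", "PNES"),
    precision = c(pC, pP), recall = c(rC, rP),
    f1 = c(f1of(pC, rC), f1of(pP, rP)),
    stringsAsFactors = FALSE)
  list(counts = c(TP = TP, TN = TN, FP = FP, FN = FN),
       accuracy = (TP + TN) / (TP + TN + FP + FN),
       perClass = perClass,
       macro = c(precision = mean(perClass$precision),
                 recall = mean(perClass$recall),
                 f1 = mean(perClass$f1)))
}

#' ROC curve and AUC from continuous scores
#'
#' Sweeps a decision threshold over the scores (larger score = more
#' PNES-like); tied scores are grouped into a single step. AUC is the
#' trapezoidal area under the resulting curve, which equals the
#' Mann-Whitney U statistic divided by n+ * n- (ties counted 1/2).
#'
#' @param scores numeric scores, one per epoch.
#' @param truth character labels in \{"CNT", "PNES"\}; both classes
#'   must be present.
#' @return list with \code{roc} (data.frame fpr / tpr / threshold,
#'   including the (0,0) and (1,1) endpoints) and \code{auc}.
#' @export
rocAuc <- function(scores, truth) {
  if (length(scores) != length(truth)) stop("length mismatch")
  pos <- truth == "PNES"
  nP <- sum(pos); nN <- sum(!pos)
  if (nP == 0L || nN == 0L)
    stop("AUC undefined: both classes must be present")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; p <- pos[o]
  # group tied scores into single threshold steps
  grp <- cumsum(!duplicated(s))
  tpG <- tapply(as.numeric(p), grp, sum)
  fpG <- tapply(as.numeric(!p), grp, sum)
  tpr <- c(0, cumsum(tpG) / nP)
  fpr <- c(0, cumsum(fpG) / nN)
  thr <- c(Inf, s[!duplicated(s)])
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  list(roc = data.frame(fpr = fpr, tpr = tpr, threshold = thr),
       auc = auc)
}

#' Vertically average ROC curves on a common FPR grid
#'
#' Interpolates each curve's TPR at a shared false-positive-rate grid
#' (stepwise-constant, matching the empirical curve) and averages
#' across curves; used to summarise a validation scheme's per-split
#' ROC curves.
#'
#' @param rocList list of ROC data.frames from \code{\link{rocAuc}}.
#' @param grid FPR grid in [0, 1].
#' @return data.frame with fpr and the averaged tpr.
#' @export
averageRoc <- function(rocList, grid = seq(0, 1, by = 0.01)) {
  tprs <- vapply(rocList, function(rc) {
    approx(rc$fpr, rc$tpr, xout = grid, method = "constant",
           f = 0, ties = max, rule = 2)$y
  }, numeric(length(grid)))
  data.frame(fpr = grid, tpr = rowMeans(as.matrix(tprs)))
}
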