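# Evaluation: confusion metrics, ROC/AUC, target-jackknife cross-validation
# and the chromosome-parity holdout split.

.asBinary <- function(labels) {
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.logical(labels)) labels <- ifelse(labels, "positive", "negative")
  if (is.numeric(labels)) labels <- ifelse(labels == 1, "positive",
                                           "negative")
  if (!all(labels %in% c("negative", "positive")))
    stop("labels must be 'positive'/'negative' (or logical / 0-1)")
  labels == "positive"
}

#' Confusion-matrix metrics
#'
#' Computes TP/TN/FP/FN and the four summary statistics:
#' ACC = (TP+TN)/(TP+FP+TN+FN), SN = TP/(TP+FN), SP = TN/(TN+FP), and
#' MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)), with
#' MCC = 0 when its denominator vanishes.
#'
#' @param labels true labels (positive = methylated).
#' @param predictions predicted labels, same encoding.
#' @param scores optional real-valued scores; when given, the ROC curve and
#'   AUC are filled in via [rocAuc()].
#' @return an \linkS4class{EvalReport}
#' @examples
#' confusionMetrics(c(1, 1, 0, 0), c(1, 0, 0, 0))
#' @export
confusionMetrics <- function(labels, predictions, scores = NULL) {
  y <- .asBinary(labels)
  p <- .asBinary(predictions)
  if (length(y) == 0L) stop("empty input")
  if (length(y) != length(p)) stop("labels and predictions differ in length")
  tp <- sum(y & p); tn <- sum(!y & !p)
  fp <- sum(!y & p); fn <- sum(y & !p)
  acc <- (tp + tn) / (tp + fp + tn + fn)
  sn <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  sp <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  den <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  mcc <- if (den > 0) (tp * tn - fp * fn) / den else 0
  roc <- data.frame(fpr = numeric(0), tpr = numeric(0))
  auc <- NA_real_
  if (!is.null(scores)) {
    ra <- rocAuc(labels, scores)
    roc <- ra$roc; auc <- ra$auc
  }
  new("EvalReport", tp = as.integer(tp), tn = as.integer(tn),
      fp = as.integer(fp), fn = as.integer(fn),
      acc = acc, mcc = mcc, sn = sn, sp = sp, roc = roc, auc = auc)
}

#' ROC curve and AUC
#'
#' Sweeps the threshold over all distinct score values to trace the ROC,
#' and computes the AUC as the trapezoidal area, which for this sweep
#' equals the Mann-Whitney statistic: the probability that a random
#' positive outscores a random negative, counting ties as 1/2.
#'
#' @param labels true binary labels.
#' @param scores real-valued scores, higher = more positive.
#' @return list with \code{roc} (data.frame of fpr, tpr from (0,0) to
#'   (1,1)) and \code{auc}.
#' @export
rocAuc <- function(labels, scores) {
  y <- .asBinary(labels)
  stopifnot(length(y) == length(scores), all(is.finite(scores)))
  nPos <- sum(y); nNeg <- sum(!y)
  if (nPos == 0L || nNeg == 0L)
    stop("ROC needs both classes present")
  ord <- order(scores, decreasing = TRUE)
  ys <- y[ord]; ss <- scores[ord]
  # merge tied scores into single threshold steps
  last <- !duplicated(ss, fromLast = TRUE) # last index of each tie group
  cumTp <- cumsum(ys)[last]
  cumFp <- cumsum(!ys)[last]
  roc <- data.frame(fpr = c(0, cumFp / nNeg), tpr = c(0, cumTp / nPos))
  auc <- sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) +
                              diff(roc$tpr) / 2))
  list(roc = roc, auc = auc)
}

#' Target-jackknife cross-validation
#'
#' Leave-one-out restricted to real samples: every real sample is held out
#' once and predicted by a model trained on all remaining rows (real and
#' synthetic); synthetic (SMOTE) rows only ever train. Predictions are
#' pooled into a single confusion matrix and ROC.
#'
#' @param fs a \linkS4class{MethylFeatureSet} with origin flags.
#' @param trainer function \code{(x, labels) -> model} whose model supports
#'   \code{predict(model, newdata, type = "response")}; defaults to
#'   [trainSparseBayes()].
#' @param threshold score cut-off for labels (default 0.5).
#' @param verbose report progress every 100 rounds.
#' @return an \linkS4class{EvalReport}; the attribute \code{"rounds"} gives
#'   the number of train/predict rounds (= number of real samples) and
#'   \code{"scores"} the pooled held-out scores in real-sample order.
#' @export
targetJackknife <- function(fs, trainer = NULL, threshold = 0.5,
                            verbose = FALSE) {
  stopifnot(is(fs, "MethylFeatureSet"))
  if (is.null(trainer))
    trainer <- function(x, labels) trainSparseBayes(x, labels)
  info <- sampleInfo(fs)
  realIdx <- which(info$origin == "real")
  if (length(realIdx) == 0L) stop("no real samples to evaluate")
  X <- featureMatrix(fs)
  lab <- as.character(info$label)
  scores <- numeric(length(realIdx))
  for (r in seq_along(realIdx)) {
    i <- realIdx[r]
    model <- trainer(X[-i, , drop = FALSE], lab[-i])
    scores[r] <- predict(model, X[i, , drop = FALSE], type = "response")
    if (verbose && r %% 100L == 0L)
      message("jackknife round ", r, "/", length(realIdx))
  }
  truth <- lab[realIdx]
  out <- confusionMetrics(truth,
                          ifelse(scores >= threshold, "positive",
                                 "negative"),
                          scores = scores)
  attr(out, "rounds") <- length(realIdx)
  attr(out, "scores") <- scores
  out
}

#' Chromosome-parity holdout split
#'
#' Routes samples on chromosomes 1, 3, 5, 7, 9, 11 to the training set and
#' samples on chromosomes 2, 4, 6, 8, 10, 12 to the test set; samples on
#' any other chromosome (or without coordinates) are excluded and reported.
#' Chromosome names may carry a "chr" prefix.
#'
#' @param x a \linkS4class{MethylWindowSet} or \linkS4class{MethylFeatureSet}
#'   with chromosome names.
#' @return list with \code{train}, \code{test} (same class as \code{x}) and
#'   \code{excluded} (character identifiers).
#' @export
chromosomeHoldoutSplit <- function(x) {
  chrom <- if (is(x, "MethylWindowSet")) x@chrom
           else if (is(x, "MethylFeatureSet")) sampleInfo(x)$chrom
           else stop("unsupported input")
  if (all(is.na(chrom)))
    stop("no chromosome coordinates present; holdout split is undefined")
  core <- sub("^chr", "", chrom, ignore.case = TRUE)
  trainSet <- core %in% c("1", "3", "5", "7", "9", "11")
  testSet <- core %in% c("2", "4", "6", "8", "10", "12")
  ids <- if (is(x, "MethylWindowSet")) names(windowSeqs(x))
         else rownames(featureMatrix(x))
  sub <- if (is(x, "MethylWindowSet")) function(i) x[i]
         else function(i) .subsetFeatureSet(x, i)
  list(train = sub(which(trainSet)), test = sub(which(testSet)),
       excluded = ids[!trainSet & !testSet])
}

setMethod("show", "EvalReport", function(object) {
  cat("EvalReport\n")
  cat(sprintf("  TP %d  FP %d  TN %d  FN %d\n",
              object@tp, object@fp, object@tn, object@fn))
  cat(sprintf("  ACC %.4f  MCC %.4f  SN %.4f  SP %.4f\n",
              object@acc, object@mcc, object@sn, object@sp))
  if (!is.na(object@auc))
    cat(sprintf("  AUC %.4f  (%d ROC points)\n", object@auc,
                nrow(object@roc)))
})

#' Serialize an EvalReport
#'
#' @param report an \linkS4class{EvalReport}
#' @param path output file; a plain-text key-value file. With
#'   \code{rocPath}, the ROC points are written as tab-separated columns.
#' @param rocPath optional path for the ROC points.
#' @return invisibly, the named metric vector written
#' @export
writeEvalReport <- function(report, path, rocPath = NULL) {
  vals <- c(TP = report@tp, FP = report@fp, TN = report@tn,
            FN = report@fn, ACC = report@acc, MCC = report@mcc,
            SN = report@sn, SP = report@sp, AUC = report@auc)
  writeLines(paste(names(vals), vals, sep = "\t"), path)
  if (!is.null(rocPath))
    utils::write.table(report@roc, rocPath, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  invisible(vals)
}
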