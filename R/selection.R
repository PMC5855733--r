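# Importance-ranked incremental feature selection: rank the features by the
# absolute weight of a linear-kernel soft-margin SVM, then grow nested
# prefixes of the ranking and keep the prefix with the best cross-validated
# accuracy.

#' SVM-weight importance scores
#'
#' Trains a single linear-kernel soft-margin SVM on the standardized
#' feature table and scores feature j by |w_j|, the magnitude of its weight
#' in the primal hyperplane. Constant features are excluded from
#' standardization and assigned score 0.
#'
#' @param x feature matrix or \linkS4class{MethylFeatureSet}.
#' @param labels binary labels (taken from \code{x} when omitted).
#' @param cost SVM cost parameter (default 1).
#' @return numeric score per feature column
#' @export
importanceScores <- function(x, labels = NULL, cost = 1) {
  rf <- .resolveFeatures(x)
  X <- rf$X
  if (is.null(labels)) labels <- rf$labels
  bl <- .binarizeLabels(labels)
  isConst <- apply(X, 2L, function(col) length(unique(col)) == 1L)
  scores <- numeric(ncol(X))
  names(scores) <- colnames(X)
  if (all(isConst)) stop("all features are constant")
  std <- .fitStandardizer(X[, !isConst, drop = FALSE])
  Xs <- .applyStandardizer(X[, !isConst, drop = FALSE], std)
  yf <- factor(ifelse(bl$y == 1, bl$levels[2], bl$levels[1]),
               levels = bl$levels)
  fit <- e1071::svm(Xs, yf, kernel = "linear", cost = cost, scale = FALSE)
  w <- drop(crossprod(fit$coefs, fit$SV))
  scores[!isConst] <- abs(w)
  scores
}

# default prefix evaluator: k-fold CV accuracy of a Gaussian SVM
#' k-fold cross-validated accuracy evaluator
#'
#' @param folds number of folds (default 5).
#' @param trainer model-fitting function with the package predict contract;
#'   defaults to [trainSVM()].
#' @param seed seed controlling the fold assignment.
#' @return a function \code{(x, labels) -> accuracy} usable as the
#'   \code{evaluator} of [incrementalSelection()].
#' @export
cvAccuracyEvaluator <- function(folds = 5L, trainer = trainSVM, seed = 1L) {
  force(folds); force(trainer); force(seed)
  function(X, labels) {
    y <- .asBinary(labels)
    set.seed(seed)
    fold <- sample(rep_len(seq_len(folds), length(y)))
    correct <- 0L
    for (f in seq_len(folds)) {
      hold <- fold == f
      if (length(unique(y[!hold])) < 2L) next
      model <- trainer(X[!hold, , drop = FALSE],
                       ifelse(y[!hold], "positive", "negative"))
      pred <- predict(model, X[hold, , drop = FALSE], type = "class")
      correct <- correct + sum((pred == "positive") == y[hold])
    }
    correct / length(y)
  }
}

#' Incremental feature selection over an importance ranking
#'
#' Sorts features by score (descending), evaluates nested prefixes of the
#' ranking with a cross-validation accuracy evaluator, and selects the
#' prefix attaining the maximum (first maximum on ties). By default every
#' dimension up to 200 is evaluated and a stride of 10 is used beyond, to
#' keep the sweep affordable; pass \code{dims} for full resolution.
#'
#' @param x feature matrix or \linkS4class{MethylFeatureSet}; when the
#'   latter, the chosen set's per-block composition is reported.
#' @param labels binary labels (taken from \code{x} when omitted).
#' @param scores importance scores, as from [importanceScores()]; computed
#'   if missing.
#' @param evaluator accuracy function \code{(x, labels) -> accuracy}; the
#'   default is [cvAccuracyEvaluator()] (5-fold, Gaussian SVM). Use a
#'   target-jackknife wrapper for full protocol fidelity on small data.
#' @param dims dimensions to evaluate; default
#'   \code{c(1:min(200, p), seq(210, p, 10))} clipped to \code{p}.
#' @return a \linkS4class{SelectionResult}
#' @export
incrementalSelection <- function(x, labels = NULL, scores = NULL,
                                 evaluator = cvAccuracyEvaluator(),
                                 dims = NULL) {
  rf <- .resolveFeatures(x)
  X <- rf$X
  if (is.null(labels)) labels <- rf$labels
  if (is.null(scores)) scores <- importanceScores(X, labels)
  p <- ncol(X)
  stopifnot(length(scores) == p)
  ranking <- order(scores, decreasing = TRUE)
  if (is.null(dims)) {
    dims <- seq_len(min(200L, p))
    if (p > 200L) dims <- c(dims, seq(210L, p, by = 10L))
    if (dims[length(dims)] != p) dims <- c(dims, p)
  }
  dims <- sort(unique(as.integer(dims)))
  stopifnot(all(dims >= 1L), all(dims <= p))
  acc <- vapply(dims, function(d) {
    evaluator(X[, ranking[seq_len(d)], drop = FALSE], labels)
  }, numeric(1))
  best <- which.max(acc)
  chosenDim <- dims[best]
  chosen <- ranking[seq_len(chosenDim)]
  composition <- integer(0)
  if (is(x, "MethylFeatureSet")) {
    b <- blockLedger(x)
    blockOf <- rep(b$block, b$length)
    composition <- vapply(b$block, function(bn)
      sum(blockOf[chosen] == bn), integer(1))
  }
  new("SelectionResult", ranking = as.integer(ranking),
      scores = as.numeric(scores),
      curve = data.frame(dim = dims, accuracy = acc),
      chosenDim = as.integer(chosenDim), chosen = as.integer(chosen),
      composition = composition)
}

setMethod("show", "SelectionResult", function(object) {
  cat("SelectionResult:", length(object@scores), "features ranked;",
      "chosen dimension", object@chosenDim, "\n")
  cat("  best CV accuracy:", sprintf("%.4f", max(object@curve$accuracy)),
      "\n")
  if (length(object@composition))
    cat("  composition:",
        paste(names(object@composition), object@composition,
              sep = "=", collapse = " "), "\n")
})

#' Write a feature-selection report
#'
#' Tab-separated (rank, feature name, block, score) table plus the accuracy
#' curve.
#'
#' @param result a \linkS4class{SelectionResult}
#' @param fs the \linkS4class{MethylFeatureSet} the selection ran on (for
#'   names and blocks).
#' @param path ranking output file.
#' @param curvePath optional accuracy-curve output file.
#' @return invisibly, the ranking data.frame
#' @export
writeSelectionReport <- function(result, fs, path, curvePath = NULL) {
  b <- blockLedger(fs)
  blockOf <- rep(b$block, b$length)
  nm <- colnames(featureMatrix(fs))
  df <- data.frame(rank = seq_along(result@ranking),
                   feature = nm[result@ranking],
                   block = blockOf[result@ranking],
                   score = result@scores[result@ranking])
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(curvePath))
    utils::write.table(result@curve, curvePath, sep = "\t",
                       row.names = FALSE, quote = FALSE)
  invisible(df)
}
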