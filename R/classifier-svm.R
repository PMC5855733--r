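# Support-vector alternative with the same train/predict contract as the
# sparse Bayesian model. This stage deliberately delegates to e1071
# (libsvm): soft-margin Gaussian-kernel classification with Platt-scaled
# probability scores.

#' Train the support vector machine alternative
#'
#' Same interface and standardization behaviour as [trainSparseBayes()];
#' the two model types are interchangeable in every pipeline (jackknife,
#' holdout, feature selection).
#'
#' @inheritParams trainSparseBayes
#' @param cost soft-margin cost parameter C (default 1).
#' @param seed seed for the internal cross-validation used by the
#'   probability calibration.
#' @return a \linkS4class{MethylSVMModel}
#' @export
trainSVM <- function(x, labels = NULL, sigma = NULL, cost = 1,
                     standardize = TRUE, seed = 1L) {
  rf <- .resolveFeatures(x)
  X <- rf$X
  if (is.null(labels)) labels <- rf$labels
  if (is.null(labels)) stop("labels are required")
  if (!all(is.finite(X))) stop("features contain non-finite values")
  bl <- .binarizeLabels(labels)
  std <- if (standardize) .fitStandardizer(X) else
    list(center = rep(0, ncol(X)), scale = rep(1, ncol(X)))
  Xs <- .applyStandardizer(X, std)
  if (is.null(sigma)) sigma <- medianKernelWidth(Xs, seed = seed)
  yf <- factor(ifelse(bl$y == 1, bl$levels[2], bl$levels[1]),
               levels = bl$levels)
  set.seed(seed)
  fit <- e1071::svm(Xs, yf, kernel = "radial",
                    gamma = 1 / (2 * sigma^2), cost = cost,
                    probability = TRUE, scale = FALSE)
  new("MethylSVMModel", fit = fit, sigma = sigma,
      center = std$center, scale = std$scale, levels = bl$levels)
}

#' @rdname predict-methods
#' @export
setMethod("predict", "MethylSVMModel",
  function(object, newdata, type = c("response", "class", "both"),
           threshold = 0.5) {
    type <- match.arg(type)
    X <- .resolveFeatures(newdata)$X
    if (ncol(X) != length(object@center))
      stop("feature width mismatch: model expects ",
           length(object@center), " features but newdata has ", ncol(X))
    Xs <- .applyStandardizer(X, list(center = object@center,
                                     scale = object@scale))
    pr <- stats::predict(object@fit, Xs, probability = TRUE)
    score <- attr(pr, "probabilities")[, object@levels[2]]
    .predictReturn(as.numeric(score), object@levels, type, threshold)
  })

setMethod("show", "MethylSVMModel", function(object) {
  cat("MethylSVMModel:", object@fit$tot.nSV, "support vectors,",
      length(object@center), "features\n")
  cat("  kernel: Gaussian, sigma =", signif(object@sigma, 4), "\n")
})
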