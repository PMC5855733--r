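# Sparse Bayesian kernel classification (relevance vector machine with a
# logistic likelihood). The model is y = sigmoid(K w + b) over Gaussian
# kernel basis functions centred on the training rows, with an independent
# zero-mean Gaussian prior per weight. Each outer iteration (i) finds the
# posterior mode of the weights by a Newton/IRLS Laplace step given the
# current precisions and (ii) re-estimates each precision by evidence
# maximisation, alpha_i <- gamma_i / w_i^2 with
# gamma_i = 1 - alpha_i * Sigma_ii. Basis functions whose precision
# exceeds the pruning threshold are removed; what survives are the
# relevance vectors.

.sigmoid <- function(z) 1 / (1 + exp(-z))

# standardization: constant columns get scale 1 so they map to zero
.fitStandardizer <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2L, stats::sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  list(center = ctr, scale = scl)
}

.applyStandardizer <- function(X, std) {
  sweep(sweep(X, 2L, std$center, "-"), 2L, std$scale, "/")
}

# squared Euclidean cross-distances between rows of A and B
.sqDist <- function(A, B) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  d2
}

#' Median-heuristic Gaussian kernel width
#'
#' The median of the pairwise Euclidean distances between (standardized)
#' training rows; a standard data-driven default when no width is given.
#'
#' @param X numeric matrix (rows = samples).
#' @param maxRows subsample cap for the quadratic distance computation.
#' @param seed used only when subsampling.
#' @return positive scalar width
#' @export
medianKernelWidth <- function(X, maxRows = 1000L, seed = 1L) {
  if (nrow(X) > maxRows) {
    set.seed(seed)
    X <- X[sample.int(nrow(X), maxRows), , drop = FALSE]
  }
  d2 <- .sqDist(X, X)
  m <- sqrt(stats::median(d2[upper.tri(d2)]))
  if (!is.finite(m) || m <= 0) 1 else as.numeric(m)
}

.gaussKernel <- function(A, B, sigma) exp(-.sqDist(A, B) / (2 * sigma^2))

# labels -> list(y01, levels); accepts factor/character/logical/0-1
.binarizeLabels <- function(labels) {
  if (is.logical(labels)) labels <- ifelse(labels, "positive", "negative")
  if (is.numeric(labels)) {
    stopifnot(all(labels %in% c(0, 1)))
    labels <- ifelse(labels == 1, "positive", "negative")
  }
  labels <- as.character(labels)
  lev <- if (all(labels %in% c("negative", "positive")))
    c("negative", "positive") else sort(unique(labels))
  if (length(unique(labels)) < 2L)
    stop("training labels contain a single class")
  if (length(lev) != 2L) stop("exactly two classes are required")
  list(y = as.numeric(labels == lev[2]), levels = lev)
}

.resolveFeatures <- function(x) {
  if (is(x, "MethylFeatureSet"))
    list(X = featureMatrix(x), labels = sampleInfo(x)$label)
  else list(X = as.matrix(x), labels = NULL)
}

#' Train the sparse Bayesian kernel classifier
#'
#' @param x numeric feature matrix (rows = samples) or a
#'   \linkS4class{MethylFeatureSet} (whose labels are used when
#'   \code{labels} is missing).
#' @param labels binary labels; \code{"positive"}/\code{"negative"},
#'   logical, or 0/1.
#' @param sigma Gaussian kernel width on standardized features; default is
#'   the median pairwise-distance heuristic ([medianKernelWidth()]).
#' @param maxIter cap on hyperparameter re-estimation rounds (default
#'   5000); non-convergence at the cap is recorded on the model with a
#'   warning, and the model is still returned.
#' @param pruneThreshold precision above which a basis function is removed
#'   (default 1e9).
#' @param tol convergence tolerance on the maximum relative change of the
#'   log-precisions (default 1e-6).
#' @param standardize standardize features to training mean/variance before
#'   the kernel (default TRUE; the four feature blocks have very different
#'   natural scales).
#' @param seed optional seed (the fit itself is deterministic; the seed
#'   covers the subsampled width heuristic on large inputs).
#' @return a \linkS4class{SparseBayesModel}
#' @examples
#' set.seed(1)
#' X <- rbind(matrix(rnorm(60, 0), 30), matrix(rnorm(60, 3), 30))
#' y <- rep(c("negative", "positive"), each = 30)
#' fit <- trainSparseBayes(X, y)
#' nrow(fit@relevanceVectors) < 60
#' @export
trainSparseBayes <- function(x, labels = NULL, sigma = NULL,
                             maxIter = 5000L, pruneThreshold = 1e9,
                             tol = 1e-6, standardize = TRUE,
                             seed = NULL) {
  rf <- .resolveFeatures(x)
  X <- rf$X
  if (is.null(labels)) labels <- rf$labels
  if (is.null(labels)) stop("labels are required")
  if (!all(is.finite(X))) stop("features contain non-finite values")
  bl <- .binarizeLabels(labels)
  y <- bl$y
  n <- nrow(X)
  stopifnot(length(y) == n)

  std <- if (standardize) .fitStandardizer(X) else
    list(center = rep(0, ncol(X)), scale = rep(1, ncol(X)))
  Xs <- .applyStandardizer(X, std)
  if (is.null(sigma))
    sigma <- medianKernelWidth(Xs, seed = if (is.null(seed)) 1L else seed)

  K <- .gaussKernel(Xs, Xs, sigma)
  Phi <- cbind(bias = 1, K)           # n x (n+1); column 1 is the bias
  M <- ncol(Phi)
  active <- seq_len(M)                # indices into the full basis
  alpha <- rep(0.01, M)               # weakly informative initial precisions
  w <- rep(0, M)

  # penalized Bernoulli log-likelihood (numerically stable log1p form)
  pobj <- function(PhiA, aA, wv) {
    zz <- drop(PhiA %*% wv)
    sum(y * zz - (pmax(zz, 0) + log1p(exp(-abs(zz))))) -
      0.5 * sum(aA * wv^2)
  }

  converged <- FALSE
  it <- 0L
  damp <- 1           # log-space step size for the precision updates
  bestMove <- Inf
  stall <- 0L
  while (it < maxIter) {
    it <- it + 1L
    PhiA <- Phi[, active, drop = FALSE]
    aA <- alpha[active]
    wA <- w[active]

    # Laplace/Newton step(s): the first round finds the posterior mode
    # from scratch; later rounds only refresh it, interleaved with the
    # precision updates, so one Hessian per round is enough and also
    # supplies the Laplace covariance.
    nsteps <- if (it == 1L) 25L else 1L
    ch <- NULL
    for (s in seq_len(nsteps)) {
      z <- drop(PhiA %*% wA)
      p <- .sigmoid(z)
      g <- drop(crossprod(PhiA, y - p)) - aA * wA
      B <- pmax(p * (1 - p), 1e-10)
      H <- crossprod(PhiA * B, PhiA)
      diag(H) <- diag(H) + aA
      ch <- tryCatch(chol(H), error = function(e) NULL)
      if (is.null(ch)) {
        diag(H) <- diag(H) + 1e-8
        ch <- chol(H)
      }
      if (max(abs(g)) < 1e-6) break
      step <- backsolve(ch, forwardsolve(t(ch), g))
      f0 <- pobj(PhiA, aA, wA)
      lam <- 1
      repeat {
        wNew <- wA + lam * step
        if (pobj(PhiA, aA, wNew) >= f0 || lam < 1e-8) break
        lam <- lam / 2
      }
      wA <- wNew
    }

    # evidence-style precision re-estimation from the Laplace covariance
    SigDiag <- diag(chol2inv(ch))
    gamma <- pmin(pmax(1 - aA * SigDiag, 0), 1)
    aNew <- ifelse(wA^2 > 0, gamma / wA^2, Inf)
    aNew <- pmax(aNew, 1e-12)
    # the bias is never pruned; pin its precision at the cap instead of
    # letting it cycle between divergence and the floor
    aNew[1] <- min(aNew[1], pruneThreshold)
    # damped (log-space) update for surviving precisions once plain
    # re-estimation stops making progress; diverging precisions are left
    # at full speed so pruning is not delayed
    if (damp < 1) {
      fin <- is.finite(aNew) & aNew < pruneThreshold / 1e3
      aNew[fin] <- exp((1 - damp) * log(aA[fin]) + damp * log(aNew[fin]))
    }

    # prune on threshold crossing, plus basis functions that are
    # numerically dead (large precision, negligible weight): they cannot
    # re-enter and only prolong the expensive early rounds
    keep <- aNew < pruneThreshold & !(aNew > 1e4 & abs(wA) < 1e-4)
    keep[1] <- TRUE
    move <- max(abs(log(pmin(aNew[keep], pruneThreshold)) -
                    log(pmin(aA[keep], pruneThreshold))))
    w[active] <- wA
    alpha[active] <- aNew
    if (!all(keep)) {
      w[active[!keep]] <- 0
      active <- active[keep]
    }
    if (move < tol || damp < 1e-6) { converged <- TRUE; break }
    if (move < bestMove * 0.9) {
      bestMove <- move
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= 20L) { damp <- damp / 2; stall <- 0L }
    }
  }
  if (!converged)
    warning("sparse Bayes hyperparameters did not converge within ",
            maxIter, " iterations; returning the current model")

  rvCols <- active[active > 1L]        # kernel columns among survivors
  rvIdx <- rvCols - 1L                 # training-row indices
  new("SparseBayesModel",
      relevanceVectors = Xs[rvIdx, , drop = FALSE],
      weights = w[rvCols],
      bias = w[1],
      alpha = pmin(alpha[active], pruneThreshold),
      sigma = sigma,
      center = std$center, scale = std$scale,
      converged = converged, iterations = it,
      levels = bl$levels)
}

.sbmDecision <- function(object, X) {
  Xs <- .applyStandardizer(X, list(center = object@center,
                                   scale = object@scale))
  if (nrow(object@relevanceVectors) == 0L)
    return(rep(object@bias, nrow(X)))
  K <- .gaussKernel(Xs, object@relevanceVectors, object@sigma)
  drop(K %*% object@weights) + object@bias
}

#' Predict methylation scores and labels
#'
#' @param object a \linkS4class{SparseBayesModel}
#'   (or \linkS4class{MethylSVMModel}).
#' @param newdata feature matrix or \linkS4class{MethylFeatureSet} with the
#'   same feature width as the training data.
#' @param type \code{"response"} for posterior probabilities of the
#'   positive class, \code{"class"} for labels, \code{"both"} for a
#'   data.frame of score and label.
#' @param threshold score cut-off for the label (default 0.5).
#' @return numeric scores in [0, 1], a label factor, or a data.frame.
#' @rdname predict-methods
#' @export
setMethod("predict", "SparseBayesModel",
  function(object, newdata, type = c("response", "class", "both"),
           threshold = 0.5) {
    type <- match.arg(type)
    X <- .resolveFeatures(newdata)$X
    if (ncol(X) != length(object@center))
      stop("feature width mismatch: model expects ",
           length(object@center), " features but newdata has ", ncol(X))
    score <- .sigmoid(.sbmDecision(object, X))
    .predictReturn(score, object@levels, type, threshold)
  })

.predictReturn <- function(score, levels, type, threshold) {
  lab <- factor(ifelse(score >= threshold, levels[2], levels[1]),
                levels = levels)
  switch(type,
         response = score,
         class = lab,
         both = data.frame(score = score, label = lab))
}

setMethod("show", "SparseBayesModel", function(object) {
  cat("SparseBayesModel:", nrow(object@relevanceVectors),
      "relevance vectors,", length(object@center), "features\n")
  cat("  kernel: Gaussian, sigma =", signif(object@sigma, 4),
      " iterations:", object@iterations,
      if (object@converged) "(converged)" else "(iteration cap hit)", "\n")
})
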