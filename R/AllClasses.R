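#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

#' Labeled methylation window set
#'
#' Container for fixed-length DNA windows centred on a candidate cytosine,
#' together with their methylation label, sample origin (real measurement or
#' SMOTE-style synthetic) and optional genomic coordinates.
#'
#' @slot seqs a \link[Biostrings]{DNAStringSet} of equal-width windows.
#' @slot label factor with levels \code{"negative"}, \code{"positive"}.
#' @slot origin character, \code{"real"} or \code{"synthetic"} per record.
#' @slot chrom character chromosome name per record (\code{NA} if unknown).
#' @slot pos integer 1-based coordinate of the central cytosine (\code{NA} if
#'   unknown).
#'
#' @seealso [MethylWindowSet()] for construction, [extractWindows()],
#'   [simulateWindows()]
#' @exportClass MethylWindowSet
setClass("MethylWindowSet",
  representation(
    seqs   = "DNAStringSet",
    label  = "factor",
    origin = "character",
    chrom  = "character",
    pos    = "integer"
  )
)

setValidity("MethylWindowSet", function(object) {
  n <- length(object@seqs)
  msg <- character()
  if (length(object@label) != n)  msg <- c(msg, "label length must match seqs")
  if (length(object@origin) != n) msg <- c(msg, "origin length must match seqs")
  if (length(object@chrom) != n)  msg <- c(msg, "chrom length must match seqs")
  if (length(object@pos) != n)    msg <- c(msg, "pos length must match seqs")
  if (!identical(levels(object@label), c("negative", "positive")))
    msg <- c(msg, "label levels must be c('negative','positive')")
  if (n > 0 && length(unique(Biostrings::width(object@seqs))) > 1)
    msg <- c(msg, "all windows must have the same length")
  if (n > 0 && !all(object@origin %in% c("real", "synthetic")))
    msg <- c(msg, "origin values must be 'real' or 'synthetic'")
  if (n > 0 && anyDuplicated(names(object@seqs)))
    msg <- c(msg, "record identifiers must be unique")
  if (length(msg)) msg else TRUE
})

#' Encoded feature set
#'
#' A numeric sample-by-feature matrix produced by [encodeWindows()] (or
#' augmented by [smoteBalance()]), with the block ledger that maps feature
#' columns back to the four extractors, per-sample metadata, and the encoder
#' configuration used.
#'
#' @slot features numeric matrix, samples in rows, named feature columns.
#' @slot blocks data.frame with columns \code{block}, \code{start},
#'   \code{length} describing contiguous column ranges.
#' @slot sampleInfo a \link[S4Vectors]{DataFrame} with columns \code{label},
#'   \code{origin}, \code{chrom}, \code{pos}.
#' @slot config named list echoing encoder settings (wavelet, padding,
#'   lambdaMax, normalizeKgram).
#'
#' @exportClass MethylFeatureSet
setClass("MethylFeatureSet",
  representation(
    features   = "matrix",
    blocks     = "data.frame",
    sampleInfo = "DataFrame",
    config     = "list"
  )
)

setValidity("MethylFeatureSet", function(object) {
  msg <- character()
  if (nrow(object@sampleInfo) != nrow(object@features))
    msg <- c(msg, "sampleInfo rows must match feature rows")
  if (!all(c("label", "origin") %in% colnames(object@sampleInfo)))
    msg <- c(msg, "sampleInfo must carry label and origin columns")
  if (nrow(object@blocks) &&
      sum(object@blocks$length) != ncol(object@features))
    msg <- c(msg, "block ledger must tile the feature columns")
  if (length(msg)) msg else TRUE
})

#' Sparse Bayesian kernel classifier
#'
#' Fit of a relevance-vector-style probabilistic classifier: a logistic
#' linear model over Gaussian-kernel basis functions with independent
#' zero-mean Gaussian weight priors whose precisions are re-estimated by
#' evidence maximisation; basis functions whose precision diverges are
#' pruned, leaving a sparse set of relevance vectors.
#'
#' @slot relevanceVectors standardized feature rows retained as kernel
#'   centres (one row per relevance vector).
#' @slot weights numeric weights, one per relevance vector.
#' @slot bias numeric scalar intercept.
#' @slot alpha numeric precision hyperparameters for the retained weights
#'   (bias first).
#' @slot sigma Gaussian kernel width (on standardized features).
#' @slot center,scale per-feature standardization parameters fitted on the
#'   training data.
#' @slot converged logical, whether hyperparameters converged before the
#'   iteration cap.
#' @slot iterations number of hyperparameter update rounds performed.
#' @slot levels class labels, negative first.
#'
#' @exportClass SparseBayesModel
setClass("SparseBayesModel",
  representation(
    relevanceVectors = "matrix",
    weights    = "numeric",
    bias       = "numeric",
    alpha      = "numeric",
    sigma      = "numeric",
    center     = "numeric",
    scale      = "numeric",
    converged  = "logical",
    iterations = "integer",
    levels     = "character"
  )
)

setValidity("SparseBayesModel", function(object) {
  msg <- character()
  if (nrow(object@relevanceVectors) != length(object@weights))
    msg <- c(msg, "one weight per relevance vector required")
  if (length(object@alpha) &&
      (any(!is.finite(object@alpha)) || any(object@alpha <= 0)))
    msg <- c(msg, "retained precisions must be finite and positive")
  if (object@sigma <= 0) msg <- c(msg, "kernel width must be positive")
  if (length(msg)) msg else TRUE
})

#' Support vector machine with the sparse-Bayes predict contract
#'
#' Wraps an \pkg{e1071} Gaussian-kernel SVM behind the same standardize /
#' train / probabilistic-predict interface as [trainSparseBayes()], so the
#' two classifiers are interchangeable in every pipeline.
#'
#' @slot fit the underlying \code{e1071::svm} object.
#' @slot sigma Gaussian kernel width (on standardized features).
#' @slot center,scale standardization parameters from the training data.
#' @slot levels class labels, negative first.
#' @exportClass MethylSVMModel
setClass("MethylSVMModel",
  representation(
    fit    = "ANY",
    sigma  = "numeric",
    center = "numeric",
    scale  = "numeric",
    levels = "character"
  )
)

#' Evaluation report
#'
#' Confusion counts, the four summary statistics, and (when scores are
#' available) the full ROC curve with its trapezoidal AUC.
#'
#' @slot tp,tn,fp,fn confusion counts over evaluated (real) samples.
#' @slot acc,mcc,sn,sp accuracy, Matthews correlation, sensitivity,
#'   specificity.
#' @slot roc data.frame of (fpr, tpr) points from the full threshold sweep;
#'   zero rows when no scores were supplied.
#' @slot auc area under the ROC curve (NA without scores).
#' @exportClass EvalReport
setClass("EvalReport",
  representation(
    tp = "integer", tn = "integer", fp = "integer", fn = "integer",
    acc = "numeric", mcc = "numeric", sn = "numeric", sp = "numeric",
    roc = "data.frame", auc = "numeric"
  )
)

#' Incremental feature-selection result
#'
#' @slot ranking integer permutation of the feature columns, most important
#'   first.
#' @slot scores importance score per original feature column.
#' @slot curve data.frame with columns \code{dim} and \code{accuracy}.
#' @slot chosenDim dimension attaining the maximum of the accuracy curve.
#' @slot chosen integer indices (original column order) of the selected set.
#' @slot composition named integer vector: number of chosen features per
#'   extractor block (empty when the feature table carries no block ledger).
#' @exportClass SelectionResult
setClass("SelectionResult",
  representation(
    ranking     = "integer",
    scores      = "numeric",
    curve       = "data.frame",
    chosenDim   = "integer",
    chosen      = "integer",
    composition = "integer"
  )
)

setValidity("SelectionResult", function(object) {
  msg <- character()
  if (!identical(sort(object@ranking), seq_along(object@scores)))
    msg <- c(msg, "ranking must be a permutation of the feature indices")
  if (length(object@chosen) != object@chosenDim)
    msg <- c(msg, "chosen set size must equal chosenDim")
  if (length(msg)) msg else TRUE
})
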