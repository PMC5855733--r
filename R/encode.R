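# Assembly of the full 612-D feature vector and batch encoding.

.defaultConfig <- function(wavelet = "haar", levels = 4L, lambdaMax = 30L,
                           normalizeKgram = FALSE, pseudocount = 0) {
  list(wavelet = wavelet, levels = levels, lambdaMax = lambdaMax,
       normalizeKgram = normalizeKgram, pseudocount = pseudocount,
       padding = "symmetric")
}

#' Feature block ledger
#'
#' @param config encoder configuration (see [encodeWindow()]); determines
#'   block lengths for non-default levels/lags.
#' @return data.frame with columns \code{block}, \code{start}, \code{length}
#'   describing the contiguous column ranges of the four extractor blocks,
#'   in the fixed order kgram, mmi, dwt, pseaac (84 + 30 + 312 + 186 = 612
#'   at the defaults).
#' @export
featureBlocks <- function(config = .defaultConfig()) {
  len <- c(kgram = 84L, mmi = 30L,
           dwt = 6L * config$levels * 13L,
           pseaac = 6L * (config$lambdaMax + 1L))
  data.frame(block = names(len),
             start = c(1L, 1L + cumsum(len)[-4L], use.names = FALSE),
             length = as.integer(len), row.names = NULL)
}

#' Encode one window into the 612-D feature vector
#'
#' Concatenates the four extractor blocks in the fixed order
#' \code{[kgram | mmi | dwt | pseaac]}. Features are raw (no
#' standardization); the classifier standardizes on its training data.
#'
#' @param sequence DNA window over A/C/G/T; must satisfy every extractor's
#'   requirement (length >= \code{lambdaMax + 2}; 41-bp windows are the
#'   canonical case).
#' @param config named list as from the defaults: \code{wavelet},
#'   \code{levels}, \code{lambdaMax}, \code{normalizeKgram},
#'   \code{pseudocount}.
#' @param properties dinucleotide property lookup.
#' @return named numeric vector, length 612 at the default configuration,
#'   with attribute \code{"blocks"} holding [featureBlocks()].
#' @examples
#' v <- encodeWindow(paste(rep("ACGT", 10), collapse = "ACGTA"))
#' @export
encodeWindow <- function(sequence, config = .defaultConfig(),
                         properties = dinucleotideProperties()) {
  s <- .checkSeq(sequence, minLen = config$lambdaMax + 2L)
  pc <- pcMatrix(s, properties)
  kg <- kgramFeatures(s, normalize = config$normalizeKgram)
  mi <- mmiFeatures(s, pseudocount = config$pseudocount)
  # block prefixes keep the 612 feature identifiers unique (k-mer and
  # canonical-tuple labels would otherwise collide)
  names(kg) <- paste0("kgram.", names(kg))
  names(mi) <- paste0("mmi.", names(mi))
  v <- c(kg, mi,
         dwtFeatures(pc, levels = config$levels, wavelet = config$wavelet),
         pseaacFeatures(pc, lambdaMax = config$lambdaMax))
  attr(v, "blocks") <- featureBlocks(config)
  v
}

#' Encode a window set into a feature matrix
#'
#' Row-wise [encodeWindow()] over a \linkS4class{MethylWindowSet},
#' preserving record order and carrying the labels, origin flags and
#' coordinates into the result's sample metadata.
#'
#' @param windows a \linkS4class{MethylWindowSet}.
#' @param config,properties as in [encodeWindow()].
#' @param skipInvalid if TRUE, records that fail validation are dropped and
#'   listed (with reasons) in \code{metadata} of the returned object's
#'   \code{sampleInfo}; if FALSE (default) the first failure is an error
#'   annotated with the record identifier.
#' @return a \linkS4class{MethylFeatureSet}
#' @export
encodeWindows <- function(windows, config = .defaultConfig(),
                          properties = dinucleotideProperties(),
                          skipInvalid = FALSE) {
  stopifnot(is(windows, "MethylWindowSet"))
  n <- length(windows)
  if (n == 0L) stop("no windows to encode")
  seqs <- as.character(windowSeqs(windows))
  ids <- names(windowSeqs(windows))
  rows <- vector("list", n)
  skipped <- character(0); reasons <- character(0)
  for (i in seq_len(n)) {
    rows[[i]] <- tryCatch(
      encodeWindow(seqs[i], config, properties),
      error = function(e) {
        if (!skipInvalid)
          stop("record '", ids[i], "': ", conditionMessage(e),
               call. = FALSE)
        skipped <<- c(skipped, ids[i])
        reasons <<- c(reasons, conditionMessage(e))
        NULL
      })
  }
  keep <- !vapply(rows, is.null, logical(1))
  if (!any(keep)) stop("all records failed validation")
  mat <- do.call(rbind, rows[keep])
  rownames(mat) <- ids[keep]
  info <- S4Vectors::DataFrame(
    label = windowLabels(windows)[keep],
    origin = windowOrigin(windows)[keep],
    chrom = windows@chrom[keep],
    pos = windows@pos[keep],
    row.names = ids[keep])
  S4Vectors::metadata(info) <- list(
    skipped = data.frame(id = skipped, reason = reasons))
  new("MethylFeatureSet", features = mat, blocks = featureBlocks(config),
      sampleInfo = info, config = config)
}

#' Accessors for MethylFeatureSet
#'
#' @param x a \linkS4class{MethylFeatureSet}
#' @return `featureMatrix`: the numeric sample-by-feature matrix;
#'   `blockLedger`: the block data.frame; `sampleInfo`: the per-sample
#'   DataFrame (label, origin, chrom, pos); `encoderConfig`: the
#'   configuration list.
#' @name featureset-accessors
NULL

#' @rdname featureset-accessors
#' @export
featureMatrix <- function(x) x@features

#' @rdname featureset-accessors
#' @export
blockLedger <- function(x) x@blocks

#' @rdname featureset-accessors
#' @export
sampleInfo <- function(x) x@sampleInfo

#' @rdname featureset-accessors
#' @export
encoderConfig <- function(x) x@config

setMethod("show", "MethylFeatureSet", function(object) {
  cat("MethylFeatureSet:", nrow(object@features), "samples x",
      ncol(object@features), "features\n")
  b <- object@blocks
  cat("  blocks:", paste(sprintf("%s[%d]", b$block, b$length),
                         collapse = " "), "\n")
  lab <- object@sampleInfo$label
  cat("  positive:", sum(lab == "positive"),
      " negative:", sum(lab == "negative"),
      " (synthetic:", sum(object@sampleInfo$origin == "synthetic"), ")\n")
})

# subset rows of a feature set
.subsetFeatureSet <- function(fs, i) {
  new("MethylFeatureSet", features = fs@features[i, , drop = FALSE],
      blocks = fs@blocks, sampleInfo = fs@sampleInfo[i, ],
      config = fs@config)
}
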