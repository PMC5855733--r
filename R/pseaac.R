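# 186-D pseudo-composition autocovariance block: for each of the six
# physicochemical tracks, the lag-lambda autocovariance of the column about
# its mean, as a raw sum over positions (no 1/(L-lambda) normalization),
# for lambda = 0..30. Any remaining scale differences between blocks are
# absorbed by per-feature standardization inside the classifier.

#' Pseudo-composition autocovariance features
#'
#' For track i with values \eqn{PC_i(1..L)} and mean \eqn{\bar{PC_i}}:
#' \deqn{p_{i,\lambda} = \sum_{n=1}^{L-\lambda}
#'   (PC_i(n) - \bar{PC_i})(PC_i(n+\lambda) - \bar{PC_i})}
#' The lag-0 entry is \eqn{L} times the population variance of the track.
#' A 41-bp window (L = 40 track values) with \code{lambdaMax = 30} yields
#' the canonical 6 x 31 = 186 features; longer windows use the same formula
#' with the upper limit \eqn{L - \lambda}.
#'
#' @param pc property matrix from [pcMatrix()], \code{L} rows (requires
#'   \code{L > lambdaMax}).
#' @param lambdaMax largest lag (default 30).
#' @return named numeric vector of length \code{6 * (lambdaMax + 1)}, track
#'   index outer, lag inner (\code{pse.<prop>.lag<k>}).
#' @export
pseaacFeatures <- function(pc, lambdaMax = 30L) {
  stopifnot(is.matrix(pc), ncol(pc) == 6L)
  L <- nrow(pc)
  if (L <= lambdaMax)
    stop("PC matrix has only ", L, " rows but lambdaMax = ", lambdaMax,
         "; the window must be at least lambdaMax + 2 nucleotides long")
  props <- colnames(pc)
  if (is.null(props)) props <- PROPERTY_NAMES
  out <- numeric(6L * (lambdaMax + 1L))
  nm <- character(length(out))
  k <- 1L
  for (i in seq_len(6L)) {
    dev <- pc[, i] - mean(pc[, i])
    for (lam in 0:lambdaMax) {
      out[k] <- sum(dev[seq_len(L - lam)] * dev[seq_len(L - lam) + lam])
      nm[k] <- paste0("pse.", props[i], ".lag", lam)
      k <- k + 1L
    }
  }
  stats::setNames(out, nm)
}
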