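# 84-D k-gram block: overlapping occurrence counts of every 1-, 2- and
# 3-mer, each block in lexicographic order (A < C < G < T).

.kgramNames <- function() {
  k1 <- DNA_BASES
  k2 <- sort(as.vector(outer(DNA_BASES, DNA_BASES, paste0)))
  k3 <- sort(as.vector(outer(k2, DNA_BASES, paste0)))
  c(k1, k2, k3)
}

#' k-gram occurrence-count features
#'
#' Counts every overlapping 1-, 2- and 3-mer of the window (sliding window,
#' step 1), giving an 84-dimensional vector: 4 mononucleotide + 16
#' dinucleotide + 64 trinucleotide counts, each block lexicographic.
#'
#' @param sequence DNA string over A/C/G/T, length >= 3.
#' @param normalize if TRUE, divide each block by its window count
#'   (\code{l}, \code{l-1}, \code{l-2}) so entries are frequencies. Off by
#'   default: raw counts are kept, and with all windows of one dataset
#'   sharing a length the scaling is immaterial.
#' @return named numeric vector of length 84. The block sums are \code{l},
#'   \code{l-1} and \code{l-2} for a window of length \code{l} (or 1, 1, 1
#'   when normalized).
#' @examples
#' v <- kgramFeatures("ACGT")
#' v[c("A", "AC", "ACG")]
#' @export
kgramFeatures <- function(sequence, normalize = FALSE) {
  s <- .checkSeq(sequence, minLen = 3L)
  x <- Biostrings::DNAString(s)
  counts <- lapply(1:3, function(k)
    Biostrings::oligonucleotideFrequency(x, width = k))
  v <- as.numeric(unlist(counts))
  names(v) <- .kgramNames()
  if (normalize) {
    l <- nchar(s)
    v <- v / rep(c(l, l - 1L, l - 2L), times = c(4L, 16L, 64L))
  }
  v
}
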