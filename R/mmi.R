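# 30-D multivariate mutual information block over unordered nucleotide
# tuples. A contiguous 2- or 3-window contributes to the canonical (sorted)
# tuple of its content, collapsing orderings: 10 two-tuples and 20
# three-tuples exist. Natural logarithms throughout; any term with a zero
# numerator or zero denominator contributes 0, which keeps every feature
# finite without pseudocounts.

.canonical2 <- function() {
  out <- character(0)
  for (i in 1:4) for (j in i:4)
    out <- c(out, paste0(DNA_BASES[i], DNA_BASES[j]))
  out
}

.canonical3 <- function() {
  out <- character(0)
  for (i in 1:4) for (j in i:4) for (k in j:4)
    out <- c(out, paste0(DNA_BASES[i], DNA_BASES[j], DNA_BASES[k]))
  out
}

.canonicalize <- function(tuple) {
  paste(sort(.seqChars(toupper(tuple))), collapse = "")
}

#' Nucleotide and canonical tuple frequencies of a window
#'
#' @param sequence DNA string over A/C/G/T, length >= 3.
#' @param pseudocount nonnegative count added to every cell of each
#'   frequency table before normalization; 0 (the default) reproduces the
#'   plain empirical frequencies.
#' @return list with components \code{f1} (4 base frequencies), \code{f2}
#'   (10 canonical 2-tuple frequencies from adjacent overlapping 2-windows)
#'   and \code{f3} (20 canonical 3-tuple frequencies from 3-windows). Each
#'   component sums to 1.
#' @examples
#' tupleFrequencies("ACAC")$f2["AC"]   # all three 2-windows canonicalize to AC
#' @export
tupleFrequencies <- function(sequence, pseudocount = 0) {
  s <- .checkSeq(sequence, minLen = 3L)
  ch <- .seqChars(s)
  n <- length(ch)
  norm <- function(counts) (counts + pseudocount) /
    (sum(counts) + pseudocount * length(counts))

  f1 <- norm(table(factor(ch, levels = DNA_BASES)))

  t2 <- .canonical2()
  w2 <- vapply(seq_len(n - 1L), function(i)
    paste(sort(ch[i:(i + 1L)]), collapse = ""), character(1))
  f2 <- norm(table(factor(w2, levels = t2)))

  t3 <- .canonical3()
  w3 <- vapply(seq_len(n - 2L), function(i)
    paste(sort(ch[i:(i + 2L)]), collapse = ""), character(1))
  f3 <- norm(table(factor(w3, levels = t3)))

  list(f1 = stats::setNames(as.numeric(f1), DNA_BASES),
       f2 = stats::setNames(as.numeric(f2), t2),
       f3 = stats::setNames(as.numeric(f3), t3))
}

#' Pairwise mutual information of a canonical 2-tuple
#'
#' Evaluates \code{f(N1,N2) * ln[f(N1,N2) / (f(N1) f(N2))]}; the result is 0
#' whenever the joint frequency vanishes or factorizes exactly.
#'
#' @param tuple canonical 2-tuple, e.g. \code{"AC"} (sorted content).
#' @param freqs output of [tupleFrequencies()].
#' @return a real number
#' @export
mmiPair <- function(tuple, freqs) {
  tuple <- .assertCanonical(tuple, 2L)
  b <- .seqChars(tuple)
  .xlogxy(freqs$f2[[tuple]], freqs$f1[[b[1]]] * freqs$f1[[b[2]]])
}

#' Three-way mutual information of a canonical 3-tuple
#'
#' Evaluates, for sorted bases N1 <= N2 <= N3:
#' \deqn{I = f(N_1,N_2)\ln\frac{f(N_1,N_2)}{f(N_1)f(N_2)}
#'   + \frac{f(N_1,N_3)}{f(N_3)}\ln\frac{f(N_1,N_3)}{f(N_3)}
#'   - \frac{f(N_1,N_2,N_3)}{f(N_2,N_3)}\ln\frac{f(N_1,N_2,N_3)}{f(N_2,N_3)}}
#' with the convention that a term with zero numerator or zero denominator
#' contributes 0. Note the asymmetric second and third terms: this is the
#' formulation this feature set defines, not the textbook interaction
#' information.
#'
#' @param tuple canonical 3-tuple, e.g. \code{"ACG"} (sorted content).
#' @param freqs output of [tupleFrequencies()].
#' @return a real number
#' @export
mmiTriple <- function(tuple, freqs) {
  tuple <- .assertCanonical(tuple, 3L)
  b <- .seqChars(tuple)
  p12 <- freqs$f2[[.canonicalize(paste0(b[1], b[2]))]]
  p13 <- freqs$f2[[.canonicalize(paste0(b[1], b[3]))]]
  p23 <- freqs$f2[[.canonicalize(paste0(b[2], b[3]))]]
  p123 <- freqs$f3[[tuple]]
  term1 <- .xlogxy(p12, freqs$f1[[b[1]]] * freqs$f1[[b[2]]])
  term2 <- if (freqs$f1[[b[3]]] > 0) .xlogxy(p13 / freqs$f1[[b[3]]], 1) else 0
  term3 <- if (p23 > 0) .xlogxy(p123 / p23, 1) else 0
  term1 + term2 - term3
}

.assertCanonical <- function(tuple, k) {
  if (!is.character(tuple) || length(tuple) != 1L || nchar(tuple) != k)
    stop("tuple must be a single ", k, "-character string")
  canon <- .canonicalize(tuple)
  if (!identical(canon, toupper(tuple)))
    stop("tuple '", tuple, "' is not canonical; its sorted form is '",
         canon, "'")
  canon
}

#' Multivariate mutual information features
#'
#' The 30-dimensional MMI block: [mmiPair()] over the 10 canonical 2-tuples
#' followed by [mmiTriple()] over the 20 canonical 3-tuples.
#'
#' @inheritParams tupleFrequencies
#' @return named numeric vector of length 30
#' @examples
#' length(mmiFeatures(paste(rep("ACGT", 11), collapse = "")))
#' @export
mmiFeatures <- function(sequence, pseudocount = 0) {
  freqs <- tupleFrequencies(sequence, pseudocount = pseudocount)
  t2 <- .canonical2(); t3 <- .canonical3()
  v2 <- vapply(t2, mmiPair, numeric(1), freqs = freqs)
  v3 <- vapply(t3, mmiTriple, numeric(1), freqs = freqs)
  stats::setNames(c(v2, v3), c(t2, t3))
}
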