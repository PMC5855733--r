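# Internal sequence validation helpers shared by all extractors.

DNA_BASES <- c("A", "C", "G", "T")

# Returns the sequence as an uppercase character scalar, or stops with a
# length/alphabet error. `minLen` is the extractor's hard requirement.
.checkSeq <- function(sequence, minLen = 2L, what = "sequence") {
  if (methods::is(sequence, "DNAString") ||
      methods::is(sequence, "DNAStringSet"))
    sequence <- as.character(sequence)
  if (!is.character(sequence) || length(sequence) != 1L)
    stop(what, " must be a single DNA string", call. = FALSE)
  s <- toupper(sequence)
  if (nchar(s) < minLen)
    stop(what, " has length ", nchar(s), " but at least ", minLen,
         " nucleotides are required", call. = FALSE)
  bad <- regexpr("[^ACGT]", s)
  if (bad > 0L)
    stop(what, " contains disallowed character '",
         substr(s, bad, bad), "' at position ", bad,
         " (alphabet is A/C/G/T; ambiguity codes are rejected)",
         call. = FALSE)
  s
}

.seqChars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

.revcomp <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(.seqChars(s)), collapse = ""))
}

# population standard deviation (divide by n)
.popSd <- function(x) sqrt(mean((x - mean(x))^2))

# x * log(x / y) with the 0 * log(.) = 0 and zero-denominator conventions
.xlogxy <- function(x, y) {
  if (x <= 0 || y <= 0) return(0)
  x * log(x / y)
}
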