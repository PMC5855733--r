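# Independent reference implementations used as oracles. These are written
# in a deliberately different style from the package code (explicit loops,
# direct transcription of the defining formulas) so that agreement is
# informative.

randomSeq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = "")

# --- k-gram: count occurrences of each k-mer by direct substring scan ----
bruteKmerCounts <- function(s, kmers) {
  vapply(kmers, function(km) {
    k <- nchar(km)
    hits <- 0L
    for (i in seq_len(nchar(s) - k + 1L))
      if (substr(s, i, i + k - 1L) == km) hits <- hits + 1L
    hits
  }, integer(1))
}

# --- MMI: direct transcription of the tuple-information formulas ---------
bruteTupleFreqs <- function(s) {
  ch <- strsplit(s, "")[[1]]
  n <- length(ch)
  f1 <- sapply(c("A", "C", "G", "T"), function(b) sum(ch == b) / n)
  sortedWindow <- function(i, k)
    paste(sort(ch[i:(i + k - 1L)]), collapse = "")
  w2 <- sapply(1:(n - 1), sortedWindow, k = 2)
  w3 <- sapply(1:(n - 2), sortedWindow, k = 3)
  list(f1 = f1,
       f2 = function(t) sum(w2 == paste(sort(strsplit(t, "")[[1]]),
                                        collapse = "")) / (n - 1),
       f3 = function(t) sum(w3 == paste(sort(strsplit(t, "")[[1]]),
                                        collapse = "")) / (n - 2))
}

bruteMmi2 <- function(t, fr) {
  b <- strsplit(t, "")[[1]]
  joint <- fr$f2(t)
  indep <- fr$f1[[b[1]]] * fr$f1[[b[2]]]
  if (joint == 0 || indep == 0) return(0)
  joint * log(joint / indep)
}

bruteMmi3 <- function(t, fr) {
  b <- strsplit(t, "")[[1]]
  term <- function(num, den) {
    if (num == 0 || den == 0) return(0)
    r <- num / den
    if (r == 0) 0 else r * log(r)
  }
  t1 <- bruteMmi2(paste0(b[1], b[2]), fr)
  t2 <- term(fr$f2(paste0(b[1], b[3])), fr$f1[[b[3]]])
  t3 <- term(fr$f3(t), fr$f2(paste0(b[2], b[3])))
  t1 + t2 - t3
}

bruteMmiVector <- function(s) {
  fr <- bruteTupleFreqs(s)
  bases <- c("A", "C", "G", "T")
  t2 <- c(); t3 <- c()
  for (i in 1:4) for (j in i:4) t2 <- c(t2, paste0(bases[i], bases[j]))
  for (i in 1:4) for (j in i:4) for (k in j:4)
    t3 <- c(t3, paste0(bases[i], bases[j], bases[k]))
  c(sapply(t2, bruteMmi2, fr = fr), sapply(t3, bruteMmi3, fr = fr))
}

# --- DWT: independent Haar cascade by explicit pairing -------------------
haarPairStep <- function(x) {
  if (length(x) %% 2 == 1) x <- c(x, x[length(x)])  # repeat-last padding
  odd <- x[seq(1, length(x), by = 2)]
  even <- x[seq(2, length(x), by = 2)]
  list(approx = (odd + even) / sqrt(2), detail = (odd - even) / sqrt(2))
}

bruteHaarFeatures <- function(signal, levels = 4) {
  popSd <- function(v) sqrt(mean((v - mean(v))^2))
  out <- NULL
  a <- signal
  for (t in seq_len(levels)) {
    st <- haarPairStep(a)
    head5 <- c(st$approx, 0, 0, 0, 0, 0)[1:5]
    out <- rbind(out, c(max(st$detail), min(st$detail), mean(st$detail),
                        popSd(st$detail),
                        max(st$approx), min(st$approx), mean(st$approx),
                        popSd(st$approx), head5))
    a <- st$approx
  }
  out
}

# --- PseAAC: naive double loop -------------------------------------------
brutePseaac <- function(pc, lambdaMax = 30) {
  out <- c()
  for (i in 1:6) {
    col <- pc[, i]
    L <- length(col)
    mu <- mean(col)
    for (lam in 0:lambdaMax) {
      acc <- 0
      for (n in seq_len(L - lam)) acc <- acc + (col[n] - mu) * (col[n + lam] - mu)
      out <- c(out, as.numeric(acc))
    }
  }
  out
}

# --- AUC: concordant-pair count ------------------------------------------
bruteAuc <- function(labels, scores) {
  pos <- scores[labels == 1 | labels == "positive"]
  neg <- scores[labels == 0 | labels == "negative"]
  tot <- 0
  for (p in pos) for (n in neg)
    tot <- tot + if (p > n) 1 else if (p == n) 0.5 else 0
  tot / (length(pos) * length(neg))
}
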