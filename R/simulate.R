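# Synthetic fixture generation. Two window classes differing both
# compositionally (a degenerate consensus motif planted near the centre of
# positives, plus a G+C enrichment) and physicochemically (the G+C shift
# moves every dinucleotide property track), so all four feature blocks
# carry signal. All windows are centred on C, as real candidate-site
# windows are.

.classProbs <- function(background, gcShift) {
  p <- background
  p["G"] <- p["G"] + gcShift / 2; p["C"] <- p["C"] + gcShift / 2
  p["A"] <- p["A"] - gcShift / 2; p["T"] <- p["T"] - gcShift / 2
  if (any(p < 0)) stop("gcShift incompatible with background composition")
  p / sum(p)
}

.sampleWindow <- function(len, probs, center, motif = NULL,
                          motifMatchProb = 0, motifStart = NA) {
  ch <- sample(DNA_BASES, len, replace = TRUE, prob = probs)
  if (!is.null(motif) && motifMatchProb > 0) {
    mb <- .seqChars(motif)
    pos <- motifStart + seq_along(mb) - 1L
    hit <- stats::runif(length(mb)) < motifMatchProb
    ch[pos[hit]] <- mb[hit]
  }
  ch[center] <- "C"
  paste(ch, collapse = "")
}

#' Simulate labeled methylation windows
#'
#' Generates a two-class window set: positives carry a partially degenerate
#' consensus motif just downstream of the central C and a G+C-enriched
#' background; negatives are background only. Deterministic given
#' \code{seed}.
#'
#' @param nPos,nNeg class sizes (default 200 each).
#' @param windowLength odd window length (default 41).
#' @param motif consensus planted in positives (default \code{"ACGCGT"});
#'   \code{NULL} for none.
#' @param motifMatchProb per-position probability that the motif base
#'   overwrites the background base (default 0.9; 0 disables the motif).
#' @param background base probabilities in A, C, G, T order (default
#'   uniform).
#' @param gcShift increase in G+C fraction of the positive class relative
#'   to \code{background} (default 0.1; 0 for the null configuration).
#' @param seed integer seed.
#' @return a \linkS4class{MethylWindowSet} (all origin "real", no
#'   coordinates)
#' @examples
#' mws <- simulateWindows(nPos = 5, nNeg = 5, seed = 7)
#' table(windowLabels(mws))
#' @export
simulateWindows <- function(nPos = 200L, nNeg = 200L, windowLength = 41L,
                            motif = "ACGCGT", motifMatchProb = 0.9,
                            background = c(A = 0.25, C = 0.25,
                                           G = 0.25, T = 0.25),
                            gcShift = 0.1, seed = 1L) {
  stopifnot(windowLength %% 2L == 1L, nPos >= 1L, nNeg >= 1L)
  background <- background[DNA_BASES]
  if (abs(sum(background) - 1) > 1e-8)
    stop("background probabilities must sum to 1")
  center <- (windowLength + 1L) %/% 2L
  if (!is.null(motif)) {
    motifStart <- center + 1L
    if (motifStart + nchar(motif) - 1L > windowLength)
      stop("motif does not fit in the window downstream of the centre")
  } else motifStart <- NA_integer_
  set.seed(seed)
  posProbs <- .classProbs(background, gcShift)
  pos <- vapply(seq_len(nPos), function(i)
    .sampleWindow(windowLength, posProbs, center, motif, motifMatchProb,
                  motifStart), character(1))
  neg <- vapply(seq_len(nNeg), function(i)
    .sampleWindow(windowLength, background, center), character(1))
  MethylWindowSet(
    seqs = c(pos, neg),
    label = rep(c("positive", "negative"), c(nPos, nNeg)),
    origin = "real",
    id = c(sprintf("pos%d", seq_len(nPos)), sprintf("neg%d", seq_len(nNeg))))
}

#' Simulate a toy genome with a CpG site table
#'
#' Builds a small multi-chromosome genome and a read-count site table that
#' round-trips through [labelSites()] and [extractWindows()]: each site's
#' position holds a C (followed by G), read depths are Poisson, and the
#' methylated-read fraction follows the site's latent state. Sites landing
#' on chromosomes 1/3/5/... vs 2/4/6/... make the chromosome-parity holdout
#' exercisable. Windows around methylated sites receive the same motif and
#' G+C enrichment as [simulateWindows()] positives.
#'
#' @param nChrom number of chromosomes (default 12, named chr1..chrN).
#' @param chromLength length of each chromosome (default 2000).
#' @param sitesPerChrom candidate CpG sites per chromosome (default 20).
#' @param meanDepth mean read depth (default 10).
#' @param flank intended window flank; sites are placed at least
#'   \code{flank + 1} from the chromosome ends (default 20).
#' @param motif,motifMatchProb,gcShift class signal, as in
#'   [simulateWindows()]; applied around methylated sites.
#' @param seed integer seed.
#' @return list with \code{genome} (named DNAStringSet) and \code{sites}
#'   (data.frame: chrom, pos, methylated_reads, total_reads)
#' @export
simulateMethylome <- function(nChrom = 12L, chromLength = 2000L,
                              sitesPerChrom = 20L, meanDepth = 10L,
                              flank = 20L, motif = "ACGCGT",
                              motifMatchProb = 0.9, gcShift = 0.1,
                              seed = 1L) {
  set.seed(seed)
  posProbs <- .classProbs(c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                          gcShift)
  genome <- vector("character", nChrom)
  sites <- vector("list", nChrom)
  for (cix in seq_len(nChrom)) {
    ch <- sample(DNA_BASES, chromLength, replace = TRUE)
    lo <- flank + 1L; hi <- chromLength - flank - 1L
    posns <- sort(sample(seq(lo, hi, by = 2L * flank + 2L),
                         min(sitesPerChrom,
                             length(seq(lo, hi, by = 2L * flank + 2L)))))
    methylated <- stats::runif(length(posns)) < 0.5
    for (s in seq_along(posns)) {
      p <- posns[s]
      if (methylated[s]) {
        span <- max(1L, p - flank):min(chromLength, p + flank)
        ch[span] <- sample(DNA_BASES, length(span), replace = TRUE,
                           prob = posProbs)
        if (!is.null(motif)) {
          mb <- .seqChars(motif)
          mpos <- p + seq_along(mb)
          hit <- stats::runif(length(mb)) < motifMatchProb
          ch[mpos[hit]] <- mb[hit]
        }
      }
      ch[p] <- "C"
      if (p < chromLength) ch[p + 1L] <- "G"
    }
    depth <- stats::rpois(length(posns), meanDepth) + 1L
    mfrac <- ifelse(methylated, 0.9, 0.1)
    mreads <- stats::rbinom(length(posns), depth, mfrac)
    genome[cix] <- paste(ch, collapse = "")
    sites[[cix]] <- data.frame(chrom = paste0("chr", cix), pos = posns,
                               methylated_reads = mreads,
                               total_reads = depth)
  }
  gset <- Biostrings::DNAStringSet(genome)
  names(gset) <- paste0("chr", seq_len(nChrom))
  list(genome = gset, sites = do.call(rbind, sites))
}
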