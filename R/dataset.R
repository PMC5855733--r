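# Dataset assembly: windows from a genome plus site table, read-count
# labeling, exact de-duplication with cross-class conflict removal, and
# SMOTE class balancing in feature space.

#' Label CpG sites from read counts
#'
#' Applies the read-count rules: sites with fewer than \code{minReads}
#' mapped reads are discarded; a kept site is methylated iff more of its
#' reads are tagged methylated than unmethylated. Exact ties are discarded
#' as ambiguous (neither majority holds) and reported.
#'
#' @param sites data.frame with columns \code{chrom}, \code{pos},
#'   \code{methylated_reads}, \code{total_reads}.
#' @param minReads minimum read depth to keep a site (default 4).
#' @return the kept rows with an added factor column \code{label}
#'   (\code{"positive"} = methylated); attributes \code{"nLowCoverage"} and
#'   \code{"nTies"} count the discarded sites of each kind.
#' @export
labelSites <- function(sites, minReads = 4L) {
  need <- c("chrom", "pos", "methylated_reads", "total_reads")
  if (!all(need %in% colnames(sites)))
    stop("site table must have columns: ", paste(need, collapse = ", "))
  if (any(sites$methylated_reads > sites$total_reads) ||
      any(sites$methylated_reads < 0))
    stop("need 0 <= methylated_reads <= total_reads")
  lowCov <- sites$total_reads < minReads
  kept <- sites[!lowCov, , drop = FALSE]
  unmeth <- kept$total_reads - kept$methylated_reads
  tie <- kept$methylated_reads == unmeth
  out <- kept[!tie, , drop = FALSE]
  out$label <- factor(ifelse(out$methylated_reads > unmeth[!tie],
                             "positive", "negative"),
                      levels = c("negative", "positive"))
  attr(out, "nLowCoverage") <- sum(lowCov)
  attr(out, "nTies") <- sum(tie)
  out
}

#' Extract labeled windows around sites from a genome
#'
#' Cuts a window of \code{2 * flank + 1} bases centred on each site from
#' the reference, so the candidate cytosine sits exactly in the middle.
#' Sites whose window would run off the chromosome, whose chromosome is
#' missing from the genome, or (by default) whose central base is not C are
#' skipped and reported.
#'
#' @param genome a named \link[Biostrings]{DNAStringSet} of chromosomes, or
#'   a path to a FASTA file.
#' @param sites labeled site table as returned by [labelSites()] (columns
#'   \code{chrom}, \code{pos}, \code{label}).
#' @param flank bases on each side of the site; 20 gives the benchmark-style
#'   41-bp window, 100 the 201-bp single-cell-style window.
#' @param requireCenterC skip windows whose central base is not C
#'   (default TRUE).
#' @return a \linkS4class{MethylWindowSet} with coordinates; the attribute
#'   \code{"skipped"} is a data.frame of skipped sites and reasons.
#' @export
extractWindows <- function(genome, sites, flank = 20L,
                           requireCenterC = TRUE) {
  if (is.character(genome) && length(genome) == 1L)
    genome <- Biostrings::readDNAStringSet(genome)
  stopifnot(is(genome, "DNAStringSet"), flank >= 1L)
  if (!"label" %in% colnames(sites))
    stop("sites must carry a 'label' column; run labelSites() first")
  n <- nrow(sites)
  seqs <- character(n); keep <- logical(n)
  skipId <- character(0); skipReason <- character(0)
  chromLens <- stats::setNames(Biostrings::width(genome), names(genome))
  for (i in seq_len(n)) {
    chrom <- as.character(sites$chrom[i]); p <- sites$pos[i]
    id <- sprintf("%s:%d", chrom, p)
    if (!chrom %in% names(genome)) {
      skipId <- c(skipId, id)
      skipReason <- c(skipReason, "chromosome not in genome"); next
    }
    if (p - flank < 1L || p + flank > chromLens[[chrom]]) {
      skipId <- c(skipId, id)
      skipReason <- c(skipReason, "window out of chromosome bounds"); next
    }
    w <- as.character(Biostrings::subseq(genome[[chrom]],
                                         p - flank, p + flank))
    if (requireCenterC && substr(w, flank + 1L, flank + 1L) != "C") {
      skipId <- c(skipId, id)
      skipReason <- c(skipReason, "central base is not C"); next
    }
    seqs[i] <- w; keep[i] <- TRUE
  }
  if (!any(keep)) stop("no extractable windows")
  out <- MethylWindowSet(
    seqs = seqs[keep],
    label = sites$label[keep],
    origin = "real",
    chrom = as.character(sites$chrom[keep]),
    pos = as.integer(sites$pos[keep]),
    id = sprintf("%s:%d", sites$chrom[keep], sites$pos[keep]))
  attr(out, "skipped") <- data.frame(id = skipId, reason = skipReason)
  out
}

#' Exact de-duplication and cross-class conflict removal
#'
#' Within each class, identical sequences are collapsed to their first
#' occurrence. A sequence occurring in both classes is contradictory
#' evidence and is removed from both. (Similarity-based redundancy
#' reduction, e.g. CD-HIT clustering, is out of scope; pass
#' \code{keepIds} with an externally produced representative list to apply
#' one.)
#'
#' @param positive,negative \linkS4class{MethylWindowSet}s of the two
#'   classes (same window width).
#' @param keepIds optional character vector of record identifiers to retain
#'   (applied before duplicate/conflict removal).
#' @return list with elements \code{positive}, \code{negative} and
#'   \code{report} (counts of within-set duplicates removed per class and
#'   cross-set conflict sequences removed).
#' @export
deduplicateWindows <- function(positive, negative, keepIds = NULL) {
  stopifnot(is(positive, "MethylWindowSet"), is(negative, "MethylWindowSet"))
  if (!is.null(keepIds)) {
    positive <- positive[names(windowSeqs(positive)) %in% keepIds]
    negative <- negative[names(windowSeqs(negative)) %in% keepIds]
  }
  posSeq <- as.character(windowSeqs(positive))
  negSeq <- as.character(windowSeqs(negative))
  dupPos <- duplicated(posSeq)
  dupNeg <- duplicated(negSeq)
  posU <- positive[!dupPos]; negU <- negative[!dupNeg]
  posSeqU <- posSeq[!dupPos]; negSeqU <- negSeq[!dupNeg]
  conflict <- intersect(posSeqU, negSeqU)
  list(
    positive = posU[!posSeqU %in% conflict],
    negative = negU[!negSeqU %in% conflict],
    report = c(duplicates_positive = sum(dupPos),
               duplicates_negative = sum(dupNeg),
               conflicts = length(conflict)))
}

#' SMOTE class balancing in feature space
#'
#' Augments the minority class with synthetic rows until the class counts
#' are equal. Each synthetic row is \code{x + u * (x_nn - x)} for a real
#' minority row \code{x}, one of its \code{k} nearest minority neighbours
#' \code{x_nn} (Euclidean distance), and \code{u} uniform on [0, 1].
#' Interpolation happens in feature space, not sequence space, so synthetic
#' rows carry no sequence or coordinates; they are flagged
#' \code{origin = "synthetic"} and are excluded from testing by
#' [targetJackknife()].
#'
#' @param fs a \linkS4class{MethylFeatureSet} with real samples.
#' @param k number of nearest neighbours (default 5); the minority class
#'   must have more than \code{k} members.
#' @param seed integer seed for reproducible interpolation.
#' @return a \linkS4class{MethylFeatureSet} with the original rows unchanged
#'   followed by the synthetic rows; equal class counts.
#' @export
smoteBalance <- function(fs, k = 5L, seed = NULL) {
  stopifnot(is(fs, "MethylFeatureSet"))
  lab <- sampleInfo(fs)$label
  nPos <- sum(lab == "positive"); nNeg <- sum(lab == "negative")
  if (nPos == nNeg) return(fs)
  minority <- if (nPos < nNeg) "positive" else "negative"
  need <- abs(nPos - nNeg)
  idx <- which(lab == minority)
  if (length(idx) <= k)
    stop("minority class has ", length(idx),
         " members; SMOTE needs more than k = ", k)
  if (!is.null(seed)) set.seed(seed)
  X <- featureMatrix(fs)[idx, , drop = FALSE]
  d <- as.matrix(stats::dist(X))
  diag(d) <- Inf
  nn <- t(apply(d, 1L, function(r) order(r)[seq_len(k)]))
  base <- rep(seq_along(idx), length.out = need)
  pick <- nn[cbind(base, sample.int(k, need, replace = TRUE))]
  u <- stats::runif(need)
  synth <- X[base, , drop = FALSE] +
    u * (X[pick, , drop = FALSE] - X[base, , drop = FALSE])
  rownames(synth) <- paste0("smote", seq_len(need))
  info <- S4Vectors::DataFrame(
    label = factor(rep(minority, need), levels = c("negative", "positive")),
    origin = rep("synthetic", need),
    chrom = NA_character_, pos = NA_integer_,
    row.names = rownames(synth))
  newInfo <- rbind(sampleInfo(fs), info)
  S4Vectors::metadata(newInfo) <- c(S4Vectors::metadata(sampleInfo(fs)),
                                    list(smote = c(added = need, k = k)))
  new("MethylFeatureSet",
      features = rbind(featureMatrix(fs), synth),
      blocks = blockLedger(fs), sampleInfo = newInfo,
      config = encoderConfig(fs))
}
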