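#' Construct a MethylWindowSet
#'
#' @param seqs a \link[Biostrings]{DNAStringSet}, or a character vector of
#'   equal-length DNA windows.
#' @param label methylation state per window: factor/character with values
#'   \code{"positive"} (methylated) / \code{"negative"}, or a logical vector
#'   (TRUE = methylated).
#' @param origin \code{"real"} or \code{"synthetic"} per window (recycled).
#' @param chrom,pos optional genomic coordinates of the central cytosine.
#' @param id record identifiers; defaults to existing names or \code{w1..wn}.
#' @return a \linkS4class{MethylWindowSet}
#' @examples
#' mws <- MethylWindowSet(c(a = "ACGTC", b = "TTCGG"),
#'                        label = c("positive", "negative"))
#' windowLabels(mws)
#' @export
MethylWindowSet <- function(seqs, label, origin = "real",
                            chrom = NA_character_, pos = NA_integer_,
                            id = NULL) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  n <- length(seqs)
  if (is.logical(label)) label <- ifelse(label, "positive", "negative")
  label <- factor(rep_len(as.character(label), n),
                  levels = c("negative", "positive"))
  if (anyNA(label)) stop("labels must be 'positive' or 'negative'")
  if (is.null(id)) id <- names(seqs)
  if (is.null(id)) id <- paste0("w", seq_len(n))
  names(seqs) <- id
  new("MethylWindowSet", seqs = seqs,
      label  = label,
      origin = rep_len(as.character(origin), n),
      chrom  = rep_len(as.character(chrom), n),
      pos    = rep_len(as.integer(pos), n))
}

#' @describeIn MethylWindowSet number of windows
#' @param x,object a MethylWindowSet
#' @export
setMethod("length", "MethylWindowSet", function(x) length(x@seqs))

#' Accessors for MethylWindowSet
#'
#' @param x a \linkS4class{MethylWindowSet}
#' @return `windowSeqs`: the DNAStringSet; `windowLabels`: the label factor;
#'   `windowOrigin`: character vector; `windowCoords`: data.frame with
#'   columns `chrom` and `pos`.
#' @name window-accessors
NULL

#' @rdname window-accessors
#' @export
windowSeqs <- function(x) x@seqs

#' @rdname window-accessors
#' @export
windowLabels <- function(x) x@label

#' @rdname window-accessors
#' @export
windowOrigin <- function(x) x@origin

#' @rdname window-accessors
#' @export
windowCoords <- function(x) data.frame(chrom = x@chrom, pos = x@pos,
                                       row.names = names(x@seqs))

#' @describeIn MethylWindowSet subset windows
#' @param i index vector
#' @export
setMethod("[", "MethylWindowSet", function(x, i) {
  new("MethylWindowSet", seqs = x@seqs[i], label = x@label[i],
      origin = x@origin[i], chrom = x@chrom[i], pos = x@pos[i])
})

setMethod("show", "MethylWindowSet", function(object) {
  n <- length(object)
  w <- if (n) Biostrings::width(object@seqs)[1] else NA_integer_
  cat("MethylWindowSet with", n, "windows of width", w, "\n")
  cat("  positive:", sum(object@label == "positive"),
      " negative:", sum(object@label == "negative"), "\n")
  cat("  origin:  real:", sum(object@origin == "real"),
      " synthetic:", sum(object@origin == "synthetic"), "\n")
  if (any(!is.na(object@chrom)))
    cat("  coordinates present for", sum(!is.na(object@chrom)),
        "windows\n")
})

# concatenate two window sets (same width enforced by validity)
.bindWindows <- function(a, b) {
  new("MethylWindowSet",
      seqs   = c(a@seqs, b@seqs),
      label  = factor(c(as.character(a@label), as.character(b@label)),
                      levels = c("negative", "positive")),
      origin = c(a@origin, b@origin),
      chrom  = c(a@chrom, b@chrom),
      pos    = c(a@pos, b@pos))
}
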