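# Dinucleotide physicochemical constants and the per-sequence property
# matrix. The six structural parameters (Twist, Tilt, Roll, Shift, Slide,
# Rise) describe the local helical geometry of each dinucleotide step; they
# are reverse-complement symmetric, so e.g. AC and GT share one row.

PROPERTY_NAMES <- c("Twist", "Tilt", "Roll", "Shift", "Slide", "Rise")

.pkgEnv <- new.env(parent = emptyenv())

#' Dinucleotide physicochemical property table
#'
#' Loads the 16 x 6 lookup of structural parameters (Twist, Tilt, Roll,
#' Shift, Slide, Rise) for every ordered dinucleotide. The table ships with
#' the package as a plain-text file and can be overridden with an
#' alternative property set of the same shape.
#'
#' @param file optional path to a tab-separated replacement table with a
#'   \code{dinucleotide} column followed by the six property columns.
#' @return numeric matrix with the 16 dinucleotides as rownames and the six
#'   properties as colnames.
#' @examples
#' pt <- dinucleotideProperties()
#' pt["AA", ]
#' stopifnot(identical(pt["AC", ], pt["GT", ]))   # reverse-complement pairs
#' @export
dinucleotideProperties <- function(file = NULL) {
  if (is.null(file)) {
    cached <- .pkgEnv$propertyTable
    if (!is.null(cached)) return(cached)
    file <- system.file("extdata", "dinucleotide_properties.tsv",
                        package = "methylWave", mustWork = TRUE)
    tab <- .readPropertyTable(file)
    .pkgEnv$propertyTable <- tab
    return(tab)
  }
  .readPropertyTable(file)
}

.readPropertyTable <- function(file) {
  df <- utils::read.delim(file, comment.char = "#",
                          stringsAsFactors = FALSE)
  if (!identical(colnames(df), c("dinucleotide", PROPERTY_NAMES)))
    stop("property table must have columns: dinucleotide, ",
         paste(PROPERTY_NAMES, collapse = ", "))
  tab <- as.matrix(df[, PROPERTY_NAMES])
  rownames(tab) <- df$dinucleotide
  dinucs <- as.vector(outer(DNA_BASES, DNA_BASES, paste0))
  if (nrow(tab) != 16L || !setequal(rownames(tab), dinucs))
    stop("property table must have exactly the 16 dinucleotides as rows")
  tab <- tab[sort(rownames(tab)), ]
  storage.mode(tab) <- "double"
  tab
}

#' Physicochemical property matrix of a sequence
#'
#' Maps each adjacent dinucleotide of an (l+1)-length window to its six
#' structural property values, yielding an l x 6 track matrix: row i holds
#' the properties of the dinucleotide at positions (i, i+1).
#'
#' @param sequence DNA string (character or \link[Biostrings]{DNAString})
#'   over A/C/G/T, length >= 2. Ambiguous bases are rejected; drop such
#'   windows at dataset-assembly time if needed.
#' @param properties property lookup, as from [dinucleotideProperties()].
#' @return numeric matrix with \code{nchar(sequence) - 1} rows and the six
#'   property columns; rownames are the dinucleotides.
#' @examples
#' pcMatrix("AAC")        # rows AA, AC
#' nrow(pcMatrix(paste(rep("ACGT", 11), collapse = "")))  # 43
#' @export
pcMatrix <- function(sequence, properties = dinucleotideProperties()) {
  s <- .checkSeq(sequence, minLen = 2L)
  ch <- .seqChars(s)
  l <- length(ch) - 1L
  dinucs <- paste0(ch[seq_len(l)], ch[seq_len(l) + 1L])
  m <- properties[dinucs, , drop = FALSE]
  rownames(m) <- dinucs
  m
}
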