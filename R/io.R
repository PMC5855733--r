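# File dialects: FASTA windows with metadata-bearing identifiers,
# tab-separated site tables and feature tables with a config comment
# header, and versioned model serialization.

#' Read and write window FASTA files
#'
#' Windows are stored as FASTA with the label, origin and optional
#' coordinates encoded in the record identifier:
#' \code{id|label=positive|origin=real[|chrom=chr1|pos=123]}.
#'
#' @param x a \linkS4class{MethylWindowSet}
#' @param path file path
#' @return \code{readWindowsFasta} returns a
#'   \linkS4class{MethylWindowSet}; \code{writeWindowsFasta} returns
#'   \code{path} invisibly.
#' @name windows-fasta
NULL

#' @rdname windows-fasta
#' @export
writeWindowsFasta <- function(x, path) {
  stopifnot(is(x, "MethylWindowSet"))
  seqs <- windowSeqs(x)
  ids <- names(seqs)
  tag <- paste0(ids, "|label=", as.character(windowLabels(x)),
                "|origin=", windowOrigin(x))
  hasCoord <- !is.na(x@chrom)
  tag[hasCoord] <- paste0(tag[hasCoord], "|chrom=", x@chrom[hasCoord],
                          "|pos=", x@pos[hasCoord])
  out <- seqs
  names(out) <- tag
  Biostrings::writeXStringSet(out, path)
  invisible(path)
}

#' @rdname windows-fasta
#' @export
readWindowsFasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  fields <- strsplit(names(seqs), "|", fixed = TRUE)
  getField <- function(f, key, default = NA_character_) {
    hit <- grep(paste0("^", key, "="), f, value = TRUE)
    if (length(hit)) sub(paste0("^", key, "="), "", hit[1]) else default
  }
  id <- vapply(fields, `[`, character(1), 1L)
  label <- vapply(fields, getField, character(1), "label")
  if (anyNA(label))
    stop("FASTA identifiers must carry |label=positive/negative")
  origin <- vapply(fields, getField, character(1), "origin")
  origin[is.na(origin)] <- "real"
  chrom <- vapply(fields, getField, character(1), "chrom")
  pos <- suppressWarnings(
    as.integer(vapply(fields, getField, character(1), "pos")))
  MethylWindowSet(as.character(seqs), label = label, origin = origin,
                  chrom = chrom, pos = pos, id = id)
}

#' Read and write CpG site tables
#'
#' Tab-separated with a header: \code{chrom}, \code{pos} (1-based
#' coordinate of the cytosine), \code{methylated_reads},
#' \code{total_reads}.
#'
#' @param sites a site data.frame
#' @param path file path
#' @return \code{readSiteTable} returns the data.frame.
#' @name site-table
NULL

#' @rdname site-table
#' @export
readSiteTable <- function(path) {
  df <- utils::read.delim(path, comment.char = "#",
                          stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "methylated_reads", "total_reads")
  if (!all(need %in% colnames(df)))
    stop("site table must have columns: ", paste(need, collapse = ", "))
  df
}

#' @rdname site-table
#' @export
writeSiteTable <- function(sites, path) {
  utils::write.table(sites, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read and write feature tables
#'
#' Tab-separated text with a \code{#}-comment header echoing the encoder
#' configuration (wavelet, padding, lambdaMax, ...), then one row per
#' sample: \code{id}, \code{label}, \code{origin}, \code{chrom},
#' \code{pos}, followed by the named feature columns.
#'
#' @param fs a \linkS4class{MethylFeatureSet}
#' @param path file path
#' @return \code{readFeatureTable} returns a
#'   \linkS4class{MethylFeatureSet}.
#' @name feature-table
NULL

#' @rdname feature-table
#' @export
writeFeatureTable <- function(fs, path) {
  stopifnot(is(fs, "MethylFeatureSet"))
  cfg <- encoderConfig(fs)
  hdr <- c("# methylWave feature table v1",
           paste0("# ", names(cfg), " = ",
                  vapply(cfg, function(v) paste(v, collapse = ","),
                         character(1))),
           paste0("# blocks = ",
                  paste(sprintf("%s:%d:%d", blockLedger(fs)$block,
                                blockLedger(fs)$start,
                                blockLedger(fs)$length), collapse = ";")))
  info <- sampleInfo(fs)
  df <- data.frame(id = rownames(featureMatrix(fs)),
                   label = as.character(info$label),
                   origin = info$origin,
                   chrom = info$chrom, pos = info$pos,
                   featureMatrix(fs), check.names = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  suppressWarnings(
    utils::write.table(df, con, sep = "\t", row.names = FALSE,
                       quote = FALSE))
  invisible(path)
}

#' @rdname feature-table
#' @export
readFeatureTable <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  cfg <- .defaultConfig()
  for (key in c("wavelet", "padding")) {
    hit <- grep(paste0("^# ", key, " = "), hdr, value = TRUE)
    if (length(hit)) cfg[[key]] <- sub(paste0("^# ", key, " = "), "", hit[1])
  }
  for (key in c("levels", "lambdaMax", "pseudocount")) {
    hit <- grep(paste0("^# ", key, " = "), hdr, value = TRUE)
    if (length(hit))
      cfg[[key]] <- as.numeric(sub(paste0("^# ", key, " = "), "", hit[1]))
  }
  hit <- grep("^# normalizeKgram = ", hdr, value = TRUE)
  if (length(hit))
    cfg$normalizeKgram <- as.logical(sub("^# normalizeKgram = ", "", hit[1]))
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  meta <- c("id", "label", "origin", "chrom", "pos")
  mat <- as.matrix(df[, !colnames(df) %in% meta, drop = FALSE])
  rownames(mat) <- df$id
  info <- S4Vectors::DataFrame(
    label = factor(df$label, levels = c("negative", "positive")),
    origin = df$origin, chrom = as.character(df$chrom),
    pos = as.integer(df$pos), row.names = df$id)
  new("MethylFeatureSet", features = mat,
      blocks = featureBlocks(cfg), sampleInfo = info, config = cfg)
}

#' Save and load classifier models
#'
#' Models are serialized with a format-version tag plus the package
#' version, so stale files are detected on load.
#'
#' @param model a \linkS4class{SparseBayesModel} or
#'   \linkS4class{MethylSVMModel}
#' @param path file path
#' @return \code{loadModel} returns the model object.
#' @name model-io
NULL

#' @rdname model-io
#' @export
saveModel <- function(model, path) {
  stopifnot(is(model, "SparseBayesModel") || is(model, "MethylSVMModel"))
  saveRDS(list(format = "methylWave-model-v1",
               package_version = as.character(
                 utils::packageVersion("methylWave")),
               model = model), path)
  invisible(path)
}

#' @rdname model-io
#' @export
loadModel <- function(path) {
  obj <- readRDS(path)
  if (!is.list(obj) || !identical(obj$format, "methylWave-model-v1"))
    stop("not a methylWave model file: ", path)
  obj$model
}
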