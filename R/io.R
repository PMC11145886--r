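#' Read a protein/peptide quantity table
#'
#' Expects delimited text with the feature id in the first column (header
#' \code{feature_id} or anything else) and one column per sample. Empty cells
#' become missing values; literal zeros are preserved, since the cleaning
#' rule treats "missing or zero" cells alike but downstream reporting keeps
#' them distinguishable.
#'
#' @param path file path.
#' @param sep field separator; \code{"\t"} (default) or \code{","}.
#' @return A raw-scale \linkS4class{QuantMatrix}.
#' @export
readQuantTable <- function(path, sep = "\t") {
  header <- strsplit(readLines(path, n = 1L), sep, fixed = TRUE)[[1]]
  sample_ids <- header[-1]
  dup <- sample_ids[duplicated(sample_ids)]
  if (length(dup))
    stop("duplicate sample column(s): ", paste(unique(dup), collapse = ", "))
  df <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                   colClasses = c("character", rep("numeric", length(sample_ids))),
                   na.strings = c("", "NA"))
  ncols <- vapply(strsplit(readLines(path), sep, fixed = TRUE), length, 0L)
  if (length(unique(ncols)) > 1L)
    stop("ragged rows: inconsistent field counts")
  fid <- df[[1]]
  if (anyDuplicated(fid))
    stop("duplicate feature id(s): ",
         paste(unique(fid[duplicated(fid)]), collapse = ", "))
  v <- as.matrix(df[, -1, drop = FALSE])
  dimnames(v) <- list(fid, sample_ids)
  QuantMatrix(v, scale = "raw")
}

#' Write a quantity matrix as delimited text
#'
#' Missing cells are written as empty fields, round-tripping through
#' \code{\link{readQuantTable}}.
#'
#' @param m a \linkS4class{QuantMatrix}.
#' @param path output path.
#' @param sep field separator.
#' @return Invisibly, \code{path}.
#' @export
writeQuantTable <- function(m, path, sep = "\t") {
  v <- quantValues(m)
  df <- data.frame(feature_id = rownames(v), v, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a sample metadata table
#'
#' Requires columns \code{sample_id}, \code{group}, \code{age}, \code{sex},
#' \code{ethnicity}, \code{batch}. Empty cells become missing values.
#'
#' @param path file path.
#' @param sep field separator.
#' @return A data.frame of sample metadata.
#' @export
readSampleInfo <- function(path, sep = "\t") {
  df <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                   na.strings = c("", "NA"), stringsAsFactors = FALSE)
  req <- c("sample_id", "group", "age", "sex", "ethnicity", "batch")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("missing metadata column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id)) stop("duplicate sample ids in metadata")
  df
}
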