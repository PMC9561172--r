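#' Read a (possibly gzipped) multi-record FASTA file
#'
#' @param path FASTA file path.
#' @return a [Biostrings::DNAStringSet].
#' @export
read_genome_fasta <- function(path) Biostrings::readDNAStringSet(path)

#' Write genome sequences as FASTA wrapped at 80 columns
#'
#' @param seqs a [Biostrings::DNAStringSet] (or named character vector).
#' @param path output path.
#' @return `path` invisibly.
#' @export
write_genome_fasta <- function(seqs, path) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path, width = 80L)
  invisible(path)
}

#' Read a samples x taxa abundance TSV
#'
#' The first column holds sample ids (or taxon ids when `transposed`); the
#' remaining columns are numeric.
#'
#' @param path TSV path.
#' @param transposed set to `TRUE` when rows are taxa and columns samples.
#' @return numeric samples x taxa matrix with dimnames.
#' @export
read_abundance_tsv <- function(path, transposed = FALSE) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  if (transposed) t(m) else m
}

#' Write a samples x taxa abundance matrix as TSV
#'
#' @param m numeric matrix with dimnames.
#' @param path output path.
#' @param id_column header for the first (sample id) column.
#' @return `path` invisibly.
#' @export
write_abundance_tsv <- function(m, path, id_column = "sample_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1] <- id_column
  write_tsv_file(df, path)
}
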