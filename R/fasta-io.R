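#' Read a protein FASTA file
#'
#' Reads a multi-record protein FASTA (wrapped lines allowed). The record id
#' is the first whitespace-delimited token of each header.
#'
#' @param path Path to a FASTA file.
#' @return A data.frame with columns `id` and `sequence`.
#' @export
read_protein_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
  data.frame(id = ids, sequence = as.character(set), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Read a DNA FASTA file
#'
#' @inheritParams read_protein_fasta
#' @return A data.frame with columns `id` and `sequence`.
#' @export
read_dna_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
  data.frame(id = ids, sequence = as.character(set), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Write sequences to FASTA
#'
#' Writes a named character vector (or `id`/`sequence` data.frame) as FASTA
#' wrapped at 60 columns.
#'
#' @param x Named character vector of sequences, or a data.frame with
#'   columns `id` and `sequence`.
#' @param path Output path.
#' @param type `"dna"` or `"protein"`.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, type = c("dna", "protein")) {
  type <- match.arg(type)
  if (is.data.frame(x)) {
    seqs <- stats::setNames(x$sequence, x$id)
  } else {
    seqs <- x
  }
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    stop("all sequences must be named")
  }
  set <- if (type == "dna") Biostrings::DNAStringSet(seqs) else
    Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}
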