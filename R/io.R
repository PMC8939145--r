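#' Read protein sequences from FASTA
#'
#' Thin wrapper over Biostrings that returns a plain named character
#' vector (ids preserved verbatim, first whitespace-delimited token).
#'
#' @param path FASTA file path.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(x))
  setNames(as.character(x), ids)
}

#' Write protein sequences to FASTA
#'
#' Sequences are wrapped at 60 columns; ids written verbatim.
#'
#' @param seqs named character vector.
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = 60L)
  invisible(path)
}

#' Read an alignment from aligned FASTA
#'
#' @param path aligned-FASTA path (gap character `-`).
#' @return a [protein_msa][new_msa].
#' @export
read_msa_fasta <- function(path) {
  x <- read_fasta(path)
  new_msa(names(x), unname(x))
}

#' Write an alignment to aligned FASTA
#'
#' @param m a [protein_msa][new_msa].
#' @param path output path.
#' @export
write_msa_fasta <- function(m, path) {
  write_fasta(setNames(m$rows, m$ids), path)
}
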