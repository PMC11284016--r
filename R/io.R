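# Thin FASTA wrappers used across modules.

#' Read amino-acid sequences from FASTA
#'
#' @param path Path to a FASTA file.
#' @return A named character vector of sequences.
#' @export
read_fasta <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(seqs), sub("\\s.*$", "", names(seqs)))
}

#' Write amino-acid sequences to FASTA
#'
#' @param sequences Named character vector.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(sequences, path) {
  x <- Biostrings::AAStringSet(sequences)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
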