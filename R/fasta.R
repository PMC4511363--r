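# FASTA in/out, thin wrappers over Biostrings.

#' Read protein sequences from a FASTA file
#'
#' @param path Path to a (multi-record) FASTA file.
#' @return Named character vector of sequences; names are the full
#'   description lines.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(set), names(set))
}

#' Write protein sequences to a FASTA file
#'
#' @param sequences Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  set <- Biostrings::AAStringSet(sequences)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
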