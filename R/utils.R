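#' @useDynLib circlip, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Read a genome FASTA preserving soft-masking
#'
#' Loads a (possibly soft-masked) genome FASTA as a named character vector.
#' Lowercase letters are preserved so that masked fractions can be computed;
#' sequence-extraction helpers uppercase their output.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector, one element per sequence; names are the
#'   first whitespace-delimited token of each header.
#' @export
read_genome <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  x <- as.character(ss)
  names(x) <- sub("\\s.*$", "", names(ss))
  x
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param append Append to an existing file?
#' @export
write_fasta <- function(seqs, path, append = FALSE) {
  ss <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(ss, filepath = path, append = append,
                              format = "fasta")
  invisible(path)
}

#' Reverse-complement nucleotide strings
#'
#' @param x Character vector of A/C/G/T/N sequences (case-insensitive).
#' @return Character vector of reverse complements (uppercase).
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(toupper(x))))
}

## 0-based half-open substring of a sequence string
subseq0 <- function(seq, start, end) {
  substr(seq, start + 1L, end)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
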