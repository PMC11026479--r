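#' Reverse-complement DNA strings
#'
#' Thin character-vector wrapper around [Biostrings::reverseComplement()].
#'
#' @param x Character vector of DNA sequences (A/C/G/T/N).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

DNA_BASES <- c("A", "C", "G", "T")

#' Random DNA sequences
#'
#' @param n Number of sequences.
#' @param len Length of each sequence (recycled).
#' @return Character vector of random A/C/G/T sequences.
#' @keywords internal
random_dna <- function(n, len) {
  len <- rep_len(len, n)
  vapply(len, function(l) paste(sample(DNA_BASES, l, replace = TRUE), collapse = ""),
         character(1))
}

#' Split sequences into single characters
#' @keywords internal
#' @noRd
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)

## Hamming distance between equal-length strings (vectorised over `x`)
hamming <- function(x, y) {
  stopifnot(nchar(y) == nchar(x)[1] || length(x) == 0)
  xs <- seq_chars(x)
  ys <- seq_chars(y)[[1]]
  vapply(xs, function(a) sum(a != ys), integer(1))
}

is_single_string <- function(x) is.character(x) && length(x) == 1 && !is.na(x)

assert_that <- function(ok, msg) if (!ok) stop(msg, call. = FALSE)

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
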