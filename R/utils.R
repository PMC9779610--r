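# Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse-complement nucleotide strings
#'
#' @param x Character vector of nucleotide sequences (A/C/G/T).
#' @return Character vector of reverse complements.
#' @export
#' @examples
#' revcomp("ACGT")
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Translate nucleotide sequences with the standard genetic code
#'
#' Trailing partial codons are dropped. Stop codons translate to `"*"`.
#'
#' @param x Character vector of nucleotide sequences.
#' @return Character vector of amino-acid sequences.
#' @export
#' @examples
#' translate_nt("TGTGCGAGATGG")
translate_nt <- function(x) {
  vapply(x, function(s) {
    n <- nchar(s) %/% 3L * 3L
    if (n == 0L) return("")
    starts <- seq.int(1L, n - 2L, by = 3L)
    paste(Biostrings::GENETIC_CODE[substring(s, starts, starts + 2L)],
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# n random nucleotide strings of width `len`, drawn from the session RNG
random_nt <- function(n, len) {
  if (n == 0L) return(character(0))
  m <- matrix(sample(DNA_BASES, n * len, replace = TRUE), nrow = n)
  apply(m, 1L, paste, collapse = "")
}

# n distinct random barcodes of width `len`
random_barcodes <- function(n, len = 16L) {
  out <- unique(random_nt(n, len))
  while (length(out) < n) {
    out <- unique(c(out, random_nt(n - length(out), len)))
  }
  out[seq_len(n)]
}

# Hamming distance between two equal-length strings
hamming <- function(a, b) {
  sum(charToRaw(a) != charToRaw(b))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
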