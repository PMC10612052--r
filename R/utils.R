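DNA_BASES <- c("A", "C", "G", "T")

# IUPAC nucleotide codes accepted in motifs/primers
IUPAC_CODES <- c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", "N")

#' Clean a nucleotide string
#'
#' Uppercases and maps U to T (direct RNA sequencing reads come in RNA
#' alphabet). Errors on characters outside the IUPAC alphabet unless
#' `strict = FALSE`.
#' @param x character vector of sequences.
#' @param strict error on non-ACGTN characters (default TRUE allows IUPAC).
#' @return cleaned character vector.
#' @keywords internal
clean_seq <- function(x, strict = FALSE) {
  x <- chartr("u", "t", toupper(x))
  x <- chartr("U", "T", x)
  bad <- stringr::str_detect(x, paste0("[^", paste(IUPAC_CODES, collapse = ""), "]"))
  if (any(bad)) stop("sequence contains non-IUPAC characters")
  if (strict) {
    bad <- stringr::str_detect(x, "[^ACGTN]")
    if (any(bad)) stop("sequence contains IUPAC ambiguity codes where ACGTN required")
  }
  x
}

#' Reverse complement of nucleotide strings
#' @param x character vector (ACGTN + IUPAC).
#' @return character vector of reverse complements.
#' @export
#' @examples
#' revcomp("ACGT")
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# substring by 1-based inclusive coordinates, vectorized over start/end
subseq_chr <- function(seq, start, end) substring(seq, start, end)

# random DNA of length n under the current RNG
random_dna <- function(n) paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")

# derive a child seed from a user seed; keeps within 32-bit integer range
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1103L + offset) %% 2147483647)
}

# split a character string into single characters
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]
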