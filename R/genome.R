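#' Create a genome object
#'
#' A genome is a named nucleotide sequence with 1-based inclusive coordinates
#' and an optional gene annotation table. This is the basic container passed
#' around the package; annotations travel with the sequence so that
#' reconstruction and liftover can re-map them.
#'
#' @param seq nucleotide string over A/C/G/T/N (U is mapped to T, case is
#'   ignored).
#' @param name genome name (used in FASTA headers and reports).
#' @param annotations tibble with columns `gene`, `start`, `end`, `strand`
#'   (1-based inclusive; strand "+" or "-").
#' @return an object of class `genome`.
#' @export
#' @examples
#' g <- genome("ATGAAATAA", name = "toy")
#' genome_length(g)
genome <- function(seq, name = "genome", annotations = NULL) {
  seq <- clean_seq(seq, strict = TRUE)
  if (nchar(seq) < 1) stop("genome sequence must have length >= 1")
  if (is.null(annotations)) {
    annotations <- tibble::tibble(gene = character(), start = integer(),
                                  end = integer(), strand = character())
  }
  annotations <- tibble::as_tibble(annotations)
  stopifnot(all(c("gene", "start", "end", "strand") %in% names(annotations)))
  if (nrow(annotations)) {
    if (any(annotations$start > annotations$end)) stop("annotation start > end")
    if (any(annotations$start < 1) || any(annotations$end > nchar(seq)))
      stop("annotation coordinates outside [1, genome length]")
    if (!all(annotations$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  }
  structure(list(name = name, seq = seq, annotations = annotations),
            class = "genome")
}

#' @export
print.genome <- function(x, ...) {
  cat("<genome> ", x$name, ": ", nchar(x$seq), " nt, ",
      nrow(x$annotations), " annotation(s)\n", sep = "")
  invisible(x)
}

#' Genome length in nucleotides
#' @param g a [genome()].
#' @return integer length.
#' @export
genome_length <- function(g) nchar(g$seq)

#' Extract genome subsequence (1-based inclusive)
#' @param g a [genome()].
#' @param start,end 1-based inclusive coordinates.
#' @return character string.
#' @export
genome_seq <- function(g, start = 1L, end = genome_length(g)) {
  stopifnot(start >= 1, end <= genome_length(g), start <= end)
  substring(g$seq, start, end)
}

#' Read a genome from a FASTA file
#'
#' Reads the first (or named) record of a FASTA file into a [genome()].
#' @param path FASTA file.
#' @param which record index or name (default first).
#' @return a [genome()].
#' @export
read_fasta <- function(path, which = 1L) {
  ss <- Biostrings::readDNAStringSet(path)
  if (is.character(which)) which <- match(which, names(ss))
  genome(as.character(ss[[which]]), name = sub("\\s.*$", "", names(ss)[which]))
}

#' Write a genome to FASTA (wrapped at 60 columns)
#' @param g a [genome()] or named character vector of sequences.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(g, path) {
  if (inherits(g, "genome")) {
    ss <- Biostrings::DNAStringSet(setNames(g$seq, g$name))
  } else {
    ss <- Biostrings::DNAStringSet(g)
  }
  Biostrings::writeXStringSet(ss, path, width = 60L)
  invisible(path)
}

#' Read/write gene annotations as BED
#'
#' BED is 0-based half-open on disk; coordinates are converted to the
#' package's 1-based inclusive convention at the boundary.
#' @param path BED file.
#' @return tibble with `gene`, `start`, `end`, `strand`.
#' @export
read_bed <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  tibble::tibble(gene = as.character(df[[4]]),
                 start = as.integer(df[[2]]) + 1L,
                 end = as.integer(df[[3]]),
                 strand = if (ncol(df) >= 6) as.character(df[[6]]) else "+")
}

#' @rdname read_bed
#' @param annotations annotation tibble (`gene`, `start`, `end`, `strand`).
#' @param chrom chromosome/sequence name for column 1.
#' @export
write_bed <- function(annotations, path, chrom = "genome") {
  df <- data.frame(chrom = chrom,
                   start = annotations$start - 1L,
                   end = annotations$end,
                   name = annotations$gene,
                   score = 0L,
                   strand = annotations$strand)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read/write gene annotations as a simple 1-based TSV
#' @param path TSV with columns gene, start, end (1-based inclusive) and
#'   optionally strand.
#' @return tibble with `gene`, `start`, `end`, `strand`.
#' @export
read_gene_tsv <- function(path) {
  df <- tibble::as_tibble(read.delim(path, stringsAsFactors = FALSE))
  if (!"strand" %in% names(df)) df$strand <- "+"
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df[, c("gene", "start", "end", "strand")]
}

#' @rdname read_gene_tsv
#' @param annotations annotation tibble.
#' @export
write_gene_tsv <- function(annotations, path) {
  write.table(annotations, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
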