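orfs_one_strand <- function(seq, min_codons) {
  L <- nchar(seq)
  out <- list()
  for (frame in 0:2) {
    starts <- seq.int(1L + frame, L - 2L, by = 3L)
    if (length(starts) < 1) next
    cod <- substring(seq, starts, starts + 2L)
    is_stop <- cod %in% STOP_CODONS
    is_atg <- cod == "ATG"
    stop_idx <- which(is_stop)
    if (!length(stop_idx)) next
    atg_idx <- which(is_atg)
    if (!length(atg_idx)) next
    # for each ATG, the index of the next in-frame stop at or after it
    nxt <- stop_idx[findInterval(atg_idx - 1L, stop_idx) + 1L]
    ok <- !is.na(nxt)
    atg_idx <- atg_idx[ok]; nxt <- nxt[ok]
    if (!length(atg_idx)) next
    # maximal ORF per stop = its earliest ATG after the previous stop
    first_atg <- tapply(atg_idx, nxt, min)
    stops <- as.integer(names(first_atg))
    n_cod <- stops - as.integer(first_atg) + 1L
    keep <- n_cod >= min_codons
    if (!any(keep)) next
    out[[length(out) + 1L]] <- tibble::tibble(
      start = starts[as.integer(first_atg[keep])],
      end = starts[stops[keep]] + 2L,
      n_codons = n_cod[keep])
  }
  dplyr::bind_rows(out)
}

#' Find open reading frames
#'
#' Reports maximal ATG-to-stop ORFs (standard genetic code) of at least
#' `min_codons` codons, where maximal means the earliest start codon after
#' the previous in-frame stop. Coordinates are 1-based inclusive and
#' include the stop codon; minus-strand ORFs are reported in plus-strand
#' coordinates with `strand = "-"`.
#'
#' @param g a [genome()].
#' @param min_codons minimum ORF length in codons, stop included
#'   (default 60).
#' @param strand `"+"`, `"-"` or `"both"`.
#' @return tibble `orf`, `start`, `end`, `strand`, `n_codons`, sorted by
#'   `start`.
#' @export
find_orfs <- function(g, min_codons = 60L, strand = c("both", "+", "-")) {
  strand <- match.arg(strand)
  L <- genome_length(g)
  res <- list()
  if (strand %in% c("both", "+")) {
    plus <- orfs_one_strand(g$seq, min_codons)
    if (nrow(plus)) plus$strand <- "+"
    res[[1]] <- plus
  }
  if (strand %in% c("both", "-")) {
    minus <- orfs_one_strand(revcomp(g$seq), min_codons)
    if (nrow(minus)) {
      tmp <- minus$start
      minus$start <- L - minus$end + 1L
      minus$end <- L - tmp + 1L
      minus$strand <- "-"
    }
    res[[2]] <- minus
  }
  out <- dplyr::bind_rows(res)
  if (nrow(out) == 0) {
    return(tibble::tibble(orf = character(), start = integer(), end = integer(),
                          strand = character(), n_codons = integer()))
  }
  out <- dplyr::arrange(out, .data$start, .data$end)
  out$orf <- sprintf("orf_%03d", seq_len(nrow(out)))
  out[, c("orf", "start", "end", "strand", "n_codons")]
}

#' Scan a genome for a (possibly degenerate) motif
#'
#' Finds all occurrences of an IUPAC motif with up to `max_mismatch`
#' mismatches, on the requested strand(s). Used for conserved intergenic
#' transcription signals (e.g. `GACACAAAAT` between rhabdovirus genes),
#' whose absence between duplication-derived ORFs argues against their
#' independent transcription.
#'
#' @param g a [genome()].
#' @param motif IUPAC motif (non-empty).
#' @param max_mismatch tolerated mismatches (default 0).
#' @param strand `"+"`, `"-"` or `"both"` (default `"+"`).
#' @return tibble `start`, `end`, `strand`, sorted by `start`.
#' @export
scan_motif <- function(g, motif, max_mismatch = 0L, strand = c("+", "-", "both")) {
  strand <- match.arg(strand)
  if (!is.character(motif) || length(motif) != 1 || !nchar(motif))
    stop("config error: motif must be a non-empty string")
  motif <- clean_seq(motif)  # errors on non-IUPAC
  subject <- Biostrings::DNAString(g$seq)
  hit <- function(pat, str) {
    m <- Biostrings::matchPattern(pat, subject, max.mismatch = max_mismatch,
                                  fixed = "subject")
    tibble::tibble(start = Biostrings::start(m), end = Biostrings::end(m),
                   strand = rep(str, length(m)))
  }
  out <- dplyr::bind_rows(
    if (strand %in% c("+", "both")) hit(motif, "+"),
    if (strand %in% c("-", "both")) hit(revcomp(motif), "-"))
  dplyr::arrange(out, .data$start)
}

#' Write ORF annotations as GFF3
#' @param orfs tibble from [find_orfs()] (or an annotation tibble with
#'   `gene`, `start`, `end`, `strand`).
#' @param path output file.
#' @param seqid sequence name for column 1.
#' @export
write_gff3 <- function(orfs, path, seqid = "genome") {
  name <- if ("orf" %in% names(orfs)) orfs$orf else orfs$gene
  lines <- c("##gff-version 3",
             sprintf("%s\tvirdup\tCDS\t%d\t%d\t.\t%s\t0\tID=%s",
                     seqid, orfs$start, orfs$end, orfs$strand, name))
  writeLines(lines, path)
  invisible(path)
}
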