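#' Define a PCR primer
#'
#' @param name primer name.
#' @param seq primer sequence 5'->3' (A/C/G/T only; at least 10 nt).
#' @param ref_start,ref_end optional documented binding coordinates on a
#'   reference genome (annealed site, `ref_start <= ref_end`).
#' @param orientation optional documented orientation ("+" forward, "-"
#'   reverse).
#' @return one-row primer tibble.
#' @export
primer <- function(name, seq, ref_start = NA_integer_, ref_end = NA_integer_,
                   orientation = NA_character_) {
  seq <- clean_seq(seq, strict = TRUE)
  if (nchar(seq) < 10) stop("primer must be at least 10 nt")
  if (stringr::str_detect(seq, "N")) stop("primer must be A/C/G/T only")
  tibble::tibble(name = name, seq = seq,
                 ref_start = as.integer(ref_start),
                 ref_end = as.integer(ref_end),
                 orientation = orientation)
}

#' Read a primer table from TSV
#'
#' Columns: `name`, `seq`, optionally `ref_start`, `ref_end`,
#' `orientation`.
#' @param path TSV file.
#' @return primer tibble.
#' @export
read_primers <- function(path) {
  df <- tibble::as_tibble(read.delim(path, stringsAsFactors = FALSE))
  dplyr::bind_rows(purrr::pmap(df, function(name, seq, ...) {
    dots <- list(...)
    primer(name, seq,
           ref_start = dots$ref_start %||% NA_integer_,
           ref_end = dots$ref_end %||% NA_integer_,
           orientation = dots$orientation %||% NA_character_)
  }))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

count_mismatches <- function(site, target) {
  mapply(function(a, b) sum(seq_chars(a) != seq_chars(b)), site, target,
         USE.NAMES = FALSE)
}

#' Find primer binding sites on a genome
#'
#' A primer anneals at every position where it (plus strand) or its reverse
#' complement (minus strand) matches with at most `max_mismatch` mismatches
#' and no mismatch in the 3'-terminal `three_prime_exact` bases (the
#' polymerase extension clamp). Indels are not considered; primer
#' thermodynamics are deliberately out of scope -- product sets on small
#' genomes are determined by coordinates.
#'
#' @param g a [genome()].
#' @param pr a [primer()] row (or plain sequence string).
#' @param max_mismatch tolerated mismatches outside the clamp (default 0).
#' @param three_prime_exact length of the exact 3' clamp (default 5).
#' @return tibble of sites: `start`, `end`, `strand`, `n_mismatch`, sorted
#'   by coordinate. A minus-strand site means the primer primes leftward
#'   (its 3' end at `start`).
#' @export
find_primer_sites <- function(g, pr, max_mismatch = 0L, three_prime_exact = 5L) {
  pseq <- if (is.character(pr)) clean_seq(pr, strict = TRUE) else pr$seq[1]
  n <- nchar(pseq)
  subject <- Biostrings::DNAString(g$seq)
  one_strand <- function(pattern, strand) {
    m <- Biostrings::matchPattern(pattern, subject, max.mismatch = max_mismatch)
    if (length(m) == 0) {
      return(tibble::tibble(start = integer(), end = integer(),
                            strand = character(), n_mismatch = integer()))
    }
    st <- Biostrings::start(m); en <- Biostrings::end(m)
    site <- substring(g$seq, st, en)
    mm <- count_mismatches(site, pattern)
    # clamp: the primer's 3' end is the right end of a plus-strand site and
    # the left end of a minus-strand site
    clamp_ok <- if (strand == "+") {
      count_mismatches(substring(site, n - three_prime_exact + 1L, n),
                       substring(pattern, n - three_prime_exact + 1L, n)) == 0L
    } else {
      count_mismatches(substring(site, 1L, three_prime_exact),
                       substring(pattern, 1L, three_prime_exact)) == 0L
    }
    tibble::tibble(start = st, end = en, strand = strand,
                   n_mismatch = as.integer(mm))[clamp_ok, , drop = FALSE]
  }
  dplyr::arrange(dplyr::bind_rows(one_strand(pseq, "+"),
                                  one_strand(revcomp(pseq), "-")),
                 .data$start)
}

#' Enumerate in-silico PCR products
#'
#' One amplicon per (plus-strand forward site, minus-strand reverse site)
#' pair with the forward site upstream of the reverse site and product
#' length `rev_end - fwd_start + 1` at most `max_len`. When a
#' [dup_model()] is supplied (and `g` is its reconstruction), each product
#' is annotated with the region its primers sit in, the ordered region path
#' it traverses, and whether it spans the duplication junction.
#'
#' @param g template [genome()].
#' @param fwd,rev forward and reverse [primer()]s.
#' @param max_len largest reported product (default 10,000; use ~2000 to
#'   emulate conventional short-extension PCR).
#' @inheritParams find_primer_sites
#' @param model optional [dup_model()] whose reconstruction `g` is.
#' @return amplicon tibble: `fwd_start`, `fwd_end`, `rev_start`, `rev_end`,
#'   `length`, `fwd_region`, `rev_region`, `path`, `spans_junction`.
#' @export
enumerate_amplicons <- function(g, fwd, rev, max_len = 10000L,
                                max_mismatch = 0L, three_prime_exact = 5L,
                                model = NULL) {
  fs <- find_primer_sites(g, fwd, max_mismatch, three_prime_exact)
  rs <- find_primer_sites(g, rev, max_mismatch, three_prime_exact)
  fs <- fs[fs$strand == "+", , drop = FALSE]
  rs <- rs[rs$strand == "-", , drop = FALSE]
  out <- tidyr::crossing(dplyr::rename(fs, fwd_start = "start", fwd_end = "end",
                                       fwd_mm = "n_mismatch", fwd_strand = "strand"),
                         dplyr::rename(rs, rev_start = "start", rev_end = "end",
                                       rev_mm = "n_mismatch", rev_strand = "strand")) %>%
    dplyr::filter(.data$fwd_end < .data$rev_start) %>%
    dplyr::mutate(length = .data$rev_end - .data$fwd_start + 1L) %>%
    dplyr::filter(.data$length <= max_len) %>%
    dplyr::arrange(.data$length)
  ann <- annotate_amplicons(out, model)
  dplyr::select(ann, "fwd_start", "fwd_end", "rev_start", "rev_end",
                "length", "fwd_region", "rev_region", "path", "spans_junction")
}

annotate_amplicons <- function(amp, model) {
  if (nrow(amp) == 0 || is.null(model)) {
    amp$fwd_region <- rep(NA_character_, nrow(amp))
    amp$rev_region <- NA_character_
    amp$path <- NA_character_
    amp$spans_junction <- rep(NA, nrow(amp))
    return(amp)
  }
  rm_ <- region_map(model)
  region_at <- function(pos) {
    rm_$region[findInterval(pos, rm_$start)]
  }
  maps <- model_maps(model)
  pr <- maps$primary_range; dr <- maps$duplication_range
  amp %>% dplyr::mutate(
    fwd_region = region_at(.data$fwd_start),
    rev_region = region_at(.data$rev_end),
    path = purrr::map2_chr(.data$fwd_start, .data$rev_end, function(a, b) {
      covered <- rm_[rm_$end >= a & rm_$start <= b, ]
      paste(covered$region, collapse = ">")
    }),
    spans_junction = .data$fwd_start <= pr[2] & .data$rev_end >= dr[1])
}

#' Apply a deletion to a genome
#'
#' Convenience for building deletion variants (e.g. an X-minus-like genome
#' lacking part of an accessory gene): removes the 1-based inclusive
#' interval `[start, end]`. Annotations overlapping the deletion are
#' dropped; downstream annotations are shifted.
#'
#' @param g a [genome()].
#' @param start,end interval to delete.
#' @return a [genome()].
#' @export
delete_interval <- function(g, start, end) {
  stopifnot(start >= 1, end <= genome_length(g), start <= end)
  w <- end - start + 1L
  ann <- g$annotations
  if (nrow(ann)) {
    keep <- ann$end < start | ann$start > end
    ann <- ann[keep, , drop = FALSE]
    shift <- ann$start > end
    ann$start[shift] <- ann$start[shift] - w
    ann$end[ann$end > end] <- ann$end[ann$end > end] - w
  }
  genome(paste0(substring(g$seq, 1L, start - 1L),
                substring(g$seq, end + 1L, genome_length(g))),
         name = paste0(g$name, "_del"), annotations = ann)
}
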